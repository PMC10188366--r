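---
title: "Quantifying base-editing outcomes in paired guide–target libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing outcomes in paired guide–target libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beditlib)
```

## The measurement problem

A base editor's practical value is set by four quantities that vary from
site to site: how often it edits at all, *where* in the protospacer it
edits (the editing window), how strongly it prefers its intended substrate
class (C-vs-A selectivity), and which flanking sequence contexts it favors.
Comprehensive-context libraries measure all four at once: thousands of
cassettes, each pairing an sgRNA with its own target site, are integrated
into a cell line, the editor is expressed, and the outcomes are read out by
paired-end amplicon sequencing — a forward read over the target cassette
and a short reverse read over the spacer that identifies the member.

`beditlib` implements the analysis for this design end to end, together
with a simulator that generates the same kind of data from a known editor
model, so that every statistic the pipeline reports can be checked against
an analytic ground truth.

Throughout, positions are protospacer coordinates: 1–20 is the
protospacer, 21–23 the PAM, 0 the base immediately upstream, and the
editing window of interest is −9..20. Only the four substitution classes a
TadA-family editor produces are tracked: A→G, C→T, and the C→G / C→A
byproducts.

## Read processing

**Quality filter.** A read pair is kept iff every base in the editing
window of the forward read and in the 20-nt spacer of the reverse read has
Phred ≥ 28. Bases outside these regions are irrelevant to genotyping and
are deliberately unconstrained.

**Candidate nomination.** The editing window (30 nt) of every member is
cut into five non-overlapping 6-mer tiles anchored at position −9. A read
nominates every member that shares at least one tile-position-matched
6-mer, ranked by shared-tile count with ties broken by member id. One
substitution corrupts at most one tile (two if it straddled overlapping
tiles, which non-overlapping tiling rules out), so any singly-mutated read
still nominates its true member — a property the test suite checks
exhaustively. Up to five candidates are carried forward; with unique
spacers, the subsequent exact spacer match almost always leaves one.

**Spacer filter.** Candidates whose library spacer differs from the
sequenced spacer in even one base are removed. This is a deliberate
exact-match rule: at a 10⁻³ per-base error rate it discards ~2% of reads
(20 nt × 10⁻³), which the unassigned-read report makes visible. Whether a
spacer edited by the editor itself should still match is an open design
point; the exact rule is conservative, and the report lets a user measure
its cost.

**Genotyping.** Each read is globally aligned to its candidate cassette
(match +1, mismatch −1, affine gaps with open −5 and extend 0; a gap run
of length L costs −5 regardless of L). "Start gap = 0" is read as free
leading gaps on *both* sequences; trailing gaps pay the penalty by
default, because the forward read is designed to span the full window and
end gaps should be rare and penalized. Traceback ties resolve
deterministically (diagonal, then consuming the read, then the reference).
Aligned columns where the reference base is C or A, the read base differs,
and the substitution is tracked become calls; indel columns, N bases and
all other substitutions yield nothing. Reads whose best alignment scores
below a floor (default: half the read length) are routed to the unassigned
bin. The aligner is implemented in C++ (Gotoh's three-matrix recurrence);
its scores are verified against an exhaustive enumeration over all gapped
alignments for short sequences — an oracle that shares no code with the DP.

## Statistics

**Batch screen.** For every (position, class), member-level mutation
frequencies are compared across batches (replicates by default) with a
classical one-way ANOVA F-test; hypotheses with p below 0.005/m (m =
testable hypotheses) are flagged. Flagged hypotheses are reported rather
than removed — in clean data none should appear — with a `drop_flagged`
switch for the alternative. Groups that are entirely constant return p = 1
by convention; groups with zero within-group variance but different means
return p = 0.

**Noise filter.** Sequencing noise at a Q30 site arrives at ~10⁻³ per
base. A mutation observed k₁/n₁ and k₂/n₂ times in the two replicates is
kept iff P(X₁ ≥ k₁)·P(X₂ ≥ k₂) < 0.05 with Xᵢ ~ Binomial(nᵢ, 10⁻³). The
tail product is the conservative joint statistic: a count that looks like
noise in either replicate alone (e.g. 1/100, joint tail 0.095) survives
when it recurs in both (0.095² ≈ 0.009). The filter's operating
characteristic is fully enumerable, and the tests compare simulated
retention rates against that closed form. One caveat this enumeration
exposes: at a true frequency of 1% and depth 300 the filter's retention is
0.961, not arbitrarily close to 1 — it fails exactly when both replicates
show ≤ 1 edited read — reaching >0.999 only at ~2%. Mutations that fail
the filter keep their coverage but contribute zero edited reads, so they
attenuate (never inflate) downstream efficiencies.

**Pooling and profiles.** Replicates are pooled as Σkᵢ/Σnᵢ — the MLE of a
per-read editing rate, not the mean of per-replicate ratios. Per-position
class efficiency is the unweighted mean over the members whose reference
actually carries the substrate base at that position; members without the
base at a position do not dilute it. Zero pooled coverage yields a missing
value, never zero.

**Window and selectivity.** The editing window is every position with at
least 30% of the peak average efficiency of the window-defining class
(C→T by default); it is scale-invariant and reported as-is, contiguous or
not. Selectivity is exp(mean over window positions of ln(e_C→T/e_A→G)) —
the geometric mean of per-position ratios. Window positions with a zero or
undefined denominator have no defined log-ratio; they are excluded with a
warning rather than imputed, which keeps the estimate finite and
conservative. This exclusion rule is a documented package choice, since
the handling of such positions in this statistic is genuinely open.

**Read-level summaries.** Average editing efficiency is the unweighted
member mean of the fraction of genotyped reads (pooled across replicates)
carrying at least one retained call of the specified class set in the
window. Conditional co-editing is P(≥1 A→G call | ≥1 C→T call) across
reads, and the ABE:CBE ratio divides the A→G and C→T averages.

**Context motifs.** Member-level pooled efficiencies at the designed
substrate position are transformed by the stabilized logit
log((x + ε)/(1 + ε − x)), ε = 0.001 — finite at 0 and 1, with ε sized to
the sequencing noise floor; the log is natural (the base would only
rescale weights). Targets are regressed on one-hot context indicators at
offsets −3..+3 (excluding the substrate base itself, separate fits per
substrate class) by ridge regression with α = 10⁻⁵ — solved from the
penalized normal equations with the intercept unpenalized, the tiny ridge
resolving the one-hot redundancy that would make ordinary least squares
rank-deficient. The split is a seeded random 80:20; the held-out Pearson R
is the motif confidence and logo opacity. Reported weights are centered to
mean zero over the four bases at each offset, the identifiable contrast.
Regressing the designed position (rather than pooling all window
positions) is the default because the library's context design is anchored
there; `target_efficiencies()` takes a `position` argument for the pooled
alternative.

**Editor comparison.** Per-member efficiencies of two editors are related
by total least squares — both axes are measured, so ordinary least squares
would attenuate the slope toward zero (a contrast the tests demonstrate).
The line is constrained through the origin because "fold change =
1/slope" is only meaningful for a one-parameter line; the slope comes from
the principal eigenvector of the 2×2 second-moment matrix, and an
`intercept` flag provides the mean-centered sensitivity variant.

## The simulator and its ground truth

The generator emulates the comprehensive-context design at reduced scale.
Each member's cassette is 94 nt — 30 nt upstream flank, the 20-nt
protospacer, an NGG PAM and a downstream flank — so the 94-nt forward read
covers the whole cassette and the window sits at fixed read offsets, as in
a fixed-primer amplicon. The reverse 56-nt read carries the spacer between
constant 18-nt scaffold flanks. The substrate base (C or A, alternating)
sits at protospacer position 6; the first 16 members per base cycle
through all 16 (5′, 3′) neighbor pairs so dinucleotide contexts are fully
covered from 32 members up. Flank lengths are parameterized package
choices: the original cassette architecture is not fully specified by its
geometry alone, and nothing downstream depends on more than the window
offsets.

The editor model is additive on the log-odds scale — conversion
probability logistic(μ + w_pos + Σ context weights) per site in engaged
reads — which makes the motif regression correctly specified and parameter
recovery a meaningful test. A per-read engagement latent (probability
`engage_prob`) couples edits across sites of the same read, so conditional
co-editing statistics are exercised; `engage_prob = 1` reduces to
independent sites. C conversions split into C→G/C→A byproducts by fixed
fractions. Depth per member and replicate is Poisson around 300× — the
coverage the assay is designed to maintain — sequencing errors substitute
uniformly at 10⁻³ (Q30), read qualities are Phred+33 with an optional
demoted fraction, and paired reads are 94/56 nt. Replicates are generated
exchangeably, so the batch screen should (and does) flag nothing.

`truth_statistics()` computes, without simulation, the expected
per-position class efficiencies, window, selectivity, averages and
co-editing implied by a model on a library, using the same estimator
definitions as the pipeline. The reference conditions in `study_models()`
fix engaged C-conversion rates (0.20, 0.35, 0.50, 0.60, 0.40, 0.25) at
positions 3–8 over a 2% floor — a ground-truth window of exactly 3–8 —
with A rates 25-fold lower everywhere (ground-truth selectivity exactly
25), an attenuated variant at 1/1.25 of every rate, and a dual editor with
equal C and A profiles at 50% engagement.

What the simulator does *not* model — indels, deaminase processivity
beyond the engagement latent, PCR amplification bias, clonal-expansion
batch artifacts, position-dependent quality decay — bounds what passing
tests show: they validate the statistical machinery against data that
satisfies the model's assumptions, not robustness to artifacts the real
assay may contain. On real data the batch screen and the unassigned-read
report are the instruments for noticing such violations.

## Numerical and scale choices

* The stabilized logit computes its denominator as `(1 − x) + ε` so that
  f(0.5) is exactly zero in floating point.
* All randomness flows through explicit seeds (`withr::with_seed`);
  identical configurations give byte-identical FASTQ and tables.
* Degenerate inputs are explicit: empty FASTQ gives an empty counts table
  with a zero-read report; all-zero profiles give an empty window with a
  warning; zero pooled coverage is missing, never zero; zero-variance
  motif targets give zero weights and test R 0 with a warning.
* Alignment ties, candidate ties and assignment ties all break by member
  id or fixed move order, so results are order-independent.
* Verification runs use 200 members × 2 replicates × 300× depth
  (~120,000 read pairs) for end-to-end recovery — large enough that the
  window is recovered exactly and selectivity to within a few percent —
  2,000 members for motif recovery, and exhaustive enumeration up to
  length-8 sequences for the aligner oracle.

## Limitations

Selectivity inherits a mild upward bias at low adenine-editing depths: the
noise filter censors members whose A→G counts sit at the noise floor,
which shrinks the denominator of the per-position ratio. At the reference
depth (300× per replicate) this stays within a few percent; at
substantially lower coverage the window-position exclusions (and their
warnings) should be inspected. The exact-match spacer filter discards
legitimately edited reads if the editor edits the spacer cassette itself;
the unassigned fraction quantifies the exposure. The motif model is linear
in one-hot contexts — interactions between flanking positions are out of
scope.
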