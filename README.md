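# beditlib

Library-scale analysis of CRISPR base-editing outcomes.

Base editors — deaminase–Cas9-nickase fusions that convert C•G→T•A (CBEs)
or A•T→G•C (ABEs) without double-strand breaks — are routinely profiled on
genomically integrated libraries of thousands of paired sgRNA/target-site
cassettes that systematically vary the sequence context around a substrate
base at protospacer position 6. `beditlib` implements the complete analysis
chain for such experiments, for researchers who need to quantify an
editor's efficiency, editing window, C-vs-A selectivity and sequence
context preferences from paired-end amplicon reads:

* **Read assignment** — Q28 quality filtering over the editing window and
  spacer, candidate nomination by locality-sensitive hashing on
  non-overlapping 6-mer tiles, exact spacer-match filtering, and
  Needleman–Wunsch genotyping (match +1, mismatch −1, gap open −5, gap
  extend 0, free start gaps) restricted to A→G, C→T, C→G and C→A calls in
  the protospacer window −9..20 (position 0 immediately upstream of the
  protospacer, PAM at 21–23).
* **Noise-aware quantification** — a batch-effect screen by one-way ANOVA
  at a Bonferroni-corrected family level of 0.005; a two-replicate
  binomial noise filter that keeps a mutation iff
  P(X₁ ≥ k₁)·P(X₂ ≥ k₂) < 0.05 with Xᵢ ~ Binomial(nᵢ, 10⁻³), so low-count
  edits present in both replicates survive; replicate pooling by the
  combined-count MLE Σkᵢ/Σnᵢ; the editing window as the positions with
  ≥ 30% of peak average efficiency; and selectivity as the geometric mean
  over window positions of the C→T : A→G efficiency ratio.
* **Context motifs** — ridge regression (α = 10⁻⁵, unpenalized intercept,
  seeded 80:20 split) of stabilized-logit efficiencies,
  log((x + ε)/(1 + ε − x)) with ε = 0.001, on one-hot context features at
  offsets −3..+3; the held-out Pearson R is the motif confidence.
* **Editor comparison** — total least squares through the origin (both
  efficiencies are measured variables), with the average fold change
  reported as the reciprocal of the slope.
* **A synthetic study generator** — a reduced-scale comprehensive-context
  library plus a parameterized editor model (logistic-additive window and
  context weights, byproduct fractions, a per-read engagement latent that
  couples co-editing, Poisson 300× depth, Q30 errors at 10⁻³, 94/56-nt
  paired reads) whose analytic ground truth (`truth_statistics()`) makes
  every stage verifiable end to end without external data.

## Worked example

Simulate a 60-member library edited by the package's reference selective
cytosine editor (ground-truth window 3–8, selectivity 25) and analyse it:

```r
library(beditlib)

lib   <- build_library(60, seed = 42)
model <- study_models()$cbe
cfg   <- sim_config(n_members = 60, mean_depth = 300, rng_seed = 43)

reads <- simulate_run(lib, model, cfg)
asg   <- assign_and_genotype(reads, lib)
asg
#> <be_assignment> 35830 read pairs: 35125 genotyped, 0 discarded (quality), 705 unassigned

quant <- quantify(asg)
quant
#> <be_quant>
#>   editing window: 3..8
#>   selectivity (C>T / A>G): 24.59
#>   average efficiency (any C): 0.6133
#>   co-editing P(A>G | C>T): 0.02681
```

The unassigned 2% are reads whose sequenced spacer no longer matches any
candidate exactly — the expected casualty rate of a 20-nt exact-match
filter at a 10⁻³ per-base error rate. The pipeline recovers the editor's
ground-truth window exactly and its selectivity within sampling error;
`autoplot(quant)` draws the per-position profile with the window shaded,
and `tidy()`/`glance()` methods expose motif (`fit_motif()`) and TLS
(`tls_fit()`) fits as tibbles.

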