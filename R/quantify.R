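#' Probability that replicate mutation counts arise from sequencing noise
#'
#' Joint tail probability of observing at least the given mutation counts in
#' both replicates under a per-read noise model: with
#' \eqn{X_i \sim Binomial(n_i, p)},
#' returns \eqn{P(X_1 \ge k_1) \cdot P(X_2 \ge k_2)}. A mutation is retained
#' by the noise filter iff this probability is below `keep_threshold`, so a
#' low-count mutation present across both replicates can survive even when
#' each replicate alone looks like noise.
#'
#' @param k1,n1,k2,n2 Mutation and total read counts in the two replicates
#'   (vectorized).
#' @param error_rate Noise rate parameter `p` (default 1e-3, Q30).
#' @return Numeric vector of joint tail probabilities.
#' @examples
#' noise_probability(1, 100, 0, 100) # ~0.095, not kept at 0.05
#' noise_probability(1, 100, 1, 100) # ~0.009, kept
#' @export
noise_probability <- function(k1, n1, k2, n2, error_rate = 1e-3) {
  if (any(k1 > n1) || any(k2 > n2)) abort("mutation count exceeds read count.")
  if (any(c(k1, n1, k2, n2) < 0)) abort("counts must be non-negative.")
  pbinom(k1 - 1, n1, error_rate, lower.tail = FALSE) *
    pbinom(k2 - 1, n2, error_rate, lower.tail = FALSE)
}

#' Two-replicate binomial noise filter
#'
#' Applies [noise_probability()] to every mutation of a counts table and
#' flags the ones retained. With more than two replicates the tail product
#' extends over all of them.
#'
#' @param counts A counts table (see [write_counts()] for the schema).
#' @param error_rate Per-base noise rate (default 1e-3).
#' @param keep_threshold Retention threshold on the joint tail probability
#'   (default 0.05).
#' @return Tibble with one row per `(member_id, position, ref_base,
#'   alt_base)` and columns `noise_p` and `kept`.
#' @export
filter_noise <- function(counts, error_rate = 1e-3, keep_threshold = 0.05) {
  stopifnot(error_rate > 0, error_rate < 1,
            keep_threshold > 0, keep_threshold < 1)
  counts |>
    dplyr::group_by(.data$member_id, .data$position, .data$ref_base,
                    .data$alt_base) |>
    dplyr::summarise(
      noise_p = prod(pbinom(.data$edited_reads - 1, .data$total_reads,
                            .env$error_rate, lower.tail = FALSE)),
      .groups = "drop") |>
    dplyr::mutate(kept = .data$noise_p < keep_threshold)
}

#' Batch-effect screen by one-way ANOVA
#'
#' Tests, for every `(position, class)`, whether member-level mutation
#' frequencies differ across batches (replicates by default) with a
#' classical one-way ANOVA F-test, and flags hypotheses significant at the
#' Bonferroni-corrected family level `family_alpha / m`, `m` being the
#' number of testable hypotheses. Hypotheses with fewer than two groups of
#' two observations are reported untestable; groups that are all identical
#' return p = 1 by convention.
#'
#' @param counts A counts table; the `replicate` column provides the batch
#'   labels.
#' @param family_alpha Family-wise significance level (default 0.005).
#' @return Tibble `(position, class, p_value, testable, flagged)`.
#' @export
batch_anova <- function(counts, family_alpha = 0.005) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  freqs <- counts |>
    dplyr::filter(.data$total_reads > 0) |>
    dplyr::mutate(freq = .data$edited_reads / .data$total_reads,
                  class = class_label(.data$ref_base, .data$alt_base))
  res <- freqs |>
    dplyr::group_by(.data$position, .data$class) |>
    dplyr::summarise(p_value = one_way_p(.data$freq, .data$replicate),
                     .groups = "drop") |>
    dplyr::mutate(testable = !is.na(.data$p_value))
  m <- sum(res$testable)
  res |>
    dplyr::mutate(flagged = .data$testable &
                    .data$p_value < family_alpha / max(m, 1L))
}

# classical one-way ANOVA p; NA when untestable, 1 when all values equal
one_way_p <- function(x, g) {
  g <- as.factor(g)
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) return(NA_real_)
  if (max(x) == min(x)) return(1)
  # zero within-group variance with differing group means: F = Inf, p = 0
  within_var <- tapply(x, g, stats::var)
  if (all(within_var == 0)) return(0)
  stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
}

#' Pool mutation counts across replicates
#'
#' Combines replicate counts per mutation by summing reads:
#' efficiency = sum(k_i) / sum(n_i), the maximum-likelihood estimate of the
#' per-read editing rate (not the mean of per-replicate ratios). Mutations
#' with zero pooled coverage get a missing efficiency, never 0.
#'
#' @param counts A counts table.
#' @return Tibble `(member_id, position, ref_base, alt_base, class,
#'   edited_reads, total_reads, efficiency)`.
#' @export
pool_replicates <- function(counts) {
  counts |>
    dplyr::group_by(.data$member_id, .data$position, .data$ref_base,
                    .data$alt_base) |>
    dplyr::summarise(edited_reads = sum(.data$edited_reads),
                     total_reads = sum(.data$total_reads),
                     .groups = "drop") |>
    dplyr::mutate(
      class = class_label(.data$ref_base, .data$alt_base),
      efficiency = dplyr::if_else(.data$total_reads > 0,
                                  .data$edited_reads / .data$total_reads,
                                  NA_real_))
}

#' Per-position efficiency profile
#'
#' Averages pooled member-level efficiencies per position and substitution
#' class. The mean is unweighted over the members whose reference carries
#' the substrate base at that position (members without the base at a
#' position do not dilute it).
#'
#' @param pooled Pooled counts from [pool_replicates()].
#' @return Profile tibble `(position, class, efficiency, n_members)` of
#'   class `efficiency_profile`.
#' @export
efficiency_profile <- function(pooled) {
  out <- pooled |>
    dplyr::filter(!is.na(.data$efficiency)) |>
    dplyr::group_by(.data$position, .data$class) |>
    dplyr::summarise(efficiency = mean(.data$efficiency),
                     n_members = dplyr::n(), .groups = "drop")
  class(out) <- c("efficiency_profile", class(out))
  out
}

#' Editing window of a profile
#'
#' The editing window is the set of positions whose average editing
#' efficiency is at least `peak_fraction` (default 30%) of the peak average
#' efficiency for the chosen class. The window is reported as-is and need
#' not be contiguous; it is invariant to rescaling the profile.
#'
#' @param profile A profile tibble (position, class, efficiency).
#' @param class Substitution class defining the window (default `"C>T"`).
#' @param peak_fraction Threshold as a fraction of the peak (default 0.30).
#' @return Sorted integer vector of window positions.
#' @export
editing_window <- function(profile, class = "C>T", peak_fraction = 0.30) {
  stopifnot(peak_fraction > 0, peak_fraction <= 1)
  p <- profile[profile$class == class & !is.na(profile$efficiency), ]
  if (nrow(p) == 0) abort("profile has no defined efficiencies for this class.")
  peak <- max(p$efficiency)
  if (peak == 0) {
    warn("all efficiencies are zero; the editing window is empty.")
    return(integer())
  }
  sort(p$position[p$efficiency >= peak_fraction * peak])
}

#' Selectivity of cytosine over adenine editing
#'
#' Geometric mean, over the window positions, of the ratio of the
#' numerator-class to denominator-class efficiency (default C>T over A>G):
#' \deqn{\exp\left(\mathrm{mean}_{pos}\,
#'   \ln\frac{e_{C>T}(pos)}{e_{A>G}(pos)}\right)}
#' Window positions where the denominator efficiency is zero or undefined
#' are excluded with a warning (the log ratio is undefined there); if no
#' usable position remains the selectivity is `NA`.
#'
#' @param profile A profile tibble.
#' @param window Integer vector of window positions.
#' @param num_class,den_class Numerator and denominator classes.
#' @return The geometric-mean selectivity (scalar).
#' @export
selectivity <- function(profile, window, num_class = "C>T",
                        den_class = "A>G") {
  if (length(window) == 0) abort("`window` must be non-empty.")
  wide <- profile |>
    dplyr::filter(.data$position %in% window,
                  .data$class %in% c(num_class, den_class)) |>
    dplyr::select("position", "class", "efficiency") |>
    tidyr::pivot_wider(names_from = "class", values_from = "efficiency")
  num <- wide[[num_class]] %||% rep(NA_real_, nrow(wide))
  den <- wide[[den_class]] %||% rep(NA_real_, nrow(wide))
  usable <- !is.na(num) & !is.na(den) & den > 0 & num > 0
  if (sum(!usable) > 0) {
    warn(sprintf("%d window position(s) excluded from the selectivity (zero or undefined ratio).",
                 sum(!usable)))
  }
  if (!any(usable)) return(NA_real_)
  exp(mean(log(num[usable] / den[usable])))
}

# retained read-level calls: calls whose mutation survived the noise filter
retained_calls <- function(calls, noise) {
  kept <- noise[noise$kept, c("member_id", "position", "ref_base", "alt_base")]
  dplyr::inner_join(calls, kept,
                    by = c("member_id", "position", "ref_base", "alt_base"))
}

#' Average editing efficiency over a library
#'
#' Per member, the fraction of genotyped reads (pooled across replicates)
#' carrying at least one retained call of the specified class(es) within
#' the window; the reported value is the unweighted mean of the member
#' fractions. Members with zero genotyped reads are excluded with a
#' warning.
#'
#' @param calls Read-level calls (from [assign_and_genotype()], optionally
#'   noise-filtered).
#' @param read_totals Genotyped reads per member and replicate.
#' @param classes Substitution classes counting as the specified outcome
#'   (default: any C editing).
#' @param window Editing window bounds.
#' @return Scalar average editing efficiency.
#' @export
average_editing_efficiency <- function(calls, read_totals,
                                       classes = c("C>T", "C>G", "C>A"),
                                       window = c(-9L, 20L)) {
  totals <- read_totals |>
    dplyr::group_by(.data$member_id) |>
    dplyr::summarise(n_reads = sum(.data$n_reads), .groups = "drop")
  if (any(totals$n_reads == 0)) {
    warn("members with zero genotyped reads excluded from the average.")
    totals <- totals[totals$n_reads > 0, ]
  }
  if (nrow(totals) == 0) abort("no members with genotyped reads.")
  edited <- calls |>
    dplyr::filter(class_label(.data$ref_base, .data$alt_base) %in% classes,
                  .data$position >= window[1], .data$position <= window[2]) |>
    dplyr::distinct(.data$member_id, .data$read_id) |>
    dplyr::count(.data$member_id, name = "n_edited")
  totals |>
    dplyr::left_join(edited, by = "member_id") |>
    dplyr::mutate(n_edited = tidyr::replace_na(.data$n_edited, 0L)) |>
    dplyr::summarise(avg = mean(.data$n_edited / .data$n_reads)) |>
    dplyr::pull("avg")
}

#' Conditional co-editing probability
#'
#' Probability of observing at least one edit of `then_classes` (default
#' A>G) in a read given that the read carries at least one edit of
#' `given_classes` (default C>T), across all genotyped reads.
#'
#' @param calls Read-level calls.
#' @param given_classes,then_classes Substitution class sets.
#' @param window Editing window bounds.
#' @return Scalar conditional probability (`NA` when no read carries a
#'   `given_classes` edit).
#' @export
conditional_coediting <- function(calls, given_classes = "C>T",
                                  then_classes = "A>G",
                                  window = c(-9L, 20L)) {
  in_win <- calls |>
    dplyr::filter(.data$position >= window[1], .data$position <= window[2]) |>
    dplyr::mutate(class = class_label(.data$ref_base, .data$alt_base))
  per_read <- in_win |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(has_given = any(.data$class %in% given_classes),
                     has_then = any(.data$class %in% then_classes),
                     .groups = "drop")
  n_given <- sum(per_read$has_given)
  if (n_given == 0) return(NA_real_)
  sum(per_read$has_given & per_read$has_then) / n_given
}

#' ABE:CBE ratio
#'
#' Ratio of the average adenine editing efficiency (A>G) to the average
#' cytosine editing efficiency (C>T), both computed with
#' [average_editing_efficiency()].
#'
#' @inheritParams average_editing_efficiency
#' @return Scalar ratio (`NA` when the cytosine average is zero).
#' @export
abe_cbe_ratio <- function(calls, read_totals, window = c(-9L, 20L)) {
  avg_a <- average_editing_efficiency(calls, read_totals, classes = "A>G",
                                      window = window)
  avg_c <- average_editing_efficiency(calls, read_totals, classes = "C>T",
                                      window = window)
  if (avg_c == 0) return(NA_real_)
  avg_a / avg_c
}

#' Quantify a run end to end
#'
#' Statistical post-processing of an assignment: batch-effect ANOVA screen
#' (flagged hypotheses reported, and optionally dropped), two-replicate
#' binomial noise filter, replicate pooling, per-position efficiency
#' profile, editing window, selectivity, average editing efficiencies,
#' conditional co-editing and the ABE:CBE ratio.
#'
#' @param assignment A `be_assignment` from [assign_and_genotype()].
#' @param error_rate Noise filter rate parameter (default 1e-3).
#' @param keep_threshold Noise filter retention threshold (default 0.05).
#' @param peak_fraction Editing-window threshold (default 0.30).
#' @param family_alpha ANOVA family-wise level (default 0.005).
#' @param window_class Class defining the editing window.
#' @param drop_flagged Drop batch-flagged hypotheses instead of only
#'   reporting them.
#' @param window Editing window bounds.
#' @return A list of class `be_quant` with elements `profile`, `window`,
#'   `selectivity`, `average` (named: `any_c`, `c2t`, `a2g`), `coediting`,
#'   `abe_cbe_ratio`, `noise`, `anova` and `pooled`.
#' @export
quantify <- function(assignment, error_rate = 1e-3, keep_threshold = 0.05,
                     peak_fraction = 0.30, family_alpha = 0.005,
                     window_class = "C>T", drop_flagged = FALSE,
                     window = c(-9L, 20L)) {
  counts <- assignment$counts
  if (nrow(counts) == 0) abort("assignment contains no genotyped reads.")

  anova_res <- batch_anova(counts, family_alpha)
  if (drop_flagged && any(anova_res$flagged)) {
    flagged <- anova_res[anova_res$flagged, c("position", "class")]
    counts <- counts |>
      dplyr::mutate(class = class_label(.data$ref_base, .data$alt_base)) |>
      dplyr::anti_join(flagged, by = c("position", "class")) |>
      dplyr::select(-"class")
  }

  noise <- filter_noise(counts, error_rate, keep_threshold)
  kept_counts <- counts |>
    dplyr::semi_join(noise[noise$kept, ],
                     by = c("member_id", "position", "ref_base", "alt_base"))
  # mutations failing the noise filter contribute zero edited reads but keep
  # their coverage in the denominator
  zeroed <- counts |>
    dplyr::anti_join(noise[noise$kept, ],
                     by = c("member_id", "position", "ref_base", "alt_base")) |>
    dplyr::mutate(edited_reads = 0L)
  pooled <- pool_replicates(dplyr::bind_rows(kept_counts, zeroed))

  profile <- efficiency_profile(pooled)
  win <- editing_window(profile, class = window_class,
                        peak_fraction = peak_fraction)
  sel <- if (length(win)) selectivity(profile, win) else NA_real_

  calls <- retained_calls(assignment$calls, noise)
  avg <- c(
    any_c = average_editing_efficiency(calls, assignment$read_totals,
                                       classes = c("C>T", "C>G", "C>A"),
                                       window = window),
    c2t = average_editing_efficiency(calls, assignment$read_totals,
                                     classes = "C>T", window = window),
    a2g = average_editing_efficiency(calls, assignment$read_totals,
                                     classes = "A>G", window = window))

  structure(list(
    profile = profile, window = win, selectivity = sel, average = avg,
    coediting = conditional_coediting(calls, window = window),
    abe_cbe_ratio = if (avg[["c2t"]] > 0) avg[["a2g"]] / avg[["c2t"]] else NA_real_,
    noise = noise, anova = anova_res, pooled = pooled),
    class = "be_quant")
}

#' @export
print.be_quant <- function(x, ...) {
  cat("<be_quant>\n")
  cat("  editing window:", if (length(x$window)) paste(range(x$window), collapse = "..") else "(empty)", "\n")
  cat("  selectivity (C>T / A>G):", format(x$selectivity, digits = 4), "\n")
  cat("  average efficiency (any C):", format(x$average[["any_c"]], digits = 4), "\n")
  cat("  co-editing P(A>G | C>T):", format(x$coediting, digits = 4), "\n")
  invisible(x)
}
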