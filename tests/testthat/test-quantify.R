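test_that("noise probability reproduces exact binomial tail products", {
  # empty event: nothing observed is always 'noise-consistent'
  expect_equal(noise_probability(0, 100, 0, 100), 1.0)
  # single-replicate count: 1 - 0.999^100
  expect_equal(noise_probability(1, 100, 0, 100), 1 - 0.999^100,
               tolerance = 1e-12)
  # the same low count in both replicates drops below the 5% threshold
  expect_equal(noise_probability(1, 100, 1, 100), (1 - 0.999^100)^2,
               tolerance = 1e-12)
  expect_gt(noise_probability(1, 100, 0, 100), 0.05)
  expect_lt(noise_probability(1, 100, 1, 100), 0.05)
  expect_error(noise_probability(5, 3, 0, 10), "exceeds")
})

test_that("the noise filter keeps cross-replicate mutations", {
  counts <- tibble::tibble(
    member_id = "M1", position = 6L, ref_base = "C", alt_base = "T",
    replicate = c(1L, 2L),
    edited_reads = c(1L, 1L), total_reads = c(100L, 100L))
  nf <- filter_noise(counts)
  expect_true(nf$kept)
  counts$edited_reads <- c(1L, 0L)
  expect_false(filter_noise(counts)$kept)
})

test_that("true edits at depth 300 are retained with high closed-form power", {
  # enumerate K_i ~ Binomial(300, freq) in both replicates; the filter fails
  # a mutation only when both replicates fall at 0 or 1 edited reads
  power_at <- function(freq) {
    k <- 0:80
    pk <- dbinom(k, 300, freq)
    kept <- outer(k, k, function(k1, k2)
      noise_probability(k1, 300, k2, 300) < 0.05)
    sum(outer(pk, pk) * kept)
  }
  p_fail_1pct <- (dbinom(0, 300, 0.01) + dbinom(1, 300, 0.01))^2
  expect_equal(power_at(0.01), 1 - p_fail_1pct, tolerance = 1e-10)
  expect_gt(power_at(0.01), 0.95)
  expect_gt(power_at(0.02), 0.999)
})

test_that("batch ANOVA matches the closed-form F test and conventions", {
  mk_counts <- function(freqs1, freqs2, n = 1000L) {
    tibble::tibble(
      member_id = rep(sprintf("M%d", seq_along(freqs1)), 2),
      replicate = rep(1:2, each = length(freqs1)),
      position = 6L, ref_base = "C", alt_base = "T",
      edited_reads = as.integer(round(c(freqs1, freqs2) * n)),
      total_reads = n)
  }
  # overlapping groups: F from the standard closed form, not flagged
  g1 <- c(0.10, 0.11, 0.09); g2 <- c(0.10, 0.09, 0.11)
  res <- batch_anova(mk_counts(g1, g2))
  x <- c(g1, g2); g <- rep(1:2, each = 3)
  msb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2)) / 1
  msw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / 4
  p_manual <- pf(msb / msw, 1, 4, lower.tail = FALSE)
  expect_equal(res$p_value, p_manual, tolerance = 1e-10)
  expect_false(res$flagged)

  # separated constant groups: within-group variance 0, flagged
  res2 <- batch_anova(mk_counts(c(0.10, 0.10, 0.10), c(0.50, 0.50, 0.50)))
  expect_equal(res2$p_value, 0)
  expect_true(res2$flagged)

  # identical constant value everywhere: p = 1 by convention
  res3 <- batch_anova(mk_counts(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2)))
  expect_equal(res3$p_value, 1)
  expect_false(res3$flagged)

  # a single group is untestable, never flagged
  one <- mk_counts(g1, g2)[1:3, ]
  res4 <- batch_anova(one)
  expect_true(is.na(res4$p_value))
  expect_false(res4$flagged)
})

test_that("replicate pooling is the combined-count MLE", {
  counts <- tibble::tibble(
    member_id = "M1", position = 6L, ref_base = "C", alt_base = "T",
    replicate = 1:2, edited_reads = c(10L, 20L), total_reads = c(100L, 100L))
  expect_equal(pool_replicates(counts)$efficiency, 0.15)
  # pooling is not the mean of per-replicate ratios
  counts$edited_reads <- c(5L, 0L); counts$total_reads <- c(10L, 990L)
  expect_equal(pool_replicates(counts)$efficiency, 0.005)
  # replicate order is irrelevant
  expect_equal(pool_replicates(counts[2:1, ])$efficiency, 0.005)
  # zero edits pool to zero; zero coverage pools to missing, never 0
  counts$edited_reads <- c(0L, 0L); counts$total_reads <- c(50L, 50L)
  expect_equal(pool_replicates(counts)$efficiency, 0)
  counts$total_reads <- c(0L, 0L)
  expect_true(is.na(pool_replicates(counts)$efficiency))
})

test_that("the editing window is the >= 30%-of-peak position set", {
  prof <- tibble::tibble(position = 2:4, class = "C>T",
                         efficiency = c(0.05, 0.35, 0.10))
  expect_equal(editing_window(prof), 3L)
  # scale invariance
  prof2 <- dplyr::mutate(prof, efficiency = efficiency * 0.5)
  expect_equal(editing_window(prof2), 3L)
  # a flat nonzero profile puts every position in the window
  flat <- tibble::tibble(position = 1:5, class = "C>T", efficiency = 0.2)
  expect_equal(editing_window(flat), 1:5)
  # adding a sub-threshold position never changes the window
  grown <- dplyr::bind_rows(prof, tibble::tibble(position = 9L, class = "C>T",
                                                 efficiency = 0.01))
  expect_equal(editing_window(grown), 3L)
  # all-zero profile: empty window with a warning
  zero <- dplyr::mutate(flat, efficiency = 0)
  expect_warning(w <- editing_window(zero), "empty")
  expect_length(w, 0)
})

test_that("selectivity is the geometric-mean window ratio with bounds", {
  prof <- tibble::tibble(position = c(1, 2, 1, 2),
                         class = rep(c("C>T", "A>G"), each = 2),
                         efficiency = c(0.4, 0.4, 0.01, 0.04))
  expect_equal(selectivity(prof, 1:2), sqrt(40 * 10))
  # one-position window reduces to the plain ratio
  expect_equal(selectivity(prof, 1), 40)
  # identical profiles give 1
  sym <- dplyr::mutate(prof, efficiency = rep(c(0.3, 0.2), 2))
  expect_equal(selectivity(sym, 1:2), 1)
  # bounded by the min and max position ratio (property, random profiles)
  withr::with_seed(11, for (i in 1:50) {
    k <- sample(2:6, 1)
    e_c <- runif(k, 0.01, 0.9); e_a <- runif(k, 0.001, 0.4)
    p <- tibble::tibble(position = rep(seq_len(k), 2),
                        class = rep(c("C>T", "A>G"), each = k),
                        efficiency = c(e_c, e_a))
    s <- selectivity(p, seq_len(k))
    expect_gte(s, min(e_c / e_a) - 1e-12)
    expect_lte(s, max(e_c / e_a) + 1e-12)
  })
  # zero-denominator positions are excluded with a warning
  prof$efficiency[3] <- 0
  expect_warning(s <- selectivity(prof, 1:2), "excluded")
  expect_equal(s, 10)
})

test_that("average efficiency is the unweighted member mean of read fractions", {
  totals <- tibble::tibble(member_id = c("M1", "M2"), replicate = 1L,
                           n_reads = c(10L, 10L))
  calls <- tibble::tibble(
    read_id = c(sprintf("a%d", 1:5), "b1"),
    member_id = c(rep("M1", 5), "M2"), replicate = 1L,
    position = 6L, ref_base = "C", alt_base = "T")
  expect_equal(average_editing_efficiency(calls, totals), 0.30)
  # no edits at all
  expect_equal(average_editing_efficiency(calls[0, ], totals), 0)
  # zero-read members are excluded with a warning
  totals2 <- dplyr::bind_rows(totals,
                              tibble::tibble(member_id = "M3", replicate = 1L,
                                             n_reads = 0L))
  expect_warning(avg <- average_editing_efficiency(calls, totals2), "zero")
  expect_equal(avg, 0.30)
})

test_that("conditional co-editing is a read-level conditional fraction", {
  mk_calls <- function(n_c, n_both) {
    c_only <- tibble::tibble(read_id = sprintf("c%d", seq_len(n_c)),
                             member_id = "M1", replicate = 1L, position = 6L,
                             ref_base = "C", alt_base = "T")
    both <- tibble::tibble(read_id = sprintf("c%d", seq_len(n_both)),
                           member_id = "M1", replicate = 1L, position = 8L,
                           ref_base = "A", alt_base = "G")
    dplyr::bind_rows(c_only, both)
  }
  expect_equal(conditional_coediting(mk_calls(10, 4)), 0.4)
  expect_equal(conditional_coediting(mk_calls(10, 0)), 0)
  expect_true(is.na(conditional_coediting(mk_calls(0, 0))))
})

test_that("quantify recovers model truth on a small simulated run", {
  lib <- build_library(60, seed = 61)
  model <- study_models()$cbe
  truth <- truth_statistics(model, lib)
  cfg <- sim_config(n_members = 60, mean_depth = 150, rng_seed = 62)
  asg <- assign_and_genotype(simulate_run(lib, model, cfg), lib)
  q <- suppressWarnings(quantify(asg))
  expect_equal(q$window, truth$window)
  expect_lt(abs(q$selectivity - truth$selectivity) / truth$selectivity, 0.2)
  expect_lt(abs(q$average[["any_c"]] - truth$average[["any_c"]]), 0.02)
  # no batch effects are simulated, so nothing should be flagged
  expect_false(any(q$anova$flagged))
})
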