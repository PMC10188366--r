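test_that("engage_prob = 0 leaves every read identical to the reference", {
  member <- manual_member()
  model <- editor_model(window_c = window_from_rates(c("6" = 0.9)),
                        engage_prob = 0)
  withr::with_seed(1, {
    oc <- simulate_outcomes(member, model, depth = 50)
  })
  expect_identical(unique(oc), member$cassette)
})

test_that("conversion frequency matches the site probability (binomial check)", {
  member <- manual_member()
  # one active site at position 6, logistic(...) = 0.5, no byproducts
  model <- editor_model(window_c = window_from_rates(c("6" = 0.5)))
  depth <- 1e4
  withr::with_seed(2, oc <- simulate_outcomes(member, model, depth))
  idx <- beditlib:::cassette_index(6, member$protospacer_start)
  frac_t <- mean(substr(oc, idx, idx) == "T")
  se <- sqrt(0.5 * 0.5 / depth)
  expect_lt(abs(frac_t - 0.5), 3 * se)
  # no edits anywhere else
  ref_rest <- paste0(substr(member$cassette, 1, idx - 1),
                     substr(member$cassette, idx + 1, nchar(member$cassette)))
  oc_rest <- paste0(substr(oc, 1, idx - 1), substr(oc, idx + 1, nchar(oc)))
  expect_true(all(oc_rest == ref_rest))
})

test_that("latent engagement couples edits across sites", {
  # choose a member and force two C sites to convert with probability 1
  member <- manual_member()
  st <- site_table(member)
  cpos <- unique(st$position[st$ref_base == "C"])[1:2]
  rates <- stats::setNames(c(1, 1), as.character(cpos))
  model <- editor_model(window_c = window_from_rates(rates), engage_prob = 0.5)
  withr::with_seed(3, oc <- simulate_outcomes(member, model, depth = 2000))
  idx <- beditlib:::cassette_index(cpos, member$protospacer_start)
  e1 <- substr(oc, idx[1], idx[1]) != "C"
  e2 <- substr(oc, idx[2], idx[2]) != "C"
  expect_equal(sum(xor(e1, e2)), 0)          # never exactly one
  expect_lt(abs(mean(e1 & e2) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("byproduct fractions split C conversions", {
  member <- manual_member()
  model <- editor_model(window_c = window_from_rates(c("6" = 1)),
                        byproduct_fracs = c(G = 0.3, A = 0.2))
  withr::with_seed(4, oc <- simulate_outcomes(member, model, depth = 5000))
  idx <- beditlib:::cassette_index(6, member$protospacer_start)
  alt <- substr(oc, idx, idx)
  expect_lt(abs(mean(alt == "G") - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  expect_lt(abs(mean(alt == "A") - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  expect_equal(sort(unique(alt)), c("A", "G", "T"))
})

test_that("sequencing errors occur at the configured rate", {
  member <- manual_member()
  model <- editor_model(engage_prob = 0, seq_error_rate = 1e-3)
  n <- 11000  # > 1e6 simulated bases on the forward read
  withr::with_seed(5, {
    reads <- simulate_reads(rep(member$cassette, n), member, model)
  })
  ref <- strsplit(member$cassette, "")[[1]][1:94]
  obs <- matrix(unlist(strsplit(reads$fwd_seq, "")), nrow = 94)
  err <- mean(obs != ref)
  se <- sqrt(1e-3 * (1 - 1e-3) / (n * 94))
  expect_lt(abs(err - 1e-3), 3 * se)
})

test_that("error-free reads are exact substrings that pass Q28", {
  member <- manual_member()
  model <- noiseless(editor_model(engage_prob = 0))
  reads <- simulate_reads(rep(member$cassette, 5), member, model)
  expect_true(all(reads$fwd_seq == substr(member$cassette, 1, 94)))
  expect_true(all(reads$rev_seq == paste0(beditlib:::rev_scaffold_5(),
                                          member$spacer,
                                          beditlib:::rev_scaffold_3())))
  qf <- quality_filter(dplyr::mutate(reads, replicate = 1L),
                       read_layout(member))
  expect_true(all(qf$qc_keep))
})

test_that("q_fail_frac = 1 makes every read fail the Q28 filter", {
  member <- manual_member()
  model <- editor_model(engage_prob = 0, seq_error_rate = 0, q_fail_frac = 1)
  withr::with_seed(6, reads <- simulate_reads(rep(member$cassette, 10), member, model))
  qf <- quality_filter(dplyr::mutate(reads, replicate = 1L),
                       read_layout(member))
  expect_false(any(qf$qc_keep))
})

test_that("read geometry violations raise errors", {
  member <- manual_member()
  model <- editor_model()
  expect_error(simulate_reads(character(), member, model), "non-empty")
  expect_error(simulate_reads(member$cassette, member, model, fwd_len = 200),
               "shorter")
})

test_that("truth_statistics matches a Monte-Carlo estimate", {
  lib <- tiny_library(6, seed = 55)
  models <- study_models()
  model <- models$cbe
  truth <- truth_statistics(model, lib)
  depth <- 4000
  est <- withr::with_seed(7, {
    purrr::map(seq_len(nrow(lib)), function(i) {
      member <- lib[i, ]
      oc <- simulate_outcomes(member, model, depth)
      st <- dplyr::distinct(site_table(member), member_id, position, ref_base)
      idx <- beditlib:::cassette_index(st$position, member$protospacer_start)
      alt <- ifelse(st$ref_base == "A", "G", "T")
      tibble::tibble(position = st$position,
                     class = paste0(st$ref_base, ">", alt),
                     frac = purrr::map2_dbl(idx, alt, function(j, a)
                       mean(substr(oc, j, j) == a)))
    }) |> dplyr::bind_rows() |>
      dplyr::group_by(position, class) |>
      dplyr::summarise(frac = mean(frac), .groups = "drop")
  })
  cmp <- dplyr::inner_join(truth$profile, est, by = c("position", "class"))
  # conservative: single-member binomial s.e. at the truth rate
  se <- sqrt(pmax(cmp$efficiency * (1 - cmp$efficiency), 1e-4) / depth)
  expect_true(all(abs(cmp$efficiency - cmp$frac) < 4 * se))
  # the worked selectivity example: C (0.4, 0.4) vs A (0.01, 0.04)
  prof <- tibble::tibble(position = c(1, 2, 1, 2),
                         class = c("C>T", "C>T", "A>G", "A>G"),
                         efficiency = c(0.4, 0.4, 0.01, 0.04))
  expect_equal(selectivity(prof, window = c(1, 2)), sqrt(40 * 10))
})

test_that("simulation output is byte-identical under a fixed seed", {
  lib <- tiny_library(4, seed = 9)
  model <- study_models()$cbe
  cfg <- sim_config(n_members = 4, mean_depth = 30, rng_seed = 13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  # small library: some window positions lack A sites, which the truth
  # selectivity warns about
  suppressWarnings(simulate_fastq(lib, model, cfg, d1))
  suppressWarnings(simulate_fastq(lib, model, cfg, d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # every read maps to exactly one ground-truth member through its id
  reads <- simulate_run(lib, model, cfg)
  id_member <- sub(":.*$", "", reads$read_id)
  expect_identical(id_member, reads$member_id)
  expect_true(all(id_member %in% lib$member_id))
})
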