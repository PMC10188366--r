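test_that("quality filter applies only to the spacer and window regions", {
  member <- manual_member()
  layout <- read_layout(member)
  reads <- manual_reads(member)

  expect_true(quality_filter(reads, layout)$qc_keep)  # all Q30

  # one spacer base at Q27 discards the pair
  rq <- reads$rev_qual
  bad_rev <- subst_at(rq, layout$spacer_start + 3L, rawToChar(as.raw(27 + 33)))
  expect_false(quality_filter(dplyr::mutate(reads, rev_qual = bad_rev),
                              layout)$qc_keep)

  # one window base at Q27 on the forward read discards the pair
  fq <- subst_at(reads$fwd_qual, layout$fwd_window_start,
                 rawToChar(as.raw(27 + 33)))
  expect_false(quality_filter(dplyr::mutate(reads, fwd_qual = fq),
                              layout)$qc_keep)

  # a Q10 base outside both regions is ignored
  fq_out <- subst_at(reads$fwd_qual, 1L, rawToChar(as.raw(10 + 33)))
  rq_out <- subst_at(reads$rev_qual, 1L, rawToChar(as.raw(10 + 33)))
  expect_true(quality_filter(dplyr::mutate(reads, fwd_qual = fq_out,
                                           rev_qual = rq_out),
                             layout)$qc_keep)

  # reads too short for the regions are discarded, not fatal
  short <- dplyr::mutate(reads, fwd_seq = substr(fwd_seq, 1, 10),
                         fwd_qual = substr(fwd_qual, 1, 10))
  expect_false(quality_filter(short, layout)$qc_keep)
})

test_that("kmer index tiles the window deterministically", {
  lib <- tiny_library(6)
  idx1 <- kmer_index(lib)
  idx2 <- kmer_index(lib)
  expect_identical(as.data.frame(idx1), as.data.frame(idx2))
  # every member contributes floor(30 / 6) = 5 tiles
  expect_equal(unname(table(idx1$member_id)), rep(5L, 6),
               ignore_attr = TRUE)
  # the tiles reconstruct the window sequence
  m1 <- idx1[idx1$member_id == lib$member_id[1], ]
  win <- substr(lib$cassette[1],
                attr(idx1, "layout")$fwd_window_start,
                attr(idx1, "layout")$fwd_window_start + 29L)
  expect_identical(paste(m1$kmer[order(m1$tile)], collapse = ""), win)
})

test_that("a read matching a member ranks it first with maximal tile count", {
  lib <- tiny_library(6)
  idx <- kmer_index(lib)
  cand <- nominate_candidates(lib$cassette[3], idx)
  expect_identical(cand$member_id[1], lib$member_id[3])
  expect_equal(cand$shared_tiles[1], 5L)
})

test_that("any single substitution still nominates the true member", {
  # exhaustive: every window position x every alternative base
  lib <- tiny_library(6)
  idx <- kmer_index(lib)
  layout <- attr(idx, "layout")
  read0 <- lib$cassette[2]
  for (off in seq_len(30L)) {
    i <- layout$fwd_window_start + off - 1L
    for (b in other_bases(substr(read0, i, i))) {
      cand <- nominate_candidates(subst_at(read0, i, b), idx)
      expect_true(lib$member_id[2] %in% cand$member_id,
                  info = sprintf("pos %d -> %s", off, b))
    }
  }
})

test_that("a read sharing no tiled 6-mer with any member is unassigned", {
  lib <- tiny_library(6)
  idx <- kmer_index(lib)
  probe <- strrep("A", 94)
  # verified counterexample: no indexed tile is AAAAAA
  expect_false(any(idx$kmer == strrep("A", 6)))
  expect_equal(nrow(nominate_candidates(probe, idx)), 0)
})

test_that("spacer filtering requires an exact match", {
  lib <- tiny_library(4)
  idx <- kmer_index(lib)
  cand <- nominate_candidates(lib$cassette[1], idx)
  keep <- spacer_filter(cand, lib$spacer[1], lib)
  expect_identical(keep$member_id, lib$member_id[1])

  mut <- subst_at(lib$spacer[1], 10L, other_bases(substr(lib$spacer[1], 10, 10))[1])
  expect_equal(nrow(spacer_filter(cand, mut, lib)), 0)

  # two candidates, only one spacer-matching
  two <- tibble::tibble(read = 1L, member_id = lib$member_id[1:2],
                        shared_tiles = c(5L, 1L))
  kept <- spacer_filter(two, lib$spacer[2], lib)
  expect_identical(kept$member_id, lib$member_id[2])
})

test_that("genotyping calls only tracked classes inside the window", {
  member <- manual_member()
  # an unedited read yields no calls
  g0 <- genotype(member$cassette, member)
  expect_equal(nrow(g0$calls), 0)
  expect_equal(g0$score, nchar(member$cassette))

  # C>T at protospacer position 6 yields exactly one call
  i6 <- beditlib:::cassette_index(6, member$protospacer_start)
  g1 <- genotype(subst_at(member$cassette, i6, "T"), member)
  expect_equal(as.data.frame(g1$calls),
               data.frame(position = 6L, ref_base = "C", alt_base = "T"))

  # an untracked class (here: anything at a G/T reference) and a mutation
  # outside the window yield no calls
  st <- site_table(member)
  gt_idx <- setdiff(beditlib:::cassette_index(-9:20, member$protospacer_start),
                    beditlib:::cassette_index(unique(st$position),
                                              member$protospacer_start))[1]
  read <- subst_at(member$cassette, gt_idx, "A")
  i25 <- beditlib:::cassette_index(25, member$protospacer_start)
  if (substr(member$cassette, i25, i25) != "T") read <- subst_at(read, i25, "T")
  g2 <- genotype(read, member)
  expect_equal(nrow(g2$calls), 0)

  # N never produces a call
  g3 <- genotype(subst_at(member$cassette, i6, "N"), member)
  expect_equal(nrow(g3$calls), 0)
})

test_that("error-free runs reproduce the simulated edit matrix exactly", {
  lib <- tiny_library(5, seed = 21)
  model <- noiseless(study_models()$cbe)
  cfg <- sim_config(n_members = 5, mean_depth = 60, rng_seed = 3)
  reads <- simulate_run(lib, model, cfg)
  asg <- assign_and_genotype(reads, lib)

  expect_equal(asg$report$kept, nrow(reads))
  expect_equal(asg$report$discarded + asg$report$unassigned, 0)
  kept <- asg$read_log[asg$read_log$status == "kept", ]
  expect_true(all(kept$member_id == kept$true_member))

  # independent oracle: diff the error-free reads against the references
  truth_counts <- purrr::map(seq_len(nrow(reads)), function(r) {
    member <- lib[lib$member_id == reads$member_id[r], ]
    st <- dplyr::distinct(site_table(member), position, ref_base)
    idx <- beditlib:::cassette_index(st$position, member$protospacer_start)
    obs <- substring(reads$fwd_seq[r], idx, idx)
    hit <- obs != st$ref_base
    if (!any(hit)) return(NULL)
    tibble::tibble(member_id = member$member_id,
                   replicate = reads$replicate[r],
                   position = st$position[hit], ref_base = st$ref_base[hit],
                   alt_base = obs[hit])
  }) |> dplyr::bind_rows() |>
    dplyr::count(member_id, replicate, position, ref_base, alt_base,
                 name = "edited_reads")
  got <- asg$counts[asg$counts$edited_reads > 0, ]
  expect_equal(as.data.frame(got[names(truth_counts)]),
               as.data.frame(truth_counts))

  # totals equal the genotyped read count per member and replicate
  tot <- dplyr::count(reads, member_id, replicate)
  chk <- dplyr::distinct(asg$counts, member_id, replicate, total_reads) |>
    dplyr::inner_join(tot, by = c("member_id", "replicate"))
  expect_true(all(chk$total_reads == chk$n))
})

test_that("degenerate inputs give empty tables and full accounting", {
  lib <- tiny_library(3)
  empty <- assign_and_genotype(
    tibble::tibble(read_id = character(), fwd_seq = character(),
                   fwd_qual = character(), rev_seq = character(),
                   rev_qual = character()), lib)
  expect_equal(empty$report$total, 0)
  expect_equal(nrow(empty$counts), 0)

  model <- editor_model(engage_prob = 0, seq_error_rate = 0, q_fail_frac = 1)
  cfg <- sim_config(n_members = 3, mean_depth = 20, rng_seed = 5)
  reads <- simulate_run(lib, model, cfg)
  asg <- assign_and_genotype(reads, lib)
  expect_equal(asg$report$discarded, nrow(reads))
  expect_equal(asg$report$kept, 0)
  expect_equal(nrow(asg$counts), 0)
})

test_that("read accounting is conserved on noisy runs", {
  lib <- tiny_library(6, seed = 41)
  model <- study_models()$cbe
  model$q_fail_frac <- 0.002
  cfg <- sim_config(n_members = 6, mean_depth = 80, rng_seed = 8)
  reads <- simulate_run(lib, model, cfg)
  asg <- assign_and_genotype(reads, lib)
  r <- asg$report
  expect_equal(r$kept + r$discarded + r$unassigned, r$total)
  expect_equal(r$total, nrow(reads))
  expect_gt(r$discarded, 0)
  # assignment recovery: kept reads overwhelmingly map to their true member
  kept <- asg$read_log[asg$read_log$status == "kept", ]
  expect_gte(mean(kept$member_id == kept$true_member), 0.999)
})
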