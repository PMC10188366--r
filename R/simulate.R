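# fixed scaffold flanks of the spacer-side (reverse) read; the 20-nt spacer
# sits between them at offset 18, giving the 56-nt read geometry
rev_scaffold_5 <- function() "GTTTTAGAGCTAGAAATA"
rev_scaffold_3 <- function() "GCAAGTTAAAATAAGGCT"

#' Simulation run configuration
#'
#' Study conditions for a simulated library experiment: number of members,
#' biological replicates, mean per-member read depth (the realized depth per
#' member and replicate is Poisson-distributed around it), paired read
#' lengths (94-nt forward over the target cassette, 56-nt reverse over the
#' spacer) and the RNG seed.
#'
#' @param n_members Number of library members.
#' @param replicates Number of biological replicates (default 2).
#' @param mean_depth Mean reads per member per replicate (default 300).
#' @param fwd_len,rev_len Read lengths (defaults 94 and 56).
#' @param rng_seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_members = 200L, replicates = 2L, mean_depth = 300,
                       fwd_len = 94L, rev_len = 56L, rng_seed = 1L) {
  stopifnot(n_members >= 1, replicates >= 1, mean_depth > 0,
            fwd_len >= 1, rev_len >= 1)
  structure(list(n_members = as.integer(n_members),
                 replicates = as.integer(replicates),
                 mean_depth = mean_depth,
                 fwd_len = as.integer(fwd_len),
                 rev_len = as.integer(rev_len),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# uniform substitution errors at `rate` per base; equal-length sequences
apply_seq_errors <- function(seqs, rate) {
  if (length(seqs) == 0 || rate <= 0) return(seqs)
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  idx <- which(runif(length(chars)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(chars[idx], bases)
    cur[is.na(cur)] <- 1L  # N treated as A for the error offset
    chars[idx] <- bases[(cur + sample.int(3L, length(idx), replace = TRUE) - 1L) %% 4L + 1L]
  }
  substring(paste(chars, collapse = ""), (seq_along(seqs) - 1L) * len + 1L,
            seq_along(seqs) * len)
}

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

# Phred+33 quality strings: q_default everywhere, a q_fail_frac fraction of
# bases demoted to q_fail
make_quals <- function(n, len, q_default, q_fail_frac, q_fail) {
  base <- strrep(phred_char(q_default), len)
  out <- rep(base, n)
  if (q_fail_frac > 0 && n > 0) {
    chars <- rep(phred_char(q_default), n * len)
    idx <- which(runif(n * len) < q_fail_frac)
    chars[idx] <- phred_char(q_fail)
    out <- substring(paste(chars, collapse = ""), (seq_len(n) - 1L) * len + 1L,
                     seq_len(n) * len)
  }
  out
}

#' Simulate editing outcomes for one library member
#'
#' Draws `depth` edited cassette sequences under the editor model: each read
#' is engaged with probability `engage_prob`; in engaged reads every C and A
#' in the editing window converts independently with its site probability
#' (logistic in the model's additive log-odds), C conversions realizing as
#' C>G / C>A with the byproduct fractions and C>T otherwise. Non-engaged
#' reads are returned unedited; nothing outside the window is ever edited.
#' Uses the current RNG state (seed at the caller).
#'
#' @param member A single-row library table.
#' @param model An [editor_model()].
#' @param depth Number of reads to draw.
#' @param window Editing window bounds.
#' @return Character vector of `depth` edited cassette sequences.
#' @export
simulate_outcomes <- function(member, model, depth, window = c(-9L, 20L)) {
  stopifnot(nrow(member) == 1, depth >= 0)
  if (depth == 0) return(character())
  sites <- site_conversion_probs(member, model, window)
  out <- matrix(rep(strsplit(member$cassette, "")[[1]], depth),
                nrow = depth, byrow = TRUE)
  engaged <- rbinom(depth, 1L, model$engage_prob) == 1L
  if (nrow(sites) > 0 && any(engaged)) {
    fG <- model$byproduct_fracs[["G"]]; fA <- model$byproduct_fracs[["A"]]
    for (s in seq_len(nrow(sites))) {
      hit <- engaged & (rbinom(depth, 1L, sites$p_conv[s]) == 1L)
      if (!any(hit)) next
      idx <- cassette_index(sites$position[s], member$protospacer_start)
      if (sites$ref_base[s] == "A") {
        out[hit, idx] <- "G"
      } else {
        out[hit, idx] <- sample(c("T", "G", "A"), sum(hit), replace = TRUE,
                                prob = c(1 - fG - fA, fG, fA))
      }
    }
  }
  apply(out, 1L, paste, collapse = "")
}

#' Simulate paired sequencing reads from editing outcomes
#'
#' Turns edited cassettes into paired FASTQ-ready records: the forward read
#' is the first `fwd_len` bases of the cassette (covering the -9..20 window
#' with flanks), the reverse read carries the member's spacer between fixed
#' scaffold flanks. Each base is substituted uniformly to one of the other
#' three with probability `seq_error_rate`; Phred+33 qualities are
#' `q_default` with a `q_fail_frac` fraction demoted to `q_fail`. Read ids
#' encode the ground-truth member. Uses the current RNG state.
#'
#' @param outcomes Character vector of edited cassettes (see
#'   [simulate_outcomes()]).
#' @param member The single-row library table the outcomes came from.
#' @param model An [editor_model()] (supplies error and quality parameters).
#' @param fwd_len,rev_len Read lengths.
#' @param id_suffix String appended to the member id in read ids (e.g. the
#'   replicate label).
#' @return Tibble `(read_id, member_id, fwd_seq, fwd_qual, rev_seq,
#'   rev_qual)`.
#' @export
simulate_reads <- function(outcomes, member, model,
                           fwd_len = 94L, rev_len = 56L, id_suffix = "rep1") {
  stopifnot(nrow(member) == 1)
  if (length(outcomes) == 0) abort("`outcomes` must be non-empty.")
  if (nchar(member$cassette) < fwd_len) {
    abort("cassette is shorter than the forward read length.")
  }
  rev_template <- paste0(rev_scaffold_5(), member$spacer, rev_scaffold_3())
  if (nchar(rev_template) < rev_len) {
    abort("spacer-side template is shorter than the reverse read length.")
  }
  n <- length(outcomes)
  fwd <- apply_seq_errors(substr(outcomes, 1L, fwd_len), model$seq_error_rate)
  rev <- apply_seq_errors(rep(substr(rev_template, 1L, rev_len), n),
                          model$seq_error_rate)
  tibble::tibble(
    read_id = sprintf("%s:%s:%06d", member$member_id, id_suffix, seq_len(n)),
    member_id = member$member_id,
    fwd_seq = fwd,
    fwd_qual = make_quals(n, fwd_len, model$q_default, model$q_fail_frac, model$q_fail),
    rev_seq = rev,
    rev_qual = make_quals(n, rev_len, model$q_default, model$q_fail_frac, model$q_fail)
  )
}

#' Simulate a full library sequencing run
#'
#' Simulates every member and replicate of a library experiment under one
#' editor model: per member and replicate the depth is drawn
#' Poisson(`mean_depth`), outcomes are simulated with [simulate_outcomes()]
#' and reads with [simulate_reads()]. Deterministic (byte-identical output)
#' given `config$rng_seed`.
#'
#' @param lib A library table.
#' @param model An [editor_model()].
#' @param config A [sim_config()]; its `n_members` must match `nrow(lib)`.
#' @return Tibble of paired reads with a `replicate` column; the replicate
#'   doubles as the batch label.
#' @export
simulate_run <- function(lib, model, config = sim_config(n_members = nrow(lib))) {
  lib <- validate_library(lib)
  if (config$n_members != nrow(lib)) {
    abort("`config$n_members` does not match the library size.")
  }
  withr::with_seed(config$rng_seed, {
    out <- vector("list", config$replicates)
    for (r in seq_len(config$replicates)) {
      per_member <- purrr::map(seq_len(nrow(lib)), function(i) {
        depth <- rpois(1L, config$mean_depth)
        if (depth == 0) return(NULL)
        member <- lib[i, ]
        oc <- simulate_outcomes(member, model, depth)
        simulate_reads(oc, member, model, config$fwd_len, config$rev_len,
                       id_suffix = sprintf("rep%d", r))
      })
      out[[r]] <- dplyr::bind_rows(per_member) |>
        dplyr::mutate(replicate = r, .after = "member_id")
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a run and write it to disk
#'
#' Convenience wrapper around [simulate_run()] that writes one pair of FASTQ
#' files per replicate (`R1_rep<k>.fastq`, `R2_rep<k>.fastq`), the library
#' TSV and a ground-truth JSON (analytic statistics from
#' [truth_statistics()]) into `out_dir`.
#'
#' @inheritParams simulate_run
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the reads tibble.
#' @export
simulate_fastq <- function(lib, model, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- simulate_run(lib, model, config)
  for (r in sort(unique(reads$replicate))) {
    rr <- reads[reads$replicate == r, ]
    write_fastq_pairs(rr,
                      file.path(out_dir, sprintf("R1_rep%d.fastq", r)),
                      file.path(out_dir, sprintf("R2_rep%d.fastq", r)))
  }
  write_library(lib, file.path(out_dir, "library.tsv"))
  truth <- truth_statistics(model, lib)
  jsonlite::write_json(
    list(window = truth$window, selectivity = truth$selectivity,
         average = as.list(truth$average), coediting = truth$coediting,
         abe_cbe_ratio = truth$abe_cbe_ratio),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(reads)
}
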