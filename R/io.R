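#' Read paired FASTQ files
#'
#' Reads a forward/reverse FASTQ pair (Phred+33, optionally gzipped) into a
#' read-pair tibble. The two files must contain the same number of records
#' with matching ids in the same order, and sequences must be over the
#' ACGTN alphabet.
#'
#' @param fwd_path,rev_path Paths to the forward and reverse FASTQ files.
#' @return Tibble `(read_id, fwd_seq, fwd_qual, rev_seq, rev_qual)`.
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  read_one <- function(path) {
    # Biostrings warns about dropping its own metadata columns here
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  fwd <- read_one(fwd_path)
  rev <- read_one(rev_path)
  if (length(fwd) != length(rev)) {
    abort(sprintf("record counts differ: %d in '%s' vs %d in '%s'",
                  length(fwd), fwd_path, length(rev), rev_path))
  }
  ids_f <- sub("\\s.*$", "", names(fwd))
  ids_r <- sub("\\s.*$", "", names(rev))
  bad <- which(ids_f != ids_r)
  if (length(bad)) {
    abort(sprintf("mismatched pair ids at record %d: '%s' vs '%s'",
                  bad[1], ids_f[bad[1]], ids_r[bad[1]]))
  }
  out <- tibble::tibble(
    read_id = ids_f,
    fwd_seq = unname(as.character(fwd)),
    fwd_qual = unname(as.character(Biostrings::quality(fwd))),
    rev_seq = unname(as.character(rev)),
    rev_qual = unname(as.character(Biostrings::quality(rev)))
  )
  for (col in c("fwd_seq", "rev_seq")) {
    bad <- which(!grepl("^[ACGTN]+$", out[[col]]))
    if (length(bad)) {
      abort(sprintf("non-ACGTN symbol in %s at record %d", col, bad[1]))
    }
  }
  out
}

#' Write paired FASTQ files
#'
#' Writes a read-pair tibble (as produced by [simulate_run()] or
#' [read_fastq_pairs()]) to a forward/reverse FASTQ pair with Phred+33
#' qualities. Output is deterministic: records are written in table order.
#'
#' @param reads Tibble with columns `read_id`, `fwd_seq`, `fwd_qual`,
#'   `rev_seq`, `rev_qual`.
#' @param fwd_path,rev_path Output paths.
#' @return Invisibly, `c(fwd_path, rev_path)`.
#' @export
write_fastq_pairs <- function(reads, fwd_path, rev_path) {
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- reads$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(reads$fwd_seq, reads$fwd_qual, fwd_path)
  write_one(reads$rev_seq, reads$rev_qual, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Decode a Phred+33 quality string
#'
#' @param qual A quality string (Sanger / Illumina 1.8+ encoding).
#' @return Integer vector of Phred scores.
#' @examples
#' decode_phred("?") # Q30
#' @export
decode_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

counts_schema <- c("member_id", "replicate", "position", "ref_base",
                   "alt_base", "edited_reads", "total_reads")

#' Read and write mutation-count tables
#'
#' The counts table holds, per `(member_id, replicate, position, ref_base,
#' alt_base)`, the number of genotyped reads carrying the substitution
#' (`edited_reads`) and the number of genotyped reads covering the position
#' (`total_reads`). Positions are protospacer coordinates. Writing validates
#' the schema (`edited_reads <= total_reads`, no missing cells) and orders
#' rows deterministically; `read_counts(write_counts(x))` round-trips.
#'
#' @param counts A counts tibble.
#' @param path File path (TSV).
#' @return `read_counts()` returns the counts tibble; `write_counts()`
#'   returns `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  missing_cols <- setdiff(counts_schema, names(counts))
  if (length(missing_cols)) {
    abort(paste0("counts table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  counts <- counts[counts_schema]
  if (anyNA(counts) || any(!is.finite(counts$edited_reads)) ||
      any(!is.finite(counts$total_reads))) {
    abort("counts table contains missing or non-finite cells.")
  }
  if (any(counts$edited_reads > counts$total_reads)) {
    abort("edited_reads exceeds total_reads.")
  }
  counts |>
    dplyr::arrange(.data$member_id, .data$replicate, .data$position,
                   .data$ref_base, .data$alt_base) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    member_id = "c", replicate = "i", position = "i",
                    ref_base = "c", alt_base = "c",
                    edited_reads = "i", total_reads = "i"))
}

#' Read and write per-position efficiency profiles
#'
#' A profile has one row per `(position, class)` with the pooled editing
#' efficiency. Non-finite efficiencies are rejected at write time; rows are
#' ordered deterministically.
#'
#' @param profile A profile tibble `(position, class, efficiency)`.
#' @param path File path (TSV).
#' @export
write_profile <- function(profile, path) {
  req <- c("position", "class", "efficiency")
  missing_cols <- setdiff(req, names(profile))
  if (length(missing_cols)) {
    abort(paste0("profile is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(profile$efficiency))) {
    abort("profile contains non-finite efficiency cells.")
  }
  profile[req] |>
    dplyr::arrange(.data$class, .data$position) |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(position = "i", class = "c",
                                          efficiency = "d"))
}

#' Read and write result lists as JSON
#'
#' Serializes scalar results and small tables (model fits, summary
#' statistics) to JSON with full numeric precision; reading restores the
#' list structure.
#'
#' @param results A named list.
#' @param path File path (JSON).
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
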