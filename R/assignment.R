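#' Read layout of a library sequencing run
#'
#' Describes where the regions of interest sit within the fixed-geometry
#' paired reads: the editing window (-9..20) inside the forward read, which
#' covers the cassette from its first base, and the 20-nt spacer inside the
#' reverse read. Requires all members to share `protospacer_start`, which
#' [build_library()] guarantees and which mirrors fixed amplicon read
#' geometry.
#'
#' @param lib A library table.
#' @param window Editing window bounds in protospacer coordinates.
#' @param spacer_offset 0-based offset of the spacer within the reverse
#'   read (default 18, the simulator's scaffold length).
#' @return A `read_layout` list with 1-based `fwd_window_start`,
#'   `window_len`, `spacer_start` and `spacer_len`.
#' @export
read_layout <- function(lib, window = c(-9L, 20L), spacer_offset = 18L) {
  ps <- unique(lib$protospacer_start)
  if (length(ps) != 1) {
    abort("all members must share `protospacer_start` for a fixed read layout.")
  }
  structure(list(
    fwd_window_start = cassette_index(window[1], ps),
    window_len = window[2] - window[1] + 1L,
    spacer_start = spacer_offset + 1L,
    spacer_len = 20L,
    window = as.integer(window),
    protospacer_start = as.integer(ps)
  ), class = "read_layout")
}

# minimum Phred score within [start, start+len-1] of each quality string;
# NA when the region extends past the read end
region_min_phred <- function(quals, start, len) {
  width <- nchar(quals)
  out <- rep(NA_integer_, length(quals))
  ok <- width >= start + len - 1L
  if (!any(ok)) return(out)
  q <- quals[ok]
  if (length(unique(nchar(q))) == 1) {
    m <- matrix(as.integer(charToRaw(paste(q, collapse = ""))),
                nrow = nchar(q[1]))
    out[ok] <- apply(m[start:(start + len - 1L), , drop = FALSE], 2, min) - 33L
  } else {
    out[ok] <- vapply(substr(q, start, start + len - 1L),
                      function(s) min(utf8ToInt(s)), integer(1)) - 33L
  }
  out
}

#' Quality-filter read pairs
#'
#' Keeps a read pair iff every base of the editing window (forward read) and
#' of the spacer (reverse read) has Phred >= `min_phred` (default Q28).
#' Bases outside those regions are unconstrained. Pairs whose reads are too
#' short for the configured regions are discarded.
#'
#' @param reads A read-pair tibble (see [read_fastq_pairs()]).
#' @param layout A [read_layout()].
#' @param min_phred Minimum Phred score (default 28).
#' @return The input tibble with a logical `qc_keep` column.
#' @export
quality_filter <- function(reads, layout, min_phred = 28L) {
  stopifnot(min_phred >= 0, min_phred <= 41)
  if (nrow(reads) == 0) return(dplyr::mutate(reads, qc_keep = logical(0)))
  fwd_min <- region_min_phred(reads$fwd_qual, layout$fwd_window_start,
                              layout$window_len)
  rev_min <- region_min_phred(reads$rev_qual, layout$spacer_start,
                              layout$spacer_len)
  keep <- !is.na(fwd_min) & !is.na(rev_min) &
    fwd_min >= min_phred & rev_min >= min_phred
  dplyr::mutate(reads, qc_keep = keep)
}

#' Tiled 6-mer index over library editing windows
#'
#' Builds the locality-sensitive-hashing index used for candidate
#' nomination: the editing window of each member is cut into non-overlapping
#' k-mer tiles (stride = k, anchored at position -9) and each
#' `(tile, k-mer)` key maps to the members carrying it. A read sharing at
#' least one tile-position-matched k-mer with a member nominates it.
#'
#' @param lib A library table (members must share `protospacer_start`).
#' @param k Tile width (default 6).
#' @param window Editing window bounds.
#' @return A tibble `(tile, kmer, member_id)` with the layout stored in
#'   attributes.
#' @export
kmer_index <- function(lib, k = 6L, window = c(-9L, 20L)) {
  lib <- validate_library(lib)
  layout <- read_layout(lib, window)
  n_tiles <- layout$window_len %/% k
  if (n_tiles < 1) abort("editing window shorter than one tile.")
  tiles <- purrr::map(seq_len(n_tiles), function(t) {
    start <- layout$fwd_window_start + (t - 1L) * k
    tibble::tibble(tile = t,
                   kmer = substr(lib$cassette, start, start + k - 1L),
                   member_id = lib$member_id)
  })
  idx <- dplyr::bind_rows(tiles)
  attr(idx, "k") <- as.integer(k)
  attr(idx, "n_tiles") <- n_tiles
  attr(idx, "layout") <- layout
  idx
}

#' Nominate candidate members for reads by shared tiles
#'
#' For each forward read, extracts the k-mer tiles at the window offsets of
#' the index and nominates every member sharing at least one
#' tile-position-matched k-mer, ranked by the number of shared tiles
#' (descending) with ties broken by `member_id` for determinism. Reads with
#' no shared tile get no rows (they are routed to the unassigned bin by
#' [assign_and_genotype()]).
#'
#' @param read_seq Character vector of forward-read sequences.
#' @param index A [kmer_index()].
#' @return Tibble `(read, member_id, shared_tiles)`, `read` indexing into
#'   `read_seq`, ordered by read, then rank.
#' @export
nominate_candidates <- function(read_seq, index) {
  k <- attr(index, "k")
  n_tiles <- attr(index, "n_tiles")
  layout <- attr(index, "layout")
  if (any(nchar(read_seq) < k)) abort("reads must be at least one tile long.")
  read_tiles <- purrr::map(seq_len(n_tiles), function(t) {
    start <- layout$fwd_window_start + (t - 1L) * k
    tibble::tibble(read = seq_along(read_seq), tile = t,
                   kmer = substr(read_seq, start, start + k - 1L))
  }) |> dplyr::bind_rows()
  read_tiles |>
    dplyr::inner_join(index, by = c("tile", "kmer"),
                      relationship = "many-to-many") |>
    dplyr::count(.data$read, .data$member_id, name = "shared_tiles") |>
    dplyr::arrange(.data$read, dplyr::desc(.data$shared_tiles),
                   .data$member_id)
}

#' Filter candidates by exact spacer match
#'
#' Retains the candidates whose library spacer equals the sequenced spacer
#' of the read exactly (one mismatch removes the candidate). Reads whose
#' spacer matches no surviving candidate become unassigned downstream.
#'
#' @param candidates A candidate tibble from [nominate_candidates()].
#' @param sequenced_spacer Character vector of sequenced spacers, indexed by
#'   the `read` column of `candidates`.
#' @param lib The library table (provides each member's spacer).
#' @return The surviving rows of `candidates`.
#' @export
spacer_filter <- function(candidates, sequenced_spacer, lib) {
  candidates |>
    dplyr::inner_join(lib[c("member_id", "spacer")], by = "member_id") |>
    dplyr::filter(.data$spacer == sequenced_spacer[.data$read]) |>
    dplyr::select(-"spacer")
}

#' Genotype one read against its assigned member
#'
#' Globally aligns the read to the member cassette and calls substitutions
#' at aligned (non-gap) columns whose reference base is C or A, whose
#' substitution is one of the tracked classes (C>T, C>G, C>A, A>G) and
#' whose reference position lies in the editing window. Indel columns, `N`
#' bases and all other substitutions yield no call.
#'
#' @param read_seq A forward-read sequence.
#' @param member A single-row library table.
#' @param params An [align_params()].
#' @param window Editing window bounds.
#' @return A list of class `genotype_call`: `calls` (tibble `position`,
#'   `ref_base`, `alt_base`), `score`, and `uncovered` (window positions the
#'   alignment placed read gaps at).
#' @export
genotype <- function(read_seq, member, params = align_params(),
                     window = c(-9L, 20L)) {
  stopifnot(nrow(member) == 1)
  check_seq(read_seq, "read_seq")
  win_lo0 <- cassette_index(window[1], member$protospacer_start) - 1L
  win_hi0 <- cassette_index(window[2], member$protospacer_start) - 1L
  g <- .genotype_batch_cpp(read_seq, member$cassette, win_lo0, win_hi0,
                           params$match, params$mismatch, params$gap_open,
                           params$gap_extend, params$free_start_gaps,
                           params$free_end_gaps)
  structure(list(
    calls = tibble::tibble(
      position = g$call_pos + 1L - member$protospacer_start,
      ref_base = g$call_ref, alt_base = g$call_alt),
    score = g$score[1],
    uncovered = g$gap_pos + 1L - member$protospacer_start
  ), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat("<genotype_call> score", x$score, "-", nrow(x$calls), "call(s)\n")
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}

#' Assign and genotype a stream of read pairs
#'
#' Runs the full read-processing chain on a read-pair table: Q28 quality
#' filtering over the editing window and spacer, tiled 6-mer candidate
#' nomination, exact spacer-match filtering, global-alignment scoring of the
#' surviving candidates (best score wins, ties by `member_id`, scores below
#' `min_score` unassigned) and genotyping restricted to the tracked
#' substitution classes within the window. Reads tally into exactly one of
#' kept (genotyped), discarded (quality) or unassigned.
#'
#' @param reads Read-pair tibble; a `replicate` column is honoured (default
#'   replicate 1) and a `member_id` column, if present, is carried through
#'   to the read log as `true_member`.
#' @param lib The library table.
#' @param params Alignment parameters.
#' @param min_phred Quality floor (default 28).
#' @param max_candidates Candidates carried into alignment per read.
#' @param min_score Alignment score floor; default is half the forward read
#'   length.
#' @param window Editing window bounds.
#' @return A list of class `be_assignment`: `counts` (the mutation count
#'   table, one row per member/replicate/position/class), `calls`
#'   (read-level calls), `read_totals` (genotyped reads per member and
#'   replicate), `read_log` (per-read status and assignment) and `report`
#'   (read accounting).
#' @export
assign_and_genotype <- function(reads, lib, params = align_params(),
                                min_phred = 28L, max_candidates = 5L,
                                min_score = NULL, window = c(-9L, 20L)) {
  lib <- validate_library(lib)
  layout <- read_layout(lib, window)
  if (!"replicate" %in% names(reads)) reads$replicate <- 1L
  true_member <- if ("member_id" %in% names(reads)) reads$member_id else NA_character_
  n_total <- nrow(reads)

  empty_counts <- tibble::tibble(
    member_id = character(), replicate = integer(), position = integer(),
    ref_base = character(), alt_base = character(),
    edited_reads = integer(), total_reads = integer())
  empty_calls <- tibble::tibble(
    read_id = character(), member_id = character(), replicate = integer(),
    position = integer(), ref_base = character(), alt_base = character())

  if (n_total == 0) {
    return(structure(list(
      counts = empty_counts, calls = empty_calls,
      read_totals = tibble::tibble(member_id = character(),
                                   replicate = integer(), n_reads = integer()),
      read_log = tibble::tibble(read_id = character(), replicate = integer(),
                                status = character(), member_id = character(),
                                true_member = character(), score = double()),
      report = list(total = 0L, kept = 0L, discarded = 0L, unassigned = 0L)),
      class = "be_assignment"))
  }

  qc <- quality_filter(reads, layout, min_phred)
  kept <- qc[qc$qc_keep, , drop = FALSE]
  n_discarded <- n_total - nrow(kept)
  status <- rep("discarded", n_total)
  assigned_member <- rep(NA_character_, n_total)
  assigned_score <- rep(NA_real_, n_total)
  kept_rows <- which(qc$qc_keep)

  best <- NULL
  geno <- NULL
  if (nrow(kept) > 0) {
    status[kept_rows] <- "unassigned"
    if (is.null(min_score)) min_score <- 0.5 * min(nchar(kept$fwd_seq))

    index <- kmer_index(lib, window = window)
    cand <- nominate_candidates(kept$fwd_seq, index) |>
      dplyr::group_by(.data$read) |>
      dplyr::slice_head(n = max_candidates) |>
      dplyr::ungroup()
    spacer_seq <- substr(kept$rev_seq, layout$spacer_start,
                         layout$spacer_start + layout$spacer_len - 1L)
    cand <- spacer_filter(cand, spacer_seq, lib)

    if (nrow(cand) > 0) {
      cand <- dplyr::left_join(cand, lib[c("member_id", "cassette")],
                               by = "member_id")
      win_lo0 <- cassette_index(window[1], layout$protospacer_start) - 1L
      win_hi0 <- cassette_index(window[2], layout$protospacer_start) - 1L
      g <- .genotype_batch_cpp(kept$fwd_seq[cand$read], cand$cassette,
                               win_lo0, win_hi0,
                               params$match, params$mismatch, params$gap_open,
                               params$gap_extend, params$free_start_gaps,
                               params$free_end_gaps)
      cand$pair <- seq_len(nrow(cand))
      cand$score <- g$score
      best <- cand |>
        dplyr::arrange(.data$read, dplyr::desc(.data$score), .data$member_id) |>
        dplyr::distinct(.data$read, .keep_all = TRUE) |>
        dplyr::filter(.data$score >= min_score)
      geno <- g
    }
  }

  calls <- empty_calls
  read_totals <- tibble::tibble(member_id = character(), replicate = integer(),
                                n_reads = integer())
  counts <- empty_counts
  if (!is.null(best) && nrow(best) > 0) {
    rows <- kept_rows[best$read]
    status[rows] <- "kept"
    assigned_member[rows] <- best$member_id
    assigned_score[rows] <- best$score

    pair_of_best <- best$pair
    keep_call <- geno$call_read %in% pair_of_best
    pair_to_best <- match(geno$call_read[keep_call], best$pair)
    calls <- tibble::tibble(
      read_id = kept$read_id[best$read[pair_to_best]],
      member_id = best$member_id[pair_to_best],
      replicate = kept$replicate[best$read[pair_to_best]],
      position = geno$call_pos[keep_call] + 1L - layout$protospacer_start,
      ref_base = geno$call_ref[keep_call],
      alt_base = geno$call_alt[keep_call])

    read_totals <- tibble::tibble(member_id = best$member_id,
                                  replicate = kept$replicate[best$read]) |>
      dplyr::count(.data$member_id, .data$replicate, name = "n_reads")

    # coverage: genotyped reads minus reads whose alignment gapped the position
    keep_gap <- geno$gap_read %in% pair_of_best
    gap_to_best <- match(geno$gap_read[keep_gap], best$pair)
    gaps <- tibble::tibble(
      member_id = best$member_id[gap_to_best],
      replicate = kept$replicate[best$read[gap_to_best]],
      position = geno$gap_pos[keep_gap] + 1L - layout$protospacer_start) |>
      dplyr::count(.data$member_id, .data$replicate, .data$position,
                   name = "n_gaps")

    grid <- site_table(lib, window) |>
      dplyr::inner_join(read_totals, by = "member_id",
                        relationship = "many-to-many")
    edited <- calls |>
      dplyr::count(.data$member_id, .data$replicate, .data$position,
                   .data$ref_base, .data$alt_base, name = "edited_reads")
    counts <- grid |>
      dplyr::left_join(edited,
                       by = c("member_id", "replicate", "position",
                              "ref_base", "alt_base")) |>
      dplyr::left_join(gaps, by = c("member_id", "replicate", "position")) |>
      dplyr::mutate(
        edited_reads = as.integer(tidyr::replace_na(.data$edited_reads, 0L)),
        total_reads = .data$n_reads -
          as.integer(tidyr::replace_na(.data$n_gaps, 0L))) |>
      dplyr::select(dplyr::all_of(counts_schema)) |>
      dplyr::arrange(.data$member_id, .data$replicate, .data$position,
                     .data$ref_base, .data$alt_base)
  }

  report <- list(total = n_total,
                 kept = sum(status == "kept"),
                 discarded = sum(status == "discarded"),
                 unassigned = sum(status == "unassigned"))

  structure(list(
    counts = counts, calls = calls, read_totals = read_totals,
    read_log = tibble::tibble(read_id = reads$read_id,
                              replicate = reads$replicate,
                              status = status, member_id = assigned_member,
                              true_member = true_member,
                              score = assigned_score),
    report = report), class = "be_assignment")
}

#' @export
print.be_assignment <- function(x, ...) {
  r <- x$report
  cat("<be_assignment>", r$total, "read pairs:", r$kept, "genotyped,",
      r$discarded, "discarded (quality),", r$unassigned, "unassigned\n")
  invisible(x)
}
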