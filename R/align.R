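#' Alignment scoring parameters
#'
#' Scoring scheme of the global (Needleman-Wunsch) aligner used for
#' genotyping: match +1, mismatch -1, affine gaps with open -5 and extend 0
#' (a gap run of length L costs `gap_open + (L-1) * gap_extend`), and free
#' leading gaps on both sequences by default ("start gap = 0"); trailing
#' gaps pay the gap penalty unless `free_end_gaps` is set. `N` scores as a
#' mismatch against everything.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (both <= 0).
#' @param free_start_gaps,free_end_gaps Whether leading/trailing gap runs
#'   are free.
#' @return An `align_params` list.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = 0, free_start_gaps = TRUE,
                         free_end_gaps = FALSE) {
  if (gap_open > 0 || gap_extend > 0) abort("gap penalties must be <= 0.")
  if (match < mismatch) abort("`match` must be >= `mismatch`.")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 free_start_gaps = isTRUE(free_start_gaps),
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "align_params")
}

check_seq <- function(x, arg) {
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(paste0("`", arg, "` must be a single non-empty sequence."))
  }
  if (!grepl("^[ACGTN]+$", x)) {
    abort(paste0("`", arg, "` must be over the ACGTN alphabet."))
  }
  x
}

#' Global alignment of two sequences
#'
#' Maximum-score global alignment under the affine scheme of
#' [align_params()], with deterministic traceback (ties prefer diagonal,
#' then consuming `a`, then consuming `b`).
#'
#' @param a,b Sequences over ACGTN.
#' @param params An [align_params()] object.
#' @return List with `score`, `aligned_a`, `aligned_b` (gapped strings of
#'   equal length).
#' @examples
#' nw_align("AAACGT", "CGT")$score # leading gap is free
#' @export
nw_align <- function(a, b, params = align_params()) {
  check_seq(a, "a"); check_seq(b, "b")
  .nw_align_cpp(a, b, params$match, params$mismatch, params$gap_open,
                params$gap_extend, params$free_start_gaps,
                params$free_end_gaps)
}

# vectorized pairwise scores (internal)
nw_scores <- function(a, b, params = align_params()) {
  stopifnot(length(a) == length(b))
  .nw_score_batch_cpp(a, b, params$match, params$mismatch, params$gap_open,
                      params$gap_extend, params$free_start_gaps,
                      params$free_end_gaps)
}

# exhaustive alignment-path enumeration oracle (internal; test use only)
nw_enum_score <- function(a, b, params = align_params()) {
  .nw_enum_score_cpp(a, b, params$match, params$mismatch, params$gap_open,
                     params$gap_extend, params$free_start_gaps,
                     params$free_end_gaps)
}
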