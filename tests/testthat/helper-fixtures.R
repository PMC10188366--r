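# shared fixtures: small libraries and editor models built in code

tiny_library <- function(n = 8, seed = 101) build_library(n, seed = seed)

# error-free sequencing so reads are exact substrings
noiseless <- function(model) {
  model$seq_error_rate <- 0
  model$q_fail_frac <- 0
  model
}

# a single-member library with a hand-built cassette, for surgical tests:
# cassette is 94 nt, protospacer_start 30, C at protospacer position 6
manual_member <- function() {
  lib <- build_library(1, seed = 77)
  validate_library(lib)
}

# read-pair tibble for one member with given sequences/qualities
manual_reads <- function(member, fwd_seq = NULL, fwd_qual = NULL,
                         rev_seq = NULL, rev_qual = NULL, replicate = 1L) {
  fwd <- fwd_seq %||% substr(member$cassette, 1, 94)
  rev <- rev_seq %||% paste0(beditlib:::rev_scaffold_5(), member$spacer,
                             beditlib:::rev_scaffold_3())
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(fwd)),
    member_id = member$member_id,
    replicate = replicate,
    fwd_seq = fwd,
    fwd_qual = fwd_qual %||% strrep("?", nchar(fwd)),  # Q30
    rev_seq = rev,
    rev_qual = rev_qual %||% strrep("?", nchar(rev)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# substitute one character of a string
subst_at <- function(s, i, ch) {
  substr(s, i, i) <- ch
  s
}

other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)
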