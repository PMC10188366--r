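#' Build a synthetic comprehensive-context target-site library
#'
#' Generates a reduced-scale version of a genomically integrated paired
#' sgRNA/target-site library: each member carries a 20-nt spacer whose
#' protospacer is embedded in a cassette with flanking sequence and an NGG
#' PAM, and a designed substrate base (C or A) at a fixed protospacer
#' position surrounded by variable sequence context.
#'
#' The first members systematically cycle through all 16 combinations of the
#' 5' and 3' neighbour of the substrate base for each target base, so that
#' with `n_members >= 32` (and the default 50:50 C/A mix) every dinucleotide
#' context is represented for both substrate bases. Remaining context
#' positions are drawn uniformly. Spacers are guaranteed unique.
#'
#' The cassette geometry is fixed: `upstream_flank` nt, the 20-nt
#' protospacer, a 3-nt NGG PAM and a downstream flank, sized so the default
#' cassette is 94 nt and a 94-nt forward read covers the whole cassette with
#' the editing window -9..20 at fixed offsets.
#'
#' @param n_members Number of library members (>= 1).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param target_base_pos Protospacer position of the designed substrate base.
#' @param target_bases Bases to alternate between for the designed position.
#' @param upstream_flank Bases upstream of protospacer position 1 (>= 9 so
#'   positions -9..0 exist; default 30).
#' @param cassette_length Total cassette length (default 94).
#' @return A tibble with columns `member_id`, `spacer`, `cassette`,
#'   `protospacer_start` (0-based offset of protospacer position 1),
#'   `target_base_pos` and `target_base`.
#' @examples
#' lib <- build_library(32, seed = 1)
#' table(lib$target_base)
#' @export
build_library <- function(n_members, seed,
                          target_base_pos = 6L,
                          target_bases = c("C", "A"),
                          upstream_flank = 30L,
                          cassette_length = 94L) {
  if (!is.numeric(n_members) || n_members < 1) {
    abort("`n_members` must be a positive integer.")
  }
  if (missing(seed)) abort("`seed` must be supplied for a reproducible library.")
  if (upstream_flank < 9) abort("`upstream_flank` must be >= 9 so positions -9..0 exist.")
  n_members <- as.integer(n_members)
  stopifnot(all(target_bases %in% c("C", "A")))
  if (cassette_length < upstream_flank + 23) {
    abort("`cassette_length` too short for flank + protospacer + PAM.")
  }

  bases <- c("A", "C", "G", "T")
  contexts <- expand.grid(up = bases, down = bases,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  withr::with_seed(seed, {
    target_base <- rep_len(target_bases, n_members)
    # force full dinucleotide-context coverage for the first 16 members of
    # each substrate base
    ctx_up <- character(n_members)
    ctx_down <- character(n_members)
    for (b in unique(target_base)) {
      idx <- which(target_base == b)
      forced <- head(idx, 16L)
      ctx_up[forced] <- contexts$up[seq_along(forced)]
      ctx_down[forced] <- contexts$down[seq_along(forced)]
      rest <- setdiff(idx, forced)
      ctx_up[rest] <- sample(bases, length(rest), replace = TRUE)
      ctx_down[rest] <- sample(bases, length(rest), replace = TRUE)
    }

    make_cassette <- function(i) {
      cas <- sample(bases, cassette_length, replace = TRUE)
      p1 <- upstream_flank + 1L              # 1-based index of protospacer pos 1
      cas[p1 + 20L + 1:2] <- c("G", "G")     # NGG PAM at positions 22-23
      t_idx <- upstream_flank + target_base_pos
      cas[t_idx] <- target_base[i]
      cas[t_idx - 1L] <- ctx_up[i]
      cas[t_idx + 1L] <- ctx_down[i]
      paste(cas, collapse = "")
    }

    cassette <- vapply(seq_len(n_members), make_cassette, character(1))
    spacer <- substr(cassette, upstream_flank + 1L, upstream_flank + 20L)

    # regenerate any duplicated spacers (deterministic: RNG stream continues)
    tries <- 0L
    while (anyDuplicated(spacer) > 0) {
      tries <- tries + 1L
      if (tries > 100L) {
        abort("could not generate unique spacers; `n_members` too large for the sequence space.")
      }
      dup <- which(duplicated(spacer))
      for (i in dup) cassette[i] <- make_cassette(i)
      spacer <- substr(cassette, upstream_flank + 1L, upstream_flank + 20L)
    }

    lib <- tibble::tibble(
      member_id = sprintf("M%05d", seq_len(n_members)),
      spacer = spacer,
      cassette = cassette,
      protospacer_start = as.integer(upstream_flank),
      target_base_pos = as.integer(target_base_pos),
      target_base = target_base
    )
    validate_library(lib)
  })
}

#' Validate a library member table
#'
#' Checks the structural invariants of a library table: required columns,
#' unique member ids, spacer embedded in the cassette at `protospacer_start`,
#' at least 9 nt of upstream flank, and the designed base present at the
#' designed position.
#'
#' @param lib A data frame of library members.
#' @return The validated library as a tibble (invisibly the same data).
#' @export
validate_library <- function(lib) {
  req <- c("member_id", "spacer", "cassette", "protospacer_start",
           "target_base_pos", "target_base")
  missing_cols <- setdiff(req, names(lib))
  if (length(missing_cols)) {
    abort(paste0("library table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  lib <- tibble::as_tibble(lib)
  if (anyDuplicated(lib$member_id)) {
    abort(paste0("duplicated member_id: ",
                 paste(unique(lib$member_id[duplicated(lib$member_id)]), collapse = ", ")))
  }
  bad <- which(lib$protospacer_start < 9)
  if (length(bad)) {
    abort(paste0("row ", bad[1], ": protospacer_start must be >= 9 so positions -9..0 exist."))
  }
  embedded <- substr(lib$cassette, lib$protospacer_start + 1L,
                     lib$protospacer_start + 20L)
  bad <- which(embedded != lib$spacer)
  if (length(bad)) {
    abort(paste0("row ", bad[1], ": cassette does not contain the spacer at protospacer_start."))
  }
  at_target <- substr(lib$cassette,
                      cassette_index(lib$target_base_pos, lib$protospacer_start),
                      cassette_index(lib$target_base_pos, lib$protospacer_start))
  bad <- which(at_target != lib$target_base)
  if (length(bad)) {
    abort(paste0("row ", bad[1], ": cassette base at target_base_pos is not target_base."))
  }
  if (!all(grepl("^[ACGT]+$", lib$cassette))) {
    abort("cassette sequences must be ACGT only.")
  }
  lib
}

#' Enumerate tracked substrate sites for each library member
#'
#' Lists every C and A within the editing window of each member, together
#' with the tracked substitution classes at that site (C sites track C>T,
#' C>G and C>A; A sites track A>G).
#'
#' @param lib A library table (see [build_library()]).
#' @param window Integer bounds of the editing window in protospacer
#'   coordinates (default -9..20).
#' @return A tibble `(member_id, position, ref_base, alt_base)`.
#' @export
site_table <- function(lib, window = c(-9L, 20L)) {
  lib <- validate_library(lib)
  pos <- window_positions(window)
  per_member <- purrr::map(seq_len(nrow(lib)), function(i) {
    idx <- cassette_index(pos, lib$protospacer_start[i])
    base <- substring(lib$cassette[i], idx, idx)
    keep <- base %in% c("C", "A")
    tibble::tibble(member_id = lib$member_id[i],
                   position = pos[keep], ref_base = base[keep])
  })
  dplyr::bind_rows(per_member) |>
    dplyr::inner_join(tracked_classes(), by = "ref_base",
                      relationship = "many-to-many")
}

#' Read and write library tables
#'
#' The on-disk format is a TSV with header columns `member_id`, `spacer`,
#' `cassette`, `protospacer_start`, `target_base_pos`, `target_base`.
#' Reading validates every structural invariant and reports the offending
#' row; writing is deterministic (rows ordered by `member_id`).
#'
#' @param path File path.
#' @param lib A library table.
#' @return `read_library()` returns the validated tibble; `write_library()`
#'   returns `path` invisibly.
#' @export
read_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           member_id = "c", spacer = "c", cassette = "c",
                           protospacer_start = "i", target_base_pos = "i",
                           target_base = "c"))
  validate_library(lib)
}

#' @rdname read_library
#' @export
write_library <- function(lib, path) {
  lib <- validate_library(lib) |> dplyr::arrange(.data$member_id)
  readr::write_tsv(lib, path)
  invisible(path)
}
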