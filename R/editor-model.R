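#' Parameterized editor model for outcome simulation
#'
#' Defines the ground truth used by the simulator. The probability that a
#' given substrate base converts in an engaged read is additive on the
#' log-odds scale:
#' \deqn{p = \mathrm{logistic}(\mu + w_{pos} + \sum_{o} c_{o, base(o)})}
#' where \eqn{w} is the per-position window weight for the substrate class
#' (C or A) and \eqn{c} are context weights over relative offsets -3..+3
#' (excluding 0). Editing only ever occurs in reads in which the editor
#' engages the cassette at all (probability `engage_prob`), which couples
#' edits at different sites of the same read. C conversions realize as C>G
#' or C>A with the byproduct fractions, otherwise C>T; A conversions are
#' always A>G.
#'
#' @param mu Baseline log-odds of conversion.
#' @param window_c,window_a Named numeric vectors mapping protospacer
#'   position (-9..20) to additive log-odds for C and A substrates.
#'   Positions absent from the vector get `-Inf` (never edited).
#' @param context_c,context_a Data frames `(offset, base, weight)` of
#'   additive log-odds context effects for C and A substrates; `NULL` means
#'   no context effect.
#' @param byproduct_fracs Named vector `c(G = , A = )`: fractions of C
#'   conversions realized as C>G and C>A (the remainder is C>T).
#' @param engage_prob Per-read probability that the editor engages.
#' @param seq_error_rate Per-base substitution error probability of the
#'   simulated sequencer (default 1e-3, i.e. Q30).
#' @param q_default Phred score assigned to bases (default 30).
#' @param q_fail_frac Fraction of bases demoted to `q_fail`.
#' @param q_fail Phred score of demoted bases (default 11, below the Q28
#'   read filter).
#' @return An object of class `editor_model`.
#' @examples
#' m <- editor_model(window_c = window_from_rates(c("6" = 0.5)))
#' @export
editor_model <- function(mu = 0,
                         window_c = numeric(),
                         window_a = numeric(),
                         context_c = NULL,
                         context_a = NULL,
                         byproduct_fracs = c(G = 0, A = 0),
                         engage_prob = 1,
                         seq_error_rate = 1e-3,
                         q_default = 30L,
                         q_fail_frac = 0,
                         q_fail = 11L) {
  stopifnot(engage_prob >= 0, engage_prob <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            q_fail_frac >= 0, q_fail_frac <= 1)
  byproduct_fracs <- byproduct_fracs[c("G", "A")]
  if (anyNA(byproduct_fracs)) abort("`byproduct_fracs` must name fractions G and A.")
  if (any(byproduct_fracs < 0) || sum(byproduct_fracs) > 1) {
    abort("byproduct fractions must be non-negative and sum to <= 1.")
  }
  check_ctx <- function(ctx, arg) {
    if (is.null(ctx)) return(NULL)
    stopifnot(all(c("offset", "base", "weight") %in% names(ctx)))
    if (any(ctx$offset == 0)) abort(paste0("`", arg, "` may not weight offset 0 (the substrate base)."))
    tibble::as_tibble(ctx[c("offset", "base", "weight")])
  }
  structure(list(
    mu = mu,
    window_c = window_c, window_a = window_a,
    context_c = check_ctx(context_c, "context_c"),
    context_a = check_ctx(context_a, "context_a"),
    byproduct_fracs = byproduct_fracs,
    engage_prob = engage_prob,
    seq_error_rate = seq_error_rate,
    q_default = as.integer(q_default),
    q_fail_frac = q_fail_frac,
    q_fail = as.integer(q_fail)
  ), class = "editor_model")
}

#' @export
print.editor_model <- function(x, ...) {
  cat("<editor_model>\n")
  cat("  engage_prob:", x$engage_prob,
      " byproducts G/A:", paste(x$byproduct_fracs, collapse = "/"), "\n")
  cat("  active C positions:", paste(names(x$window_c)[is.finite(x$window_c)], collapse = " "), "\n")
  cat("  active A positions:", paste(names(x$window_a)[is.finite(x$window_a)], collapse = " "), "\n")
  invisible(x)
}

#' Window weights from target conversion rates
#'
#' Convenience inverse of the logistic link: returns window weights such
#' that, with baseline `mu` and no context effect, the per-site conversion
#' probability in an engaged read equals `rates`.
#'
#' @param rates Named numeric vector, names are protospacer positions.
#' @param mu Baseline log-odds the weights are relative to.
#' @return Named numeric vector of log-odds weights.
#' @export
window_from_rates <- function(rates, mu = 0) {
  w <- qlogis(rates) - mu
  names(w) <- names(rates)
  w
}

# per-site conversion probability (given engagement) for every tracked
# substrate site of every member
site_conversion_probs <- function(lib, model, window = c(-9L, 20L)) {
  lib <- validate_library(lib)
  pos <- window_positions(window)

  ctx_eta <- function(ctx, cas, idx) {
    if (is.null(ctx) || nrow(ctx) == 0) return(0)
    eta <- 0
    for (r in seq_len(nrow(ctx))) {
      b <- substring(cas, idx + ctx$offset[r], idx + ctx$offset[r])
      eta <- eta + ifelse(b == ctx$base[r], ctx$weight[r], 0)
    }
    eta
  }
  wlook <- function(w, p) {
    out <- unname(w[as.character(p)])
    out[is.na(out)] <- -Inf
    out
  }

  purrr::map(seq_len(nrow(lib)), function(i) {
    idx <- cassette_index(pos, lib$protospacer_start[i])
    base <- substring(lib$cassette[i], idx, idx)
    keep <- base %in% c("C", "A")
    p <- pos[keep]; b <- base[keep]; ix <- idx[keep]
    eta <- ifelse(b == "C",
                  model$mu + wlook(model$window_c, p) +
                    ctx_eta(model$context_c, lib$cassette[i], ix),
                  model$mu + wlook(model$window_a, p) +
                    ctx_eta(model$context_a, lib$cassette[i], ix))
    tibble::tibble(member_id = lib$member_id[i], position = p,
                   ref_base = b, p_conv = plogis(eta))
  }) |> dplyr::bind_rows()
}

#' Analytic ground-truth statistics of an editor model on a library
#'
#' Computes, without simulation, the expected per-position editing
#' efficiencies of every tracked substitution class, the implied editing
#' window, selectivity, average editing efficiencies, the conditional
#' co-editing probability and the ABE:CBE ratio. These are the quantities
#' the analysis pipeline estimates from reads; parameter-recovery tests
#' compare pipeline output against them.
#'
#' Per-position efficiency is the unweighted mean, over members whose
#' reference carries the substrate base at that position, of the expected
#' fraction of reads with the given substitution. The window, selectivity
#' and averages use the same definitions as [editing_window()],
#' [selectivity()] and [average_editing_efficiency()].
#'
#' @param model An [editor_model()].
#' @param lib A library table.
#' @param window Window bounds (protospacer coordinates).
#' @param peak_fraction Window threshold as a fraction of peak efficiency.
#' @param window_class Class whose profile defines the editing window.
#' @return A list with elements `profile` (tibble `position`, `class`,
#'   `efficiency`), `window` (integer vector), `selectivity`,
#'   `average` (named: `c2t`, `any_c`, `a2g`), `coediting` and
#'   `abe_cbe_ratio`.
#' @export
truth_statistics <- function(model, lib, window = c(-9L, 20L),
                             peak_fraction = 0.30, window_class = "C>T") {
  sp <- site_conversion_probs(lib, model, window)
  fG <- model$byproduct_fracs[["G"]]
  fA <- model$byproduct_fracs[["A"]]
  e <- model$engage_prob

  class_frac <- function(ref, alt) {
    dplyr::case_when(
      ref == "C" & alt == "T" ~ 1 - fG - fA,
      ref == "C" & alt == "G" ~ fG,
      ref == "C" & alt == "A" ~ fA,
      ref == "A" & alt == "G" ~ 1
    )
  }

  per_site <- sp |>
    dplyr::inner_join(tracked_classes(), by = "ref_base",
                      relationship = "many-to-many") |>
    dplyr::mutate(efficiency = e * .data$p_conv *
                    class_frac(.data$ref_base, .data$alt_base),
                  class = class_label(.data$ref_base, .data$alt_base))

  profile <- per_site |>
    dplyr::group_by(.data$position, .data$class) |>
    dplyr::summarise(efficiency = mean(.data$efficiency), .groups = "drop")

  win <- editing_window(profile, class = window_class,
                        peak_fraction = peak_fraction)
  sel <- selectivity(profile, win)

  # per-member probability that a read carries >= 1 edit of a class set
  p_member <- function(classes) {
    per_site |>
      dplyr::filter(.data$class %in% classes) |>
      dplyr::group_by(.data$member_id) |>
      dplyr::summarise(p_cond = 1 - prod(1 - .data$p_conv *
                                           class_frac(.data$ref_base, .data$alt_base)),
                       .groups = "drop") |>
      dplyr::right_join(dplyr::distinct(sp, .data$member_id), by = "member_id") |>
      dplyr::mutate(p_cond = tidyr::replace_na(.data$p_cond, 0))
  }
  pc <- p_member("C>T")
  pany <- p_member(c("C>T", "C>G", "C>A"))
  pa <- p_member("A>G")

  avg <- c(c2t = e * mean(pc$p_cond),
           any_c = e * mean(pany$p_cond),
           a2g = e * mean(pa$p_cond))
  # co-editing via the shared engagement latent: within an engaged read the
  # sites are independent, across reads they are coupled by engagement
  co_num <- e * sum(pc$p_cond * pa$p_cond)
  co_den <- e * sum(pc$p_cond)
  coediting <- if (co_den > 0) co_num / co_den else NA_real_

  list(profile = profile, window = win, selectivity = sel, average = avg,
       coediting = coediting,
       abe_cbe_ratio = if (avg[["c2t"]] > 0) avg[["a2g"]] / avg[["c2t"]] else NA_real_)
}
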