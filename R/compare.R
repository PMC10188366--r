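#' Total least squares fit between two editors' efficiencies
#'
#' Fits the line `y = beta * x` through the origin minimizing the sum of
#' squared orthogonal distances (errors-in-variables regression: both
#' efficiencies are measured), via the principal eigenvector of the 2x2
#' second-moment matrix. The fold change between the editors is the
#' reciprocal of the slope. With `intercept = TRUE` the data are
#' mean-centered first (a sensitivity variant; the fold-change reading then
#' only applies near the mean).
#'
#' @param x,y Paired per-member efficiencies of the two editors.
#' @param intercept Fit the mean-centered variant instead of the
#'   origin-constrained line.
#' @return An object of class `tls_fit`: `slope`, `fold_change` (= 1 /
#'   slope), `intercept`, `n` and `rms` (orthogonal residual RMS).
#' @examples
#' f <- tls_fit(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3))
#' f$fold_change # 2
#' @export
tls_fit <- function(x, y, intercept = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("at least 3 paired observations are required.")
  x0 <- x; y0 <- y
  b0 <- 0
  if (intercept) {
    x0 <- x - mean(x); y0 <- y - mean(y)
  }
  M <- crossprod(cbind(x0, y0))
  if (sum(M) == 0) abort("degenerate point cloud (all points at the origin).")
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1]  # principal axis
  if (abs(v[1]) < .Machine$double.eps) {
    abort("TLS line is vertical; the slope is undefined.")
  }
  slope <- v[2] / v[1]
  if (intercept) b0 <- mean(y) - slope * mean(x)
  structure(list(
    slope = slope,
    fold_change = if (slope != 0) 1 / slope else NA_real_,
    intercept = b0, n = n,
    rms = sqrt(max(e$values[2], 0) / n),
    x = x, y = y), class = "tls_fit")
}

#' @export
print.tls_fit <- function(x, ...) {
  cat("<tls_fit> n =", x$n, " slope =", format(x$slope, digits = 4),
      " fold change =", format(x$fold_change, digits = 4), "\n")
  invisible(x)
}

#' @method tidy tls_fit
#' @export
tidy.tls_fit <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @method glance tls_fit
#' @export
glance.tls_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, fold_change = x$fold_change,
                 intercept = x$intercept, n = x$n, rms = x$rms)
}

#' @method autoplot tls_fit
#' @export
autoplot.tls_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = "editor A efficiency", y = "editor B efficiency",
                  title = sprintf("TLS slope %.3f (fold change %.2f)",
                                  object$slope, object$fold_change)) +
    ggplot2::theme_minimal()
}

#' Compare two editors on a shared member set
#'
#' Joins the per-member efficiencies of two editors, fits the
#' origin-constrained TLS line (editor A on x, editor B on y, so the fold
#' change 1/slope is the average fold decrease from A to B) and reports
#' both editors' peak and mean member efficiencies side by side.
#'
#' @param a,b Tibbles `(member_id, efficiency)` for the two editors, e.g.
#'   from [target_efficiencies()].
#' @param labels Length-2 labels for the editors.
#' @param intercept Passed to [tls_fit()].
#' @return A list of class `editor_comparison`: `tls` (the [tls_fit()]),
#'   `summary` (per-editor peak and mean member efficiency) and `data` (the
#'   joined member table).
#' @export
compare_editors <- function(a, b, labels = c("A", "B"), intercept = FALSE) {
  for (nm in list(a, b)) {
    if (!all(c("member_id", "efficiency") %in% names(nm))) {
      abort("both inputs need columns `member_id` and `efficiency`.")
    }
  }
  if (nrow(a) == 0) abort(paste0("profile '", labels[1], "' is empty."))
  if (nrow(b) == 0) abort(paste0("profile '", labels[2], "' is empty."))
  joined <- dplyr::inner_join(a, b, by = "member_id",
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("the two profiles share no members.")
  fit <- tls_fit(joined$efficiency_a, joined$efficiency_b,
                 intercept = intercept)
  summary <- tibble::tibble(
    editor = labels,
    n_members = c(nrow(a), nrow(b)),
    peak_efficiency = c(max(a$efficiency), max(b$efficiency)),
    mean_efficiency = c(mean(a$efficiency), mean(b$efficiency)))
  structure(list(tls = fit, summary = summary, data = joined),
            class = "editor_comparison")
}

#' @export
print.editor_comparison <- function(x, ...) {
  cat("<editor_comparison> fold change (A over B):",
      format(x$tls$fold_change, digits = 4), "\n")
  print(x$summary)
  invisible(x)
}
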