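#' Stabilized logit transform
#'
#' \deqn{f(x) = \ln\frac{x + \epsilon}{1 + \epsilon - x}}
#' A logit variant that stays finite at 0 and 1; strictly increasing on
#' \[0, 1\], antisymmetric about 0.5 (`f(1 - x) = -f(x)`), and `f(0.5) = 0`
#' exactly. Efficiencies are transformed with it before the motif
#' regression, `epsilon` acting as a conservative estimate of the
#' sequencing noise floor.
#'
#' @param x Numeric vector in \[0, 1\].
#' @param epsilon Stabilization constant (default 0.001).
#' @return Natural-log transformed values.
#' @examples
#' stabilized_logit(0.5) # 0
#' stabilized_logit(0)   # about -6.909
#' @export
stabilized_logit <- function(x, epsilon = 0.001) {
  stopifnot(epsilon > 0, epsilon < 1)
  if (any(x < 0 | x > 1, na.rm = TRUE)) abort("`x` must lie in [0, 1].")
  # (1 - x) + epsilon rather than 1 + epsilon - x so that f(0.5) == 0 exactly
  log((x + epsilon) / ((1 - x) + epsilon))
}

#' One-hot encode sequence contexts
#'
#' Encodes fixed-length context strings (one base per offset) as 4
#' indicators per offset; exactly one indicator is set per offset.
#'
#' @param contexts Character vector of context strings, one character per
#'   offset, over ACGT.
#' @param offsets Integer offsets the characters correspond to (default
#'   -3..+3 excluding 0, the library's 6-mer design).
#' @return Numeric matrix with `4 * length(offsets)` columns named
#'   `"<offset>_<base>"`.
#' @export
encode_context <- function(contexts, offsets = c(-3:-1, 1:3)) {
  n_off <- length(offsets)
  if (any(nchar(contexts) != n_off)) {
    abort("every context must have one base per offset.")
  }
  if (any(!grepl("^[ACGT]+$", contexts))) abort("contexts must be ACGT only.")
  bases <- c("A", "C", "G", "T")
  X <- matrix(0, nrow = length(contexts), ncol = 4L * n_off,
              dimnames = list(NULL, paste0(rep(offsets, each = 4), "_",
                                           rep(bases, n_off))))
  for (j in seq_len(n_off)) {
    b <- substr(contexts, j, j)
    X[cbind(seq_along(contexts), (j - 1L) * 4L + match(b, bases))] <- 1
  }
  X
}

#' Extract member context strings from a library
#'
#' Reads the bases at the given offsets around each member's designed
#' substrate base.
#'
#' @param lib A library table.
#' @param offsets Integer offsets relative to the substrate base.
#' @return Tibble `(member_id, context)`.
#' @export
member_contexts <- function(lib, offsets = c(-3:-1, 1:3)) {
  lib <- validate_library(lib)
  idx <- cassette_index(lib$target_base_pos, lib$protospacer_start)
  if (any(idx + min(offsets) < 1) ||
      any(idx + max(offsets) > nchar(lib$cassette))) {
    abort("context offsets extend past the cassette.")
  }
  ctx <- vapply(seq_len(nrow(lib)), function(i) {
    paste(vapply(offsets, function(o) substr(lib$cassette[i], idx[i] + o,
                                             idx[i] + o), character(1)),
          collapse = "")
  }, character(1))
  tibble::tibble(member_id = lib$member_id, context = ctx)
}

#' Member-level efficiencies at the designed target position
#'
#' Pulls, for each member, the pooled efficiency of the given substitution
#' class at the member's designed substrate position (or at a fixed
#' position when `position` is given).
#'
#' @param pooled Pooled counts from [pool_replicates()].
#' @param lib The library table.
#' @param class Substitution class (default `"C>T"`).
#' @param position Optional fixed protospacer position; default is each
#'   member's `target_base_pos`.
#' @return Tibble `(member_id, efficiency)`, members without a defined
#'   efficiency dropped.
#' @export
target_efficiencies <- function(pooled, lib, class = "C>T", position = NULL) {
  lib <- validate_library(lib)
  want <- tibble::tibble(member_id = lib$member_id,
                         position = if (is.null(position))
                           lib$target_base_pos else as.integer(position))
  cls <- class
  pooled |>
    dplyr::inner_join(want, by = c("member_id", "position")) |>
    dplyr::filter(class_label(.data$ref_base, .data$alt_base) == .env$cls,
                  !is.na(.data$efficiency)) |>
    dplyr::select("member_id", "efficiency")
}

#' Fit a sequence-context motif by ridge regression
#'
#' Regresses stabilized-logit-transformed efficiencies on one-hot context
#' features with ridge regression (penalty `alpha` on the squared
#' coefficient norm, intercept unpenalized), after a seeded random
#' train/test split. The held-out Pearson correlation `test_r` is the motif
#' confidence (logo opacity). Reported weights are centered to mean zero
#' over the four bases within each offset, which resolves the one-hot
#' redundancy.
#'
#' @param contexts Character vector of context strings.
#' @param efficiency Numeric efficiencies in \[0, 1\], same length.
#' @param offsets Offsets the context characters correspond to.
#' @param epsilon Stabilized-logit constant (default 0.001).
#' @param alpha Ridge penalty (default 1e-5).
#' @param train_fraction Training fraction of the split (default 0.8).
#' @param seed Seed for the split.
#' @return An object of class `motif_fit`: `weights` (tibble `offset`,
#'   `base`, `weight`, centered), `intercept`, `test_r`, `coefs` (raw
#'   coefficients used for prediction) and the configuration.
#' @export
fit_motif <- function(contexts, efficiency, offsets = c(-3:-1, 1:3),
                      epsilon = 0.001, alpha = 1e-5, train_fraction = 0.8,
                      seed = 1L) {
  stopifnot(length(contexts) == length(efficiency),
            alpha > 0, train_fraction > 0, train_fraction < 1)
  n <- length(contexts)
  if (n < 50) abort("at least 50 observations are required to fit a motif.")
  if (any(efficiency < 0 | efficiency > 1)) abort("efficiencies must lie in [0, 1].")

  y <- stabilized_logit(efficiency, epsilon)
  X <- encode_context(contexts, offsets)
  bases <- c("A", "C", "G", "T")

  zero_fit <- function() {
    warn("zero-variance targets; all motif weights set to 0.")
    list(coefs = stats::setNames(rep(0, ncol(X) + 1L), c("(Intercept)", colnames(X))),
         test_r = 0)
  }

  idx_train <- withr::with_seed(seed, sample.int(n, floor(train_fraction * n)))
  idx_test <- setdiff(seq_len(n), idx_train)

  if (stats::var(y[idx_train]) == 0) {
    f <- zero_fit()
    f$coefs["(Intercept)"] <- y[idx_train][1]
  } else {
    Xt <- cbind(`(Intercept)` = 1, X[idx_train, , drop = FALSE])
    penalty <- diag(c(0, rep(alpha, ncol(X))))
    beta <- solve(crossprod(Xt) + penalty, crossprod(Xt, y[idx_train]))
    coefs <- stats::setNames(drop(beta), colnames(Xt))
    pred_test <- drop(cbind(1, X[idx_test, , drop = FALSE]) %*% beta)
    test_r <- if (stats::var(y[idx_test]) == 0 || stats::var(pred_test) == 0) {
      warn("degenerate held-out set; test_r reported as 0.")
      0
    } else {
      stats::cor(pred_test, y[idx_test])
    }
    f <- list(coefs = coefs, test_r = test_r)
  }

  raw <- f$coefs[-1]
  weights <- tibble::tibble(
    offset = as.integer(sub("_.*$", "", names(raw))),
    base = sub("^.*_", "", names(raw)),
    weight = unname(raw)) |>
    dplyr::group_by(.data$offset) |>
    dplyr::mutate(weight = .data$weight - mean(.data$weight)) |>
    dplyr::ungroup()

  structure(list(weights = weights, intercept = unname(f$coefs[1]),
                 test_r = f$test_r, coefs = f$coefs, offsets = offsets,
                 epsilon = epsilon, alpha = alpha,
                 n_train = length(idx_train), n_test = length(idx_test),
                 seed = seed),
            class = "motif_fit")
}

#' @export
print.motif_fit <- function(x, ...) {
  cat("<motif_fit>", length(x$offsets), "offsets, test R =",
      format(x$test_r, digits = 3), "\n")
  invisible(x)
}

#' Predict transformed efficiencies for new contexts
#'
#' @param object A [fit_motif()] object.
#' @param contexts Character vector of context strings.
#' @param ... Unused.
#' @return Predicted stabilized-logit values.
#' @export
predict.motif_fit <- function(object, contexts, ...) {
  X <- encode_context(contexts, object$offsets)
  drop(cbind(1, X) %*% object$coefs)
}

#' @method tidy motif_fit
#' @export
tidy.motif_fit <- function(x, ...) x$weights

#' @method glance motif_fit
#' @export
glance.motif_fit <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_test = x$n_test, test_r = x$test_r,
                 alpha = x$alpha, epsilon = x$epsilon)
}

#' Motif logo matrix
#'
#' Centered weight matrix (rows = offsets, columns = A, C, G, T) plus the
#' logo opacity, `max(test_r, 0)`.
#'
#' @param fit A [fit_motif()] object.
#' @return Numeric matrix with an `opacity` attribute.
#' @export
motif_matrix <- function(fit) {
  w <- tidyr::pivot_wider(fit$weights, names_from = "base",
                          values_from = "weight")
  m <- as.matrix(w[c("A", "C", "G", "T")])
  rownames(m) <- w$offset
  attr(m, "opacity") <- max(fit$test_r, 0)
  m
}

#' Read and write motif fits as JSON
#'
#' Round-trip serialization of the fitted weights, intercept, held-out
#' correlation and configuration.
#'
#' @param fit A `motif_fit`.
#' @param path File path.
#' @export
write_motif <- function(fit, path) {
  jsonlite::write_json(list(
    weights = fit$weights, intercept = fit$intercept, test_r = fit$test_r,
    coefs = as.list(fit$coefs), offsets = fit$offsets,
    epsilon = fit$epsilon, alpha = fit$alpha,
    n_train = fit$n_train, n_test = fit$n_test, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_motif
#' @export
read_motif <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = tibble::as_tibble(x$weights),
                 intercept = x$intercept, test_r = x$test_r,
                 coefs = unlist(x$coefs), offsets = x$offsets,
                 epsilon = x$epsilon, alpha = x$alpha,
                 n_train = x$n_train, n_test = x$n_test, seed = x$seed),
            class = "motif_fit")
}

#' @method autoplot motif_fit
#' @export
autoplot.motif_fit <- function(object, ...) {
  ggplot2::ggplot(object$weights,
                  ggplot2::aes(x = factor(.data$offset), y = .data$base,
                               fill = .data$weight)) +
    ggplot2::geom_tile(alpha = max(object$test_r, 0)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "offset from substrate base", y = NULL,
                  fill = "weight",
                  title = sprintf("context motif (test R = %.2f)", object$test_r)) +
    ggplot2::theme_minimal()
}
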