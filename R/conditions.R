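#' Reference editor models for simulated studies
#'
#' Canonical editor models used throughout the package's examples, tests
#' and the bundled acceptance analysis. All three share a C-editing window
#' profile peaking at protospacer position 6 with engaged per-site
#' conversion rates (0.20, 0.35, 0.50, 0.60, 0.40, 0.25) at positions 3-8,
#' a 2% floor elsewhere in the protospacer, which yields a ground-truth
#' editing window of positions 3-8 under the 30%-of-peak definition:
#'
#' * `cbe`: a selective cytosine editor; adenine rates are 25-fold lower at
#'   every position, so the ground-truth selectivity is exactly 25.
#' * `cbe_attenuated`: the same editor with every engaged conversion rate
#'   divided by 1.25 (the style of change a window-refining point mutation
#'   produces), giving a ground-truth per-member fold change of 1.25.
#' * `dual`: an editor with equal cytosine and adenine rate profiles and a
#'   0.5 per-read engagement probability, producing strongly correlated
#'   co-editing.
#'
#' @param floor_rate Engaged conversion rate outside the active positions
#'   (default 0.02).
#' @return Named list of [editor_model()] objects with an attribute
#'   `truth` holding the shared window positions and CBE selectivity.
#' @export
study_models <- function(floor_rate = 0.02) {
  pos <- as.character(window_positions())
  rates_c <- stats::setNames(rep(floor_rate, length(pos)), pos)
  rates_c[c("3", "4", "5", "6", "7", "8")] <- c(0.20, 0.35, 0.50, 0.60, 0.40, 0.25)
  rates_a <- rates_c / 25

  models <- list(
    cbe = editor_model(window_c = window_from_rates(rates_c),
                       window_a = window_from_rates(rates_a)),
    cbe_attenuated = editor_model(window_c = window_from_rates(rates_c / 1.25),
                                  window_a = window_from_rates(rates_a / 1.25)),
    dual = editor_model(window_c = window_from_rates(rates_c),
                        window_a = window_from_rates(rates_c),
                        engage_prob = 0.5)
  )
  attr(models, "truth") <- list(window = 3:8, selectivity = 25,
                                fold_change = 1.25)
  models
}
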