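#' Disease time-lag functions
#'
#' The mortality effect of a dietary change phases in over time following an
#' s-shaped curve: the cumulative distribution function of a normal
#' variable, rescaled on the active interval so the weight is exactly 0 up
#' to the onset delay and exactly 1 from the full-effect time onwards.
#' Cardiometabolic outcomes (coronary heart disease, stroke, type 2
#' diabetes) reach full effect after about 10 years with no onset delay;
#' cancers reach full effect after about 30 years with no change in risk for
#' the first 10 years. The normal-CDF parameters on the active interval are
#' configurable (defaults: mean 5, sd 2 years for cardiometabolic; mean 20,
#' sd 3.3 years for cancers). An `"instant"` class (weight 1 for any t > 0)
#' is available for lag-free analyses.
#'
#' @param disease_class `"cardiometabolic"`, `"cancer"` or `"instant"`.
#' @param onset_delay,full_effect_time,mean,sd Override the class defaults
#'   (all in years).
#' @return A list with class `lag_function`.
#' @export
#' @examples
#' lag_weight(lag_function("cancer"), 10)           # 0
#' lag_weight(lag_function("cardiometabolic"), 10)  # 1
lag_function <- function(disease_class = c("cardiometabolic", "cancer",
                                           "instant"),
                         onset_delay = NULL, full_effect_time = NULL,
                         mean = NULL, sd = NULL) {
  disease_class <- match.arg(disease_class)
  def <- switch(disease_class,
                cardiometabolic = list(onset = 0, full = 10, mean = 5, sd = 2),
                cancer = list(onset = 10, full = 30, mean = 20, sd = 3.3),
                instant = list(onset = 0, full = 0, mean = 0, sd = 1))
  out <- list(disease_class = disease_class,
              onset_delay = onset_delay %||% def$onset,
              full_effect_time = full_effect_time %||% def$full,
              mean = mean %||% def$mean, sd = sd %||% def$sd)
  if (out$onset_delay > out$full_effect_time)
    abort("onset delay cannot exceed the full-effect time.")
  structure(out, class = "lag_function")
}

#' Evaluate a lag weight
#'
#' @param lag A [lag_function()].
#' @param t Years since the dietary change was adopted (vectorised, >= 0).
#' @return Weights in \[0, 1\]: 0 for `t <= onset_delay`, 1 for
#'   `t >= full_effect_time` (and for any `t > 0` for the `"instant"`
#'   class), a rescaled normal CDF in between. Continuous and
#'   non-decreasing.
#' @export
lag_weight <- function(lag, t) {
  stopifnot(inherits(lag, "lag_function"))
  if (any(t < 0)) abort("`t` must be non-negative.")
  on <- lag$onset_delay; full <- lag$full_effect_time
  if (full <= on) return(as.numeric(t > on))       # instant switch
  lo <- pnorm((on - lag$mean) / lag$sd)
  hi <- pnorm((full - lag$mean) / lag$sd)
  w <- (pnorm((t - lag$mean) / lag$sd) - lo) / (hi - lo)
  pmin(pmax(ifelse(t <= on, 0, ifelse(t >= full, 1, w)), 0), 1)
}

#' Default disease-to-lag-class assignment
#'
#' Coronary heart disease, stroke and type 2 diabetes are cardiometabolic
#' (10-year phase-in); diseases whose name contains "cancer" follow the
#' cancer lag (10-year onset delay, 30-year phase-in).
#'
#' @param diseases Character vector of disease labels.
#' @param instant If `TRUE`, assign the instant (lag-free) class to all.
#' @return A named list of [lag_function()] objects.
#' @export
default_lags <- function(diseases, instant = FALSE) {
  purrr::map(setNames(diseases, diseases), function(d) {
    if (instant) lag_function("instant")
    else if (grepl("cancer", d)) lag_function("cancer")
    else lag_function("cardiometabolic")
  })
}
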