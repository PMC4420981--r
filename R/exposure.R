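#' Scale a relative risk to an arbitrary intake change
#'
#' Exposure-response functions are log-linear: a relative risk `rr` per
#' `increment_g` grams/day scales to `rr^(delta / increment_g)` for a signed
#' change `delta`. A zero change gives 1 and the scaling is sign-symmetric,
#' `scale_rr(-d) = 1 / scale_rr(d)`.
#'
#' @param erf One ERF row (list or one-row tibble with `rr`, `rr_low`,
#'   `rr_high`, `increment_g`).
#' @param delta Signed intake change in g/day.
#' @param which Which RR to scale: `"central"` (default), or the CI bound
#'   giving the `"low"`-impact or `"high"`-impact estimate. The low-impact
#'   bound is the CI bound nearer 1 (least effect on mortality); the
#'   high-impact bound is the farther one.
#' @return A positive hazard multiplier.
#' @export
#' @examples
#' fruit_chd <- list(rr = 0.93, rr_low = 0.89, rr_high = 0.96, increment_g = 80)
#' scale_rr(fruit_chd, 80)    # 0.93
#' scale_rr(fruit_chd, 160)   # 0.93^2
scale_rr <- function(erf, delta, which = c("central", "low", "high")) {
  which <- match.arg(which)
  rr <- pick_rr(erf, which)
  if (rr <= 0) abort("relative risks must be positive.")
  if (erf$increment_g <= 0) abort("reference increment must be positive.")
  rr^(delta / erf$increment_g)
}

## "low" = CI bound nearest 1 on the log scale (weakest effect),
## "high" = farthest bound (strongest effect), for protective and harmful
## RRs alike.
pick_rr <- function(erf, which) {
  if (which == "central") return(erf$rr)
  b <- c(erf$rr_low, erf$rr_high)
  near <- b[which.min(abs(log(b)))]
  far <- b[which.max(abs(log(b)))]
  if (which == "low") near else far
}

#' Combine per-exposure multipliers for one disease
#'
#' When several dietary exposures affect the same disease their hazard
#' multipliers are multiplied together. The empty product is 1.
#'
#' @param multipliers Numeric vector of positive multipliers.
#' @param disease Optional disease label attached to the result.
#' @param sex Optional sex label attached to the result.
#' @return A one-row tibble with `disease`, `sex`, `value`.
#' @export
combine_multipliers <- function(multipliers, disease = NA_character_,
                                sex = NA_character_) {
  if (length(multipliers) && any(multipliers <= 0))
    abort("hazard multipliers must be positive.")
  tibble::tibble(disease = disease, sex = sex,
                 value = prod(multipliers))
}

#' Exposure changes implied by a diet scenario
#'
#' Sums the change in consumption over the groups carrying each exposure
#' tag (fruit, vegetable, red meat, processed meat); groups tagged `other`
#' contribute nothing.
#'
#' @param scenario A `diet_scenario` from [optimise_diet()].
#' @return A tibble with `sex`, `exposure`, `delta_g` (signed g/day).
#' @export
deltas_from_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "diet_scenario"))
  tibble::tibble(exposure = scenario$exposure,
                 change = unname(scenario$x - scenario$baseline)) |>
    dplyr::filter(.data$exposure != "other") |>
    dplyr::group_by(.data$exposure) |>
    dplyr::summarise(delta_g = sum(.data$change), .groups = "drop") |>
    dplyr::mutate(sex = scenario$sex %||% NA_character_, .before = 1)
}

#' Per-disease hazard multipliers from exposure changes
#'
#' Applies [scale_rr()] to every ERF row matching an observed exposure
#' change and multiplies within disease ([combine_multipliers()]). Diseases
#' with no matching ERF (or whose exposures are all masked) get multiplier
#' 1. Masking exposures supports structural sensitivity analyses in which
#' only fruit or only vegetable effects are counted.
#'
#' @param deltas Tibble from [deltas_from_scenario()] (`exposure`, `delta_g`,
#'   optionally `sex`).
#' @param erfs ERF tibble, e.g. [generate_erf_table()].
#' @param which `"central"`, `"low"` or `"high"` (CI-based impact bound,
#'   see [scale_rr()]).
#' @param mask_exposures Character vector of exposure tags whose effects are
#'   ignored (multiplier contributions forced to 1).
#' @param diseases Diseases to report; defaults to those in `erfs`.
#' @return A tibble with `disease`, `sex`, `value` (> 0), the full-effect
#'   (un-lagged) multiplier per disease.
#' @export
hazard_multipliers <- function(deltas, erfs, which = "central",
                               mask_exposures = character(0),
                               diseases = NULL) {
  validate_erf_table(erfs)
  diseases <- diseases %||% unique(erfs$disease)
  sx <- if ("sex" %in% names(deltas)) unique(deltas$sex) else NA_character_
  if (length(sx) > 1) abort("`deltas` mixes sexes; supply one sex at a time.")
  purrr::map(diseases, function(d) {
    rows <- dplyr::filter(erfs, .data$disease == d,
                          !(.data$exposure %in% mask_exposures))
    mult <- purrr::pmap_dbl(rows, function(exposure, ...) {
      erf <- list(...)
      dd <- deltas$delta_g[deltas$exposure == exposure]
      if (length(dd) == 0) return(1)
      scale_rr(erf, dd, which = which)
    })
    combine_multipliers(mult, disease = d, sex = sx)
  }) |>
    dplyr::bind_rows()
}
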