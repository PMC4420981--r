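#' Plot a scenario sweep
#'
#' Two-panel figure: total YLL averted per horizon and the deviation index
#' (acceptability proxy: the optimiser objective at the solution) against
#' the achieved GHG reduction. The deviation index typically stays flat up
#' to moderate targets and rises steeply for radical ones.
#'
#' @param object A `diet_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diet_sweep
#' @export
autoplot.diet_sweep <- function(object, ...) {
  sm <- dplyr::filter(object$summary, is.na(.data$error))
  yll <- dplyr::filter(object$impacts, .data$disease == "total") |>
    dplyr::left_join(dplyr::select(sm, "target", "achieved"), by = "target")
  dev <- dplyr::transmute(sm, achieved = .data$achieved,
                          horizon = NA_integer_,
                          value = .data$objective,
                          panel = "deviation index")
  dat <- dplyr::bind_rows(
    dplyr::transmute(yll, achieved = .data$achieved, horizon = .data$horizon,
                     value = .data$yll, panel = "YLL averted"),
    dev
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = 100 * .data$achieved,
                                    y = .data$value,
                                    colour = factor(.data$horizon))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "achieved GHG reduction (%)", y = NULL,
                  colour = "horizon (y)") +
    ggplot2::theme_minimal()
}

#' Plot per-disease impacts across the target ladder
#'
#' @param sweep A `diet_sweep`.
#' @param horizon Which horizon to plot (default the largest).
#' @return A ggplot object.
#' @export
plot_disease_impacts <- function(sweep, horizon = max(sweep$horizons)) {
  stopifnot(inherits(sweep, "diet_sweep"))
  dat <- dplyr::filter(sweep$impacts, .data$disease != "total",
                       .data$horizon == .env$horizon) |>
    dplyr::mutate(target_label = ifelse(is.na(.data$target), "none",
                                        paste0(100 * .data$target, "%")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$target_label, y = .data$yll,
                                    fill = .data$disease)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "GHG reduction target",
                  y = sprintf("YLL averted over %d years", horizon),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diet scenario's changes by food group
#'
#' @param object A `diet_scenario` from [optimise_diet()].
#' @param ... Unused.
#' @return A ggplot object of percentage changes, coloured by exposure tag.
#' @method autoplot diet_scenario
#' @export
autoplot.diet_scenario <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$group_id,
                                                       .data$pct_change),
                                    y = .data$pct_change,
                                    fill = .data$exposure)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% change from baseline", fill = NULL) +
    ggplot2::theme_minimal()
}
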