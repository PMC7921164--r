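#' Plot a simulation result
#'
#' Faceted state trajectories over time.
#'
#' @param object a `simulation_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot simulation_result
#' @export
autoplot.simulation_result <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$kind == "state")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "amount / concentration")
}

#' Plot an estimated trajectory solution
#'
#' Parameter trajectories (relative to baseline) or any other quantity kind
#' over the segment grid.
#'
#' @param object an `adapt_solution`.
#' @param kind one of "parameter", "state", "flux", "output".
#' @param relative divide each trajectory by its baseline value (parameters
#'   only; default TRUE).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot adapt_solution
#' @export
autoplot.adapt_solution <- function(object, kind = "parameter",
                                    relative = kind == "parameter", ...) {
  df <- tidy(object) |> dplyr::filter(.data$kind == !!kind)
  if (relative) {
    df <- df |>
      dplyr::group_by(.data$name) |>
      dplyr::mutate(value = .data$value / .data$value[1]) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "time (days)",
                  y = if (relative) "value / baseline" else "value")
}

#' Plot ensemble summaries of selected quantities
#'
#' Median line with the central-95% band across the ensemble's solutions.
#'
#' @param object a `solution_ensemble`.
#' @param quantities quantity names (default: the states).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot solution_ensemble
#' @export
autoplot.solution_ensemble <- function(object, quantities = NULL, ...) {
  first <- object$solutions[[which(!vapply(object$solutions, is.null, TRUE))[1]]]
  if (is.null(quantities)) quantities <- rownames(first$states)
  df <- dplyr::bind_rows(lapply(quantities, function(q) {
    dplyr::mutate(ensemble_summary(object, q), quantity = q, .before = 1)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "median and central 95% band")
}

#' Variance-reduction heat map
#'
#' Quantity-by-time tile map of `1 - Var_group / Var_reference`, the display
#' used to show which model estimates the gene data effectively constrains.
#' Negative values are clipped to 0 for display only.
#'
#' @param vr tibble with columns `quantity, time, vr` (e.g. stacked
#'   [variance_reduction()] results).
#' @return a ggplot object.
#' @export
plot_variance_reduction <- function(vr) {
  stopifnot(all(c("quantity", "time", "vr") %in% names(vr)))
  vr$vr_display <- pmin(pmax(vr$vr, 0), 1)
  ggplot2::ggplot(vr, ggplot2::aes(.data$time, .data$quantity,
                                   fill = .data$vr_display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1), name = "VR") +
    ggplot2::labs(x = "time (days)", y = NULL)
}
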