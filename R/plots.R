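#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_errorbar geom_col labs theme_minimal scale_x_log10 scale_y_log10
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot a calibration curve fit
#'
#' Observed responses against nominal concentrations on log-log axes, with
#' the fitted curve and the LLOQ/ULOQ bracket.
#'
#' @param object An `sq_curvefit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sq_curvefit
#' @export
autoplot.sq_curvefit <- function(object, ...) {
  s <- object$series
  grid <- tibble::tibble(
    nominal_conc = exp(seq(log(min(s$nominal_conc)),
                           log(max(s$nominal_conc)), length.out = 200)))
  grid$response <- predict_response(object, grid$nominal_conc)
  ggplot(s, aes(x = .data$nominal_conc, y = .data$response)) +
    geom_line(data = grid, color = "grey40") +
    geom_point() +
    scale_x_log10() + scale_y_log10() +
    labs(x = "nominal concentration", y = "response (area ratio)",
         title = sprintf("%s / %s / %s  R² = %.4f",
                         object$model, object$transform, object$weighting,
                         object$r_squared),
         subtitle = sprintf("LLOQ %s, ULOQ %s", format(object$lloq),
                            format(object$uloq))) +
    theme_minimal()
}

#' Plot reference medians with credibility intervals
#'
#' @param object An `sq_reffit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sq_reffit
#' @export
autoplot.sq_reffit <- function(object, ...) {
  est <- object$estimates
  ggplot(est, aes(x = stats::reorder(.data$hmdb_id, .data$posterior_median),
                  y = .data$posterior_median)) +
    geom_errorbar(aes(ymin = .data$cri_lower, ymax = .data$cri_upper),
                  width = 0.2) +
    geom_point() +
    scale_y_log10() +
    labs(x = NULL, y = "population median (µmol/L)",
         title = "Reference medians with 95% credibility intervals") +
    theme_minimal() +
    ggplot2::coord_flip()
}

#' QC drift control chart
#'
#' Per-batch mean QC concentration over time for each metabolite, a visual
#' companion to [compare_to_history()].
#'
#' @param history QC history tibble.
#' @param hmdb_ids Optional subset of metabolites.
#' @return A ggplot object.
#' @export
plot_qc_history <- function(history, hmdb_ids = NULL) {
  if (!is.null(hmdb_ids)) history <- dplyr::filter(history, .data$hmdb_id %in% hmdb_ids)
  per_batch <- history |>
    dplyr::group_by(.data$hmdb_id, .data$batch_id, .data$qc_lot) |>
    dplyr::summarise(run_date = min(.data$run_date),
                     mean_conc = mean(.data$conc_umol_l, na.rm = TRUE),
                     .groups = "drop")
  ggplot(per_batch, aes(x = .data$run_date, y = .data$mean_conc,
                        color = .data$qc_lot)) +
    geom_point() + geom_line(aes(group = 1), alpha = 0.3) +
    facet_wrap(~hmdb_id, scales = "free_y") +
    labs(x = "run date", y = "QC mean concentration (µmol/L)",
         color = "QC lot") +
    theme_minimal()
}
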