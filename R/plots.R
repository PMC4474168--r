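#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated profile
#'
#' Free-drug concentration on a log scale and, for full-model simulations,
#' target occupancy, as stacked panels over time.
#'
#' @param object A `tmdd_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmdd_sim <- function(object, ...) {
  df <- tibble::as_tibble(object)
  panels <- dplyr::bind_rows(
    tibble::tibble(time = df$time,
                   value = ifelse(df$conc > 0, df$conc, NA_real_),
                   panel = "free drug (nmol/l)"),
    if ("occupancy" %in% names(df)) {
      tibble::tibble(time = df$time, value = df$occupancy,
                     panel = "target occupancy")
    }
  )
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Child/adult exposure ratios across the dose axis
#'
#' Line plot of the AUC ratio versus the 18-year reference against nominal
#' dose, one line per age group, faceted by target level, for one
#' (target policy, dose policy, model kind) slice of a scenario table.
#'
#' @param table A `scenario_table` from [run_grid()].
#' @param target_policy,dose_policy,model_kind Slice selectors.
#' @return A ggplot object.
#' @export
plot_auc_ratios <- function(table, target_policy = "same_concentration",
                            dose_policy = "per_kg", model_kind = "tmdd") {
  df <- dplyr::filter(
    tibble::as_tibble(table),
    .data$target_policy == !!target_policy,
    .data$dose_policy == !!dose_policy,
    .data$model_kind == !!model_kind
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nominal_dose,
                                   y = .data$auc_ratio_vs_18y,
                                   colour = .data$age_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::facet_wrap(~target_level, labeller = ggplot2::label_both) +
    ggplot2::labs(x = paste0("nominal dose (",
                             if (dose_policy == "per_kg") "mg/kg" else "mg",
                             ")"),
                  y = "AUC ratio vs 18-year group (%)",
                  colour = "age group") +
    ggplot2::theme_minimal()
}
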