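# ggplot2 views of the main result types.

#' Plot ensemble resilience curves
#'
#' Lost-patient fraction and remaining relative free capacity against the
#' fraction of physicians removed, one line per federal state, with
#' ensemble-SD ribbons and the critical-limit guide lines (1% lost patients,
#' 20% remaining free capacity).
#'
#' @param object A `resilience_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resilience_curves <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(tibble::as_tibble(object), .data$region,
                     .data$frac_removed, observable = "lost patients",
                     mean = .data$lost_mean, sd = .data$lost_sd),
    dplyr::transmute(tibble::as_tibble(object), .data$region,
                     .data$frac_removed, observable = "free capacity",
                     mean = .data$free_capacity_mean,
                     sd = .data$free_capacity_sd)
  )
  guides <- data.frame(observable = c("lost patients", "free capacity"),
                       y = c(0.01, 0.20))
  ggplot2::ggplot(long, ggplot2::aes(.data$frac_removed, .data$mean,
                                     colour = .data$region,
                                     fill = .data$region)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = guides, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "fraction of physicians removed", y = NULL,
                  colour = "state", fill = "state") +
    ggplot2::theme_minimal()
}

#' Plot shock-recovery curves
#'
#' Number of patients with an active physician over the displacement rounds
#' following a single large shock, one line per replicate (country-wide
#' totals).
#'
#' @param object A `shock_trajectories` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shock_trajectories <- function(object, ...) {
  tot <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$replicate, .data$step),
    located = sum(.data$located), .groups = "drop")
  ggplot2::ggplot(tot, ggplot2::aes(.data$step, .data$located,
                                    group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "displacement step after shock",
                  y = "patients with an active physician") +
    ggplot2::theme_minimal()
}

#' Risk-benefit score map per physician
#'
#' @param risk Output of [risk_scores()].
#' @param benefit Output of [benefit_scores()].
#' @return A ggplot object: benefit against risk, coloured by state.
#' @export
plot_risk_benefit <- function(risk, benefit) {
  d <- dplyr::inner_join(tibble::as_tibble(risk),
                         dplyr::select(tibble::as_tibble(benefit), "node_id",
                                       "benefit"),
                         by = "node_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$risk, .data$benefit,
                                  colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "risk score", y = "benefit score", colour = "state") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
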