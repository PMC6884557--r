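# ggplot2 views of the observable tables. Each plot_* takes the tidy tibble
# produced by the matching observable function, so plots compose with dplyr
# filtering in a pipe.

.cond_label <- function(df) {
  interaction(paste0("eps=", df$pore_epsilon),
              paste0("Rp=", df$pore_radius),
              paste0("f=", df$pull_force), sep = ", ")
}

#' Plot per-monomer mean waiting times
#'
#' @param wt tibble from [waiting_times()].
#' @return A ggplot object.
#' @export
plot_waiting_times <- function(wt) {
  wt$condition <- .cond_label(wt)
  ggplot2::ggplot(wt, ggplot2::aes(x = .data$s, y = .data$waiting_time,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "monomer number s", y = "mean waiting time (t_LJ)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative mean exit-time curves
#'
#' @param curves tibble from [exit_time_curves()].
#' @return A ggplot object.
#' @export
plot_exit_time_curves <- function(curves) {
  curves$condition <- .cond_label(curves)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$s, y = .data$mean_exit_time,
                                       colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "monomer number s",
                  y = "cumulative mean exit time (t_LJ)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot translocation time against pore interaction energy
#'
#' @param summary tibble from [translocation_time_summary()] (typically over
#'   a sweep of `pore_epsilon`).
#' @return A ggplot object.
#' @export
plot_translocation_times <- function(summary) {
  summary$radius <- factor(summary$pore_radius)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$pore_epsilon, y = .data$mean_tau,
                               colour = .data$radius, group = .data$radius)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pull_force, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "pore interaction energy (eps0)",
                  y = "mean translocation time (t_LJ)",
                  colour = "pore radius (sigma)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pt_ensemble <- function(object, ...) {
  plot_waiting_times(waiting_times(object))
}
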