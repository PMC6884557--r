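#' Tidy a translocation ensemble into long per-monomer exit times
#'
#' One row per (event, s): the condition columns, the event index and the
#' first-passage time (t_LJ since release) of monomer s.
#'
#' @param x a `pt_ensemble` from [run_ensemble()].
#' @param ... unused.
#' @return A tibble with columns `pore_radius`, `pore_epsilon`,
#'   `pull_force`, `event`, `s`, `exit_time`.
#' @export
tidy.pt_ensemble <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(c(.cond_vars, "event", "exit_times"))) |>
    tidyr::unnest_longer("exit_times", values_to = "exit_time",
                         indices_to = "s") |>
    dplyr::relocate("s", .before = "exit_time")
}

#' One-row-per-condition summary of a translocation ensemble
#'
#' @inheritParams tidy.pt_ensemble
#' @return A tibble with the condition columns, event counts, mean/sd of the
#'   translocation time, the mean equilibration time and the total number of
#'   discarded (retracted or failed) attempts.
#' @export
glance.pt_ensemble <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.cond_vars))) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_tau = mean(.data$total_time),
                     sd_tau = sd(.data$total_time),
                     mean_equil_time = mean(.data$equil_time),
                     n_discarded = sum(.data$n_discarded),
                     .groups = "drop")
}

#' @export
print.pt_ensemble <- function(x, ...) {
  cat(sprintf("<pt_ensemble> %d completed translocation events\n", nrow(x)))
  NextMethod()
}
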