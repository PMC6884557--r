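# Analysis of event collections: per-monomer first-passage statistics,
# crossing points of cumulative curves, centre-of-mass trajectory, and the
# two shape descriptors (aspect ratio alpha, shape factor delta).

.check_ensemble <- function(ensemble) {
  if (!inherits(ensemble, "pt_ensemble") && !is.data.frame(ensemble))
    stop("expected a pt_ensemble tibble")
  if (nrow(ensemble) == 0) stop("empty event collection")
  invisible(ensemble)
}

.cond_vars <- c("pore_radius", "pore_epsilon", "pull_force")

#' Mean exit-time (cumulative waiting-time) curves
#'
#' For each condition and each reaction coordinate s (number of monomers
#' already on the trans side), the mean over events of the first-passage
#' time of monomer s.
#'
#' @param ensemble a `pt_ensemble` tibble from [run_ensemble()].
#' @return Tibble with the condition columns, `s`, `mean_exit_time`, `n`.
#' @export
exit_time_curves <- function(ensemble) {
  .check_ensemble(ensemble)
  tidy(ensemble) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.cond_vars, "s")))) |>
    dplyr::summarise(mean_exit_time = mean(.data$exit_time),
                     n = dplyr::n(), .groups = "drop")
}

#' Per-monomer mean waiting times
#'
#' The mean waiting time at reaction coordinate s is the difference between
#' the event-averaged first-exit times of monomers s + 1 and s, for
#' s = 1..N-1. By construction the waiting times telescope back to the
#' cumulative curve exactly.
#'
#' @inheritParams exit_time_curves
#' @return Tibble with the condition columns, `s`, `waiting_time`, `n`.
#' @export
waiting_times <- function(ensemble) {
  exit_time_curves(ensemble) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.cond_vars))) |>
    dplyr::arrange(.data$s, .by_group = TRUE) |>
    dplyr::reframe(s = .data$s[-length(.data$s)],
                   waiting_time = diff(.data$mean_exit_time),
                   n = .data$n[-length(.data$n)])
}

#' First crossing point of two per-s curves
#'
#' Smallest s at which the sign of `curve_a - curve_b` differs from its sign
#' at s = 1; an exact tie counts as a crossing at that s. `NA` if the curves
#' never cross.
#'
#' @param curve_a,curve_b equal-length numeric vectors indexed by s = 1, 2,
#'   ...
#' @return Integer s of the first crossing, or `NA_integer_`.
#' @export
crossing_index <- function(curve_a, curve_b) {
  stopifnot(length(curve_a) == length(curve_b), length(curve_a) >= 1)
  d <- curve_a - curve_b
  s0 <- sign(d[1])
  if (s0 == 0) return(1L)
  hit <- which(sign(d) != s0)
  if (length(hit)) as.integer(hit[1]) else NA_integer_
}

#' Crossing-point report between two pore interaction energies
#'
#' For each (pore radius, force) pair present at both interaction energies,
#' the first s at which the cumulative mean exit-time curve of `eps_b`
#' crosses that of `eps_a`. With a strongly attractive pore the early
#' monomers are pulled through faster but the late ones are held back, so
#' the curves cross at a radius-dependent s.
#'
#' @inheritParams exit_time_curves
#' @param eps_a,eps_b the two pore interaction energies to compare.
#' @return Tibble with `pore_radius`, `pull_force`, `eps_a`, `eps_b`,
#'   `crossing_s`.
#' @export
crossing_report <- function(ensemble, eps_a = 1, eps_b = 8) {
  curves <- exit_time_curves(ensemble)
  pairs <- curves |>
    dplyr::distinct(.data$pore_radius, .data$pull_force)
  purrr::pmap_dfr(pairs, function(pore_radius, pull_force) {
    a <- curves |>
      dplyr::filter(.data$pore_radius == !!pore_radius,
                    .data$pull_force == !!pull_force,
                    .data$pore_epsilon == eps_a) |>
      dplyr::arrange(.data$s)
    b <- curves |>
      dplyr::filter(.data$pore_radius == !!pore_radius,
                    .data$pull_force == !!pull_force,
                    .data$pore_epsilon == eps_b) |>
      dplyr::arrange(.data$s)
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    tibble::tibble(pore_radius = pore_radius, pull_force = pull_force,
                   eps_a = eps_a, eps_b = eps_b,
                   crossing_s = crossing_index(b$mean_exit_time,
                                               a$mean_exit_time))
  })
}

#' Centre of mass (x component)
#'
#' Mass-uniform mean of the bead x coordinates.
#'
#' @param positions N x 3 coordinate matrix, or a [polymer_state()].
#' @return Scalar x coordinate.
#' @export
com_x <- function(positions) {
  if (inherits(positions, "polymer_state")) positions <- positions$positions
  mean(positions[, 1])
}

#' Per-s observable series from snapshotted ensembles
#'
#' `com_vs_s()`, `alpha_vs_s()` and `delta_vs_s()` average, at each reaction
#' coordinate s, an observable evaluated on the configuration snapshot taken
#' at the first-passage instant of monomer s, across all events of each
#' condition. The ensemble must have been produced with
#' `record_snapshots = TRUE`; s values with no snapshot are flagged by
#' `n = 0` and `NA`.
#'
#' @inheritParams exit_time_curves
#' @param geom a [membrane_geometry()] (needed for alpha, which is measured
#'   relative to the pore axis and the trans exit plane).
#' @return Tibble with the condition columns, `s`, the mean observable, `n`.
#' @name per_s_series
NULL

.snapshot_series <- function(ensemble, fn, value_name) {
  .check_ensemble(ensemble)
  if (!"snapshots" %in% names(ensemble) ||
      all(purrr::map_lgl(ensemble$snapshots, is.null)))
    stop("ensemble has no snapshots; rerun with record_snapshots = TRUE")
  n_mono <- attr(ensemble, "n_monomers") %||%
    length(ensemble$exit_times[[1]])
  long <- ensemble |>
    dplyr::mutate(.vals = purrr::map(.data$snapshots, function(snaps) {
      purrr::map_dbl(seq_len(n_mono), function(s) {
        snap <- snaps[[s]]
        if (is.null(snap)) NA_real_ else fn(snap)
      })
    })) |>
    dplyr::select(dplyr::all_of(.cond_vars), "event", ".vals") |>
    tidyr::unnest_longer(".vals", values_to = "value", indices_to = "s")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.cond_vars, "s")))) |>
    dplyr::summarise(
      !!value_name := if (any(is.finite(.data$value)))
        mean(.data$value[is.finite(.data$value)]) else NA_real_,
      n = sum(is.finite(.data$value)), .groups = "drop")
}

#' @rdname per_s_series
#' @export
com_vs_s <- function(ensemble) {
  .snapshot_series(ensemble, function(p) mean(p[, 1]), "mean_com_x")
}

#' Aspect ratio of the translocated monomer cloud
#'
#' Over the beads already on the trans side: `alpha = dx / (2 r)` with `dx`
#' the maximal axial protrusion beyond the trans exit plane and the lateral
#' scale `sqrt(y_max^2 + z_max^2)` built from the maximal offsets from
#' the pore axis. Large alpha means a rod-like plume along the pore axis,
#' small alpha a pancake spread over the exit plane.
#'
#' @inheritParams com_x
#' @param geom a [membrane_geometry()].
#' @return Scalar alpha; `NA` (with a warning) if no bead is on the trans
#'   side.
#' @export
aspect_ratio_alpha <- function(positions, geom) {
  if (inherits(positions, "polymer_state")) positions <- positions$positions
  trans <- positions[, 1] > geom$trans_plane_x
  if (!any(trans)) {
    warning("no beads on the trans side; alpha undefined")
    return(NA_real_)
  }
  p <- positions[trans, , drop = FALSE]
  dx <- max(p[, 1]) - geom$trans_plane_x
  y_max <- max(abs(p[, 2] - geom$pore_center[2]))
  z_max <- max(abs(p[, 3] - geom$pore_center[3]))
  dx / (2 * sqrt(y_max^2 + z_max^2))
}

#' @rdname per_s_series
#' @export
alpha_vs_s <- function(ensemble, geom) {
  .snapshot_series(ensemble,
                   function(p) suppressWarnings(aspect_ratio_alpha(p, geom)),
                   "mean_alpha")
}

#' Shape factor: gyration radius over Kirkwood hydrodynamic radius
#'
#' Computed over all beads (cis and trans): `delta = R_g / R_h` with `R_g`
#' the root-mean-square bead distance from the centroid and `R_h` the
#' Kirkwood estimate `R_h^-1 = N^-2 sum_{i != j} 1/r_ij`. On the anchor
#' scale of the descriptor, compact-globule configurations sit near the
#' uniform-sphere limit 0.77 (= sqrt(3/5), gyration over geometric radius)
#' and elongated rods near 4.
#'
#' @inheritParams com_x
#' @return Scalar delta.
#' @seealso [delta_sphere_anchor()]
#' @export
shape_factor_delta <- function(positions) {
  if (inherits(positions, "polymer_state")) positions <- positions$positions
  n <- nrow(positions)
  if (n < 2) stop("shape factor needs at least 2 beads")
  d <- as.matrix(stats::dist(positions))
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop("coincident beads: pairwise distance zero")
  ctr <- colMeans(positions)
  rg <- sqrt(mean(rowSums(sweep(positions, 2, ctr)^2)))
  rh <- 1 / (2 * sum(1 / off) / n^2)   # sum over ordered pairs = 2 * upper
  rg / rh
}

#' @rdname per_s_series
#' @export
delta_vs_s <- function(ensemble) {
  .snapshot_series(ensemble, shape_factor_delta, "mean_delta")
}

#' Compact-sphere anchor of the shape factor
#'
#' Closed-form ratio of a uniform ball's gyration radius to its geometric
#' (Stokes) radius: R_g^2 of a uniform ball of radius R is (3/5) R^2, so the
#' ratio is sqrt(3/5) = 0.7746, printed as 0.77 on the descriptor's anchor
#' scale. The rod end of the scale sits at 4.0.
#'
#' @return sqrt(3/5).
#' @export
delta_sphere_anchor <- function() sqrt(3 / 5)

#' Translocation-time summary per condition
#'
#' @inheritParams exit_time_curves
#' @return Tibble with the condition columns, `n`, `mean_tau`, `sd_tau`
#'   (`NA` for a single event).
#' @export
translocation_time_summary <- function(ensemble) {
  .check_ensemble(ensemble)
  ensemble |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.cond_vars))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_tau = mean(.data$total_time),
                     sd_tau = sd(.data$total_time), .groups = "drop")
}

#' Binned translocation-time histogram per condition
#'
#' @inheritParams exit_time_curves
#' @param bins number of bins (shared breaks across conditions).
#' @return Tibble with the condition columns, `bin_mid`, `count`.
#' @export
translocation_time_histogram <- function(ensemble, bins = 30) {
  .check_ensemble(ensemble)
  rng <- range(ensemble$total_time)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  ensemble |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.cond_vars))) |>
    dplyr::reframe(bin_mid = mids,
                   count = as.numeric(table(cut(.data$total_time, breaks,
                                                include.lowest = TRUE))))
}
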