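# Sweep layer: condition grids, incremental on-disk event production
# (resumable by condition), and re-analysis of stored event files. Tables
# are plain CSV, manifests JSON, so a production run is inspectable with
# nothing but a text editor.

#' Build a sweep plan over (pore radius, interaction energy, force)
#'
#' Defaults reproduce the studied grid: nine interaction energies (0.1 and
#' 1 through 8), four pore radii (diameters 3--6 sigma) and two forces.
#'
#' @param pore_radius,pore_epsilon,pull_force condition values; the grid is
#'   their Cartesian product.
#' @param n_events completed events per condition.
#' @param base_seed base RNG seed.
#' @param preset `"desk"` (25 events, quick-look) or `"production"` (1500 events,
#'   production scale); an explicit `n_events` overrides the preset.
#' @param base_params a [simulation_parameters()] supplying all non-swept
#'   fields.
#' @return A `sweep_plan` list: `grid` tibble (unique conditions),
#'   `n_events`, `base_seed`, `base_params`.
#' @export
sweep_plan <- function(pore_radius = c(1.5, 2, 2.5, 3),
                       pore_epsilon = c(0.1, 1, 2, 3, 4, 5, 6, 7, 8),
                       pull_force = c(1, 2),
                       n_events = NULL, base_seed = 1L,
                       preset = c("desk", "production"),
                       base_params = simulation_parameters()) {
  preset <- match.arg(preset)
  if (is.null(n_events)) n_events <- if (preset == "desk") 25L else 1500L
  if (n_events < 1L) stop("n_events must be >= 1")
  grid <- tidyr::expand_grid(pore_radius = pore_radius,
                             pore_epsilon = pore_epsilon,
                             pull_force = pull_force)
  if (anyDuplicated(grid)) stop("sweep conditions must be unique")
  structure(list(grid = grid, n_events = as.integer(n_events),
                 base_seed = as.integer(base_seed),
                 base_params = base_params),
            class = "sweep_plan")
}

#' @export
print.sweep_plan <- function(x, ...) {
  cat(sprintf("<sweep_plan> %d conditions x %d events (seed %d)\n",
              nrow(x$grid), x$n_events, x$base_seed))
  print(x$grid, n = 8)
  invisible(x)
}

.condition_tag <- function(r, eps, f) {
  sprintf("rp%s_eps%s_f%s", format(r), format(eps), format(f))
}

#' Run a sweep, streaming event tables to disk
#'
#' One wide CSV per condition (`events_<tag>.csv`: event bookkeeping columns
#' plus the N exit times `t1..tN`) and a `manifest.json` recording the plan,
#' seeds and package version. A condition whose file already holds the
#' requested number of events is skipped, so interrupted sweeps resume and
#' re-running a finished sweep is a no-op.
#'
#' @param plan a [sweep_plan()].
#' @param out_dir output directory (created if needed).
#' @param progress print per-event progress lines?
#' @param ... passed on to [run_event()] via [run_ensemble()].
#' @return Invisibly, the manifest list.
#' @export
run_sweep <- function(plan, out_dir, progress = FALSE, ...) {
  stopifnot(inherits(plan, "sweep_plan"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_mono <- plan$base_params$n_monomers
  files <- character(0)
  for (i in seq_len(nrow(plan$grid))) {
    cond <- plan$grid[i, ]
    tag <- .condition_tag(cond$pore_radius, cond$pore_epsilon,
                          cond$pull_force)
    path <- file.path(out_dir, paste0("events_", tag, ".csv"))
    files <- c(files, path)
    if (file.exists(path) &&
        nrow(read.csv(path, check.names = FALSE)) >= plan$n_events)
      next
    params <- do.call(simulation_parameters, c(
      list(pore_radius = cond$pore_radius, pore_epsilon = cond$pore_epsilon,
           pull_force = cond$pull_force),
      .non_default_overrides(plan$base_params)))
    ens <- run_ensemble(params, n_events = plan$n_events,
                        base_seed = plan$base_seed, progress = progress, ...)
    write_events_csv(ens, path)
  }
  manifest <- list(
    grid = plan$grid, n_events = plan$n_events, base_seed = plan$base_seed,
    n_monomers = n_mono, timestep = plan$base_params$timestep,
    package_version = as.character(utils::packageVersion("poretrans")),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# overrides of base_params relative to the package defaults, minus the
# condition fields themselves (rlang splicing needs a plain named list)
.non_default_overrides <- function(base_params) {
  def <- .default_params()
  keep <- setdiff(names(def), c("pore_radius", "pore_epsilon", "pull_force"))
  out <- list()
  for (f in keep)
    if (!identical(base_params[[f]], def[[f]])) out[[f]] <- base_params[[f]]
  out
}

#' Write / read a wide per-event exit-time table
#'
#' Columns: the condition triple, event bookkeeping, `total_time`, then one
#' exit-time column per monomer (`t1`..`tN`).
#'
#' @param ensemble a `pt_ensemble`.
#' @param path CSV file.
#' @return `write_events_csv`: `path` invisibly; `read_events_csv`: a
#'   `pt_ensemble` tibble (without snapshots).
#' @export
write_events_csv <- function(ensemble, path) {
  .check_ensemble(ensemble)
  wide <- ensemble |>
    tibble::as_tibble() |>
    dplyr::select(-dplyr::any_of("snapshots"))
  tmat <- do.call(rbind, wide$exit_times)
  colnames(tmat) <- paste0("t", seq_len(ncol(tmat)))
  wide <- dplyr::bind_cols(dplyr::select(wide, -"exit_times"),
                           tibble::as_tibble(tmat))
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  wide <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  tcols <- grep("^t[0-9]+$", names(wide), value = TRUE)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  tmat <- as.matrix(wide[, tcols])
  out <- wide |>
    dplyr::select(-dplyr::all_of(tcols)) |>
    dplyr::mutate(exit_times = lapply(seq_len(nrow(tmat)),
                                      function(i) unname(tmat[i, ])),
                  snapshots = rep(list(NULL), nrow(tmat)))
  attr(out, "n_monomers") <- length(tcols)
  class(out) <- c("pt_ensemble", class(out))
  out
}

#' Analyze stored event files into observable tables
#'
#' Reads every `events_*.csv` under `event_dir`, concatenates conditions and
#' writes tidy CSVs: `tau_summary.csv`, `waiting_times.csv`,
#' `exit_time_curves.csv` and `crossing_report.csv` (cumulative-curve
#' crossing between two interaction energies per (radius, force) pair).
#' Corrupt or empty files are skipped with a warning. The analysis is a pure
#' function of the event files.
#'
#' @param event_dir directory holding `events_*.csv` files.
#' @param out_dir where to write the tables; defaults to `event_dir`.
#' @param eps_a,eps_b interaction energies compared in the crossing report.
#' @return Invisibly, a list of the four tibbles.
#' @export
analyze_events <- function(event_dir, out_dir = event_dir,
                           eps_a = 1, eps_b = 8) {
  files <- list.files(event_dir, pattern = "^events_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no event files found under ", event_dir)
  parts <- list()
  for (f in files) {
    ens <- tryCatch(read_events_csv(f), error = function(e) {
      warning("skipping unreadable event file ", f, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(ens) && nrow(ens)) parts[[f]] <- tibble::as_tibble(ens)
  }
  if (!length(parts)) stop("no readable event files under ", event_dir)
  all <- dplyr::bind_rows(parts)
  attr(all, "n_monomers") <- length(all$exit_times[[1]])
  class(all) <- c("pt_ensemble", class(all))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    tau_summary = translocation_time_summary(all),
    waiting_times = waiting_times(all),
    exit_time_curves = exit_time_curves(all),
    crossing_report = crossing_report(all, eps_a, eps_b))
  for (nm in names(tabs))
    write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  invisible(tabs)
}

#' Write bead configurations as a standard XYZ trajectory
#'
#' Each frame: atom count, a comment line with the time tag, then one `C x
#' y z` line per bead. Readable by any molecular viewer.
#'
#' @param frames a single N x 3 matrix, a [polymer_state()], or a list of
#'   matrices.
#' @param path output `.xyz` file.
#' @param times optional per-frame time tags.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, times = NULL) {
  if (inherits(frames, "polymer_state")) {
    times <- frames$time
    frames <- list(frames$positions)
  }
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    m <- frames[[i]]
    if (is.null(m)) next
    writeLines(as.character(nrow(m)), con)
    t_i <- if (!is.null(times)) times[i] else i
    writeLines(sprintf("frame %d t = %g", i, t_i), con)
    writeLines(sprintf("C %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
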