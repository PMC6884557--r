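# Shared reduced-scale ensembles for the ordinal/statistical acceptance
# checks, computed once per test run and cached. Conditions follow the
# study setup (N = 50 chain, f = 2 "strong" drive, narrow 1.5-sigma and
# wide 3-sigma pores, pore interaction energies 1, 4, 8); 25 events per
# condition keeps the suite at desk scale.
acceptance_ensembles <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    conds <- list(c(1.5, 1), c(1.5, 4), c(1.5, 8), c(3, 1))
    parts <- lapply(conds, function(cv) {
      params <- simulation_parameters(pore_radius = cv[1],
                                      pore_epsilon = cv[2],
                                      pull_force = 2)
      run_ensemble(params, n_events = 25L, base_seed = 101L)
    })
    ens <- dplyr::bind_rows(parts)
    attr(ens, "n_monomers") <- 50L
    class(ens) <- c("pt_ensemble", class(tibble::tibble()))
    cache <<- ens
    cache
  }
})

# Hand-built tiny ensembles for exact arithmetic checks of the observables.
make_ensemble <- function(exit_time_list, pore_radius = 1.5,
                          pore_epsilon = 1, pull_force = 2,
                          snapshots = NULL) {
  n_ev <- length(exit_time_list)
  ens <- tibble::tibble(
    event = seq_len(n_ev),
    pore_radius = pore_radius, pore_epsilon = pore_epsilon,
    pull_force = pull_force,
    seed = 1L, stream = seq_len(n_ev), attempts = 1L, n_discarded = 0L,
    equil_time = 0,
    total_time = vapply(exit_time_list, function(x) x[length(x)], 0),
    exit_times = exit_time_list,
    snapshots = if (is.null(snapshots)) rep(list(NULL), n_ev) else snapshots)
  attr(ens, "n_monomers") <- if (n_ev) length(exit_time_list[[1]]) else 0L
  class(ens) <- c("pt_ensemble", class(tibble::tibble()))
  ens
}

# moving-average smoother used for the bell-shape/ascending-tail checks
smooth_ma <- function(x, k = 9) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}
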