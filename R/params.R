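# Reduced Lennard-Jones unit system: sigma = epsilon0 = m = 1, so the time
# unit t_LJ = sqrt(m sigma^2 / eps0) = 1 and thermal energy kT = 1.2.
# SI values (sigma_nm, monomer_mass_amu, temperature_si) are carried along
# only for reporting.

.kB  <- 1.380649e-23    # J/K
.amu <- 1.66053906660e-27  # kg

.default_params <- function() {
  list(
    n_monomers   = 50L,
    sigma        = 1,
    monomer_mass = 1,
    epsilon0     = 1,
    kT           = 1.2,
    friction     = 0.7,
    fene_k       = 30,
    fene_r0      = 1.5,
    pore_length  = 6,
    pore_radius  = 1.5,
    pore_epsilon = 1,
    pull_force   = 2,
    cutoff_wca   = 2^(1/6),
    cutoff_pore  = 2.5,
    timestep     = 0.005,
    rng_seed     = 1L,
    n_events     = 25L,
    pore_center  = c(40, 38, 40),
    temperature_si   = 295,
    sigma_nm         = 1.5,
    monomer_mass_amu = 936,
    flory_nu     = 0.588,
    pore_dialect = "shifted"
  )
}

#' Simulation parameters in reduced Lennard-Jones units
#'
#' Collects every physical and numerical constant of the translocation model:
#' a chain of `n_monomers` beads of diameter `sigma` bonded by FENE springs
#' (`fene_k`, `fene_r0`), thermostatted at `kT` with friction `friction`,
#' threaded through a cylindrical pore of length `pore_length` and radius
#' `pore_radius` whose inner surface attracts beads with well depth
#' `pore_epsilon`, and pulled by `pull_force` acting on beads inside the
#' pore. Internal computation uses reduced units (`sigma = epsilon0 =
#' monomer_mass = 1`, hence `kT = 1.2` and `friction = 0.7`); the SI mapping
#' fields (`sigma_nm`, `monomer_mass_amu`, `temperature_si`) are used only by
#' [lj_time_unit()] and [epsilon0_joules()].
#'
#' @param ... named overrides of any default field. Unknown names are an
#'   error (this catches typos in sweep scripts).
#' @return A `sim_params` list with validated fields.
#' @details Defaults: N = 50 beads, kT = 1.2 eps0, friction 0.7 m/t_LJ,
#'   FENE k = 30 eps0/sigma^2 and R0 = 1.5 sigma, pore length 6 sigma,
#'   pore radius 1.5 sigma (pore diameters 3--6 sigma are the studied range),
#'   pulling force 2 eps0/sigma ("strong"; 1 eps0/sigma is "medium"),
#'   timestep 0.005 t_LJ, pore centre (40, 38, 40) sigma.
#'   `pore_dialect` selects how the attractive pore potential is handled at
#'   its 2.5 sigma cutoff: `"shifted"` (default, continuous) or `"literal"`
#'   (plus-epsilon form with a step at the cutoff); see [pore_lj_energy()].
#' @examples
#' p <- simulation_parameters(pore_radius = 2.5, pore_epsilon = 8)
#' lj_time_unit(p)  # ~32.1 ps
#' @export
simulation_parameters <- function(...) {
  p <- .default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$n_monomers <- as.integer(p$n_monomers)
  p$rng_seed <- as.integer(p$rng_seed)
  p$n_events <- as.integer(p$n_events)
  validate_params(p)
  structure(p, class = "sim_params")
}

validate_params <- function(p) {
  pos <- c("sigma", "monomer_mass", "epsilon0", "kT", "friction", "timestep",
           "fene_k", "fene_r0", "pore_length")
  for (f in pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      stop("parameter '", f, "' must be a single strictly positive number")
  if (p$n_monomers < 1L) stop("n_monomers must be >= 1")
  if (p$pore_radius <= p$sigma / 2)
    stop("pore_radius must exceed sigma/2: a bead must fit through the pore")
  if (abs(p$cutoff_wca - 2^(1/6) * p$sigma) > 1e-12)
    stop("cutoff_wca must equal 2^(1/6)*sigma")
  if (abs(p$cutoff_pore - 2.5 * p$sigma) > 1e-12)
    stop("cutoff_pore must equal 2.5*sigma")
  if (p$pore_epsilon < 0) stop("pore_epsilon must be non-negative")
  if (length(p$pore_center) != 3 || !all(is.finite(p$pore_center)))
    stop("pore_center must be a finite 3-vector")
  if (p$timestep > 0.01)
    stop("timestep must not exceed 0.01 t_LJ (unstable for fene_k = 30)")
  if (!p$pore_dialect %in% c("shifted", "literal"))
    stop("pore_dialect must be 'shifted' or 'literal'")
  if (p$n_events < 1L) stop("n_events must be >= 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> forced nanopore translocation, reduced LJ units\n")
  cat(sprintf("  chain: N = %d, FENE k = %g, R0 = %g; kT = %g, friction = %g\n",
              x$n_monomers, x$fene_k, x$fene_r0, x$kT, x$friction))
  cat(sprintf("  pore: length %g sigma, radius %g sigma, well depth %g eps0 (%s)\n",
              x$pore_length, x$pore_radius, x$pore_epsilon, x$pore_dialect))
  cat(sprintf("  drive: f = %g eps0/sigma; dt = %g t_LJ; seed %d, %d events\n",
              x$pull_force, x$timestep, x$rng_seed, x$n_events))
  invisible(x)
}

#' Energy unit in joules
#'
#' The reduced energy unit is fixed by the thermal anchor kT = 1.2 eps0 at
#' the mapping temperature: eps0 = kB * T / 1.2. At T = 295 K this is about
#' 3.39e-21 J.
#'
#' @param params a [simulation_parameters()] object.
#' @return Energy unit eps0 in joules.
#' @export
epsilon0_joules <- function(params) {
  .check_si(params)
  .kB * params$temperature_si / (params$kT / params$epsilon0)
}

#' Intrinsic simulation time unit in picoseconds
#'
#' Computes t_LJ = sqrt(m sigma^2 / eps0) from the SI mapping fields
#' (`sigma_nm`, `monomer_mass_amu`, `temperature_si`), with eps0 fixed by
#' kT = 1.2 eps0. For the default mapping (sigma = 1.5 nm, m = 936 amu,
#' T = 295 K) this gives about 32.1 ps.
#'
#' @inheritParams epsilon0_joules
#' @return Time unit in picoseconds.
#' @export
lj_time_unit <- function(params) {
  .check_si(params)
  eps0 <- epsilon0_joules(params)
  m_kg <- params$monomer_mass_amu * .amu
  sigma_m <- params$sigma_nm * 1e-9
  sqrt(m_kg * sigma_m^2 / eps0) * 1e12
}

.check_si <- function(params) {
  for (f in c("sigma_nm", "monomer_mass_amu", "temperature_si")) {
    v <- params[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        v <= 0)
      stop("SI mapping field '", f, "' must be set to a positive number")
  }
  invisible(params)
}

#' Force bounds separating the weak, medium and strong driving regimes
#'
#' The driven regime studied here requires the pulling force to exceed the
#' entropic scale kT/(sigma N^nu) while a force above kT/sigma saturates the
#' pore response ("strong"). Returns both bounds in reduced force units
#' eps0/sigma.
#'
#' @inheritParams epsilon0_joules
#' @param flory_nu Flory exponent; defaults to the value stored in `params`
#'   (0.588, the 3D self-avoiding-walk value consistent with the
#'   excluded-volume chain).
#' @return Named numeric vector `c(lower, upper)`.
#' @seealso [classify_force()]
#' @export
force_regime_bounds <- function(params, flory_nu = params$flory_nu) {
  if (!is.numeric(flory_nu) || flory_nu <= 0 || flory_nu > 1)
    stop("flory_nu must lie in (0, 1]")
  if (params$n_monomers < 1L) stop("n_monomers must be >= 1")
  kT <- params$kT
  s <- params$sigma
  if (kT <= 0 || s <= 0) stop("kT and sigma must be positive")
  c(lower = kT / (s * params$n_monomers^flory_nu), upper = kT / s)
}

#' Classify a pulling force as weak, medium or strong
#'
#' @param f force in reduced units eps0/sigma.
#' @inheritParams force_regime_bounds
#' @return `"weak"`, `"medium"` or `"strong"`.
#' @export
classify_force <- function(f, params, flory_nu = params$flory_nu) {
  b <- force_regime_bounds(params, flory_nu)
  ifelse(f < b[["lower"]], "weak",
         ifelse(f <= b[["upper"]], "medium", "strong"))
}

# ---- flat key-value configuration files (YAML) ----------------------------

#' Write simulation parameters to a flat YAML configuration file
#'
#' One key per parameter field, exactly the field names of
#' [simulation_parameters()]. Numbers are written with full double precision
#' so a write/read round trip reproduces every field exactly.
#'
#' @inheritParams epsilon0_joules
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  handler <- list(numeric = function(x) {
    r <- sprintf("%.17g", x)   # exact double round trip, no padding
    class(r) <- "verbatim"
    r
  })
  yaml::write_yaml(unclass(params), path, handlers = handler)
  invisible(path)
}

#' Read simulation parameters from a flat YAML configuration file
#'
#' Unknown keys are an error: a misspelled key in a sweep script silently
#' falling back to a default would corrupt a whole production run.
#'
#' @param path file to read.
#' @return A validated `sim_params` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw)))
    stop("configuration file must contain named keys")
  # YAML reads whole numbers as integers; restore the field's natural type
  def <- .default_params()
  for (nm in intersect(names(raw), names(def)))
    if (is.double(def[[nm]])) raw[[nm]] <- as.numeric(raw[[nm]])
  do.call(simulation_parameters, raw)
}
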