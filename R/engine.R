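#' Default simulation configuration
#'
#' All model parameters with their default values: the printed geometry and
#' release parameters of the mossy-fiber to granule-cell synapse (16-nm
#' cleft, 160-nm PSD, 600-nm apposition, 3,000 released molecules, 125
#' AMPARs at 10 pS, 50 NMDARs at 25 pS, perisynaptic mGluR1 annulus),
#' two-zone glutamate diffusion (0.25/0.4 um^2/ms), the engine clock
#' (dt = 0.1 us), 33-35 C temperature, and the config-exposed quantities the
#' model leaves open (extracellular resistivity 250 Ohm cm, 30 mGluR1s, ion
#' permeability split, AP template).
#'
#' @return nested named list (blocks `run`, `geometry`, `particles`,
#'   `field`, `ions`, `receptors`, `membrane`)
#' @export
default_config <- function() {
  list(
    run = list(dt_ms = 1e-4, duration_ms = 5, seed = 1, c_snapshot_every = 10),
    geometry = list(
      cleft_height_nm = 16, apposition_width_nm = 600, psd_width_nm = 160,
      neighbor_gap_nm = 50, mglur_ring_inner_nm = 172.5,
      mglur_ring_outer_nm = 187.5, escape_radius_nm = 1500,
      structure_height_nm = 1500, bin_width_nm = 20),
    particles = list(
      n_released = 3000, D_cleft_um2_ms = 0.25, D_out_um2_ms = 0.4,
      release_time_ms = 0, step_mode = "fixed"),
    field = list(
      enabled = TRUE, rex_ohm_cm = 2500, temperature_K = 307, valence = -1,
      driving_force_scale = 1),
    ions = list(
      enabled = TRUE, na_mM = 151.25, k_mM = 3, cl_mM = 135,
      d_na_um2_ms = 0.66, d_k_um2_ms = 0.98, d_cl_um2_ms = 1.0,
      f_na = 0.5, f_k = 0.5, e_na_mV = 65, e_k_mV = -95, substeps = 2),
    receptors = list(
      n_ampar = 125, n_nmdar = 50, n_mglur = 30, placement_seed = 1,
      ampar_scheme = "ampar", nmdar_scheme = "nmdar", mglur_scheme = "mglur1",
      dgg_mM = 0, dgg_kon_mM_ms = 5, dgg_koff_ms = 5, nbqx_block = 0,
      mg_mM = 0),
    membrane = list(
      v_hold_mV = -70, ap_enabled = FALSE, ap_onset_ms = 0,
      ap_mode = "template", ap_peak_mV = 30, ap_rise_ms = 0.2,
      ap_decay_ms = 0.6, ap_duration_ms = 2.5)
  )
}

.merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) stop("config block '", path, nm, "' must be a list")
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and resolve a simulation configuration
#'
#' Fills a partial configuration with the defaults, rejects unknown keys and
#' checks every constraint (positive dimensions, dt > 0, duration >= dt,
#' explicit seed, fractions in range) before any computation.
#'
#' @param config partial configuration (nested named list)
#' @return fully resolved configuration of class `sim_config`
#' @export
resolve_config <- function(config = list()) {
  if (inherits(config, "sim_config")) return(config)
  cfg <- .merge_config(default_config(), config)
  r <- cfg$run
  if (!is.numeric(r$dt_ms) || r$dt_ms <= 0) stop("run$dt_ms must be > 0")
  if (r$duration_ms < r$dt_ms) stop("run$duration_ms must be >= dt")
  if (is.null(r$seed) || !is.finite(r$seed)) stop("an explicit run$seed is required")
  if (cfg$particles$n_released < 0) stop("particles$n_released must be >= 0")
  if (cfg$particles$D_cleft_um2_ms < 0 || cfg$particles$D_out_um2_ms < 0)
    stop("diffusion coefficients must be >= 0")
  if (!cfg$particles$step_mode %in% c("fixed", "gaussian"))
    stop("particles$step_mode must be 'fixed' or 'gaussian'")
  if (cfg$field$temperature_K <= 0) stop("field$temperature_K must be > 0")
  if (cfg$field$rex_ohm_cm < 0) stop("field$rex_ohm_cm must be >= 0")
  if (cfg$receptors$nbqx_block < 0 || cfg$receptors$nbqx_block > 1)
    stop("receptors$nbqx_block must be in [0, 1]")
  if (cfg$receptors$dgg_mM < 0) stop("receptors$dgg_mM must be >= 0")
  with(cfg$ions, {
    if (f_na < 0 || f_k < 0 || f_na + f_k > 1 + 1e-9)
      stop("ion permeability fractions must be >= 0 and sum to <= 1")
  })
  build_geometry(cfg$geometry)  # errors on non-physical dimensions
  structure(cfg, class = c("sim_config", "list"))
}

#' Initialize the full simulation state for the duty-cycle engine
#'
#' Builds the geometry, places and groups the receptors by radial
#' concentration bin, loads and temperature-scales the kinetic schemes
#' (augmenting the AMPAR scheme with the competitive antagonist when
#' gamma-DGG is configured), precomputes the membrane-potential grid and
#' pre-equilibrates the ion state.
#'
#' @param config a configuration (partial configurations are resolved)
#' @return opaque state list consumed by [step_duty_cycle()] /
#'   [run_simulation()]
#' @export
init_sim_state <- function(config = list()) {
  cfg <- resolve_config(config)
  geom <- build_geometry(cfg$geometry)
  dt <- cfg$run$dt_ms
  n_steps <- round(cfg$run$duration_ms / dt)
  Tk <- cfg$field$temperature_K

  schemes <- list(
    AMPAR  = q10_scale(load_scheme(cfg$receptors$ampar_scheme), Tk),
    NMDAR  = q10_scale(load_scheme(cfg$receptors$nmdar_scheme), Tk),
    mGluR1 = q10_scale(load_scheme(cfg$receptors$mglur_scheme), Tk))
  if (cfg$receptors$dgg_mM > 0)
    schemes$AMPAR <- add_competitive_antagonist(
      schemes$AMPAR, cfg$receptors$dgg_kon_mM_ms, cfg$receptors$dgg_koff_ms,
      cfg$receptors$dgg_mM)

  layout <- place_receptors(
    geom, counts = c(cfg$receptors$n_ampar, cfg$receptors$n_nmdar,
                     cfg$receptors$n_mglur),
    seed = cfg$receptors$placement_seed,
    conductance_pS = c(AMPAR = schemes$AMPAR$conductance_pS,
                       NMDAR = schemes$NMDAR$conductance_pS))

  nb <- length(seq(0, geom$outer_radius_nm, by = geom$bin_width_nm)) - 1
  if (nb * geom$bin_width_nm < geom$outer_radius_nm) nb <- nb + 1

  # receptors of one type in the same bin share identical mean-field
  # dynamics -> collapse to (type, bin) groups with a count
  type_id <- c(AMPAR = 0L, NMDAR = 1L, mGluR1 = 2L)
  groups <- list()
  for (ty in names(type_id)) {
    rows <- layout[layout$type == ty, , drop = FALSE]
    if (!nrow(rows)) next
    sc <- schemes[[ty]]
    r <- sqrt(rows$x_nm^2 + rows$y_nm^2)
    bins <- pmin(floor(r / geom$bin_width_nm), nb - 1)
    st_idx <- function(states) match(states, sc$states) - 1L
    tr <- sc$transitions
    ant <- if (is.null(sc$ant_mM)) 0 else sc$ant_mM
    p0 <- resting_occupancy(sc, ant)
    for (b in sort(unique(bins))) {
      groups[[length(groups) + 1]] <- list(
        n_states = length(sc$states),
        tr_from = st_idx(tr$from), tr_to = st_idx(tr$to),
        tr_rate = tr$rate,
        tr_lig = match(tr$ligand, c("none", "glu", "ant")) - 1L,
        open_idx = st_idx(sc$open_states),
        active_idx = st_idx(sc$active_states),
        p = unname(p0),
        count = sum(bins == b), gamma_pS = sc$conductance_pS,
        erev_mV = sc$erev_mV,
        block = if (ty == "AMPAR") cfg$receptors$nbqx_block else 0,
        ant_mM = ant, type = type_id[[ty]], bin = as.integer(b))
    }
  }

  # membrane-potential grid over the whole run
  mem <- cfg$membrane
  protocol <- membrane_protocol(
    Vo_mV = mem$v_hold_mV,
    ap_onsets_ms = if (isTRUE(mem$ap_enabled)) mem$ap_onset_ms else numeric(0),
    mode = mem$ap_mode,
    template = list(peak_mV = mem$ap_peak_mV, rise_ms = mem$ap_rise_ms,
                    decay_ms = mem$ap_decay_ms, duration_ms = mem$ap_duration_ms),
    dt_ms = dt)
  vm <- vm_at(protocol, (0:(n_steps - 1)) * dt)

  ion <- list(
    enabled = isTRUE(cfg$ions$enabled),
    conc_mM = matrix(rep(c(cfg$ions$na_mM, cfg$ions$k_mM, cfg$ions$cl_mM),
                         each = nb), nb, 3),
    baseline_mM = c(cfg$ions$na_mM, cfg$ions$k_mM, cfg$ions$cl_mM),
    D_nm2_ms = 1e6 * c(cfg$ions$d_na_um2_ms, cfg$ions$d_k_um2_ms,
                       cfg$ions$d_cl_um2_ms),
    f_na = cfg$ions$f_na, f_k = cfg$ions$f_k,
    e_na_mV = cfg$ions$e_na_mV, e_k_mV = cfg$ions$e_k_mV,
    # explicit diffusion stability: h <= bin_width^2 / (4 D_max)
    substeps = as.integer(max(
      cfg$ions$substeps,
      ceiling(dt * 4 * 1e6 * max(cfg$ions$d_na_um2_ms, cfg$ions$d_k_um2_ms,
                                 cfg$ions$d_cl_um2_ms) /
                geom$bin_width_nm^2))))

  n <- cfg$particles$n_released
  pos <- matrix(rep(c(0, 0, geom$cleft_height_nm / 2), each = n), ncol = 3)
  D_fast <- max(cfg$particles$D_cleft_um2_ms, cfg$particles$D_out_um2_ms) * 1e6

  params <- list(
    dt_ms = dt, cleft_height_nm = geom$cleft_height_nm,
    half_nm = geom$apposition_width_nm / 2,
    structure_height_nm = geom$structure_height_nm,
    pitch_nm = geom$lattice_pitch_nm,
    escape_radius_nm = geom$escape_radius_nm,
    ra_nm = geom$active_zone_radius_nm, R_out_nm = geom$outer_radius_nm,
    bin_width_nm = geom$bin_width_nm, n_bins = as.integer(nb),
    D_cleft_um2_ms = cfg$particles$D_cleft_um2_ms,
    D_out_um2_ms = cfg$particles$D_out_um2_ms,
    step_mode = if (cfg$particles$step_mode == "fixed") 0L else 1L,
    mu_cleft = mobility(cfg$particles$D_cleft_um2_ms, cfg$field$valence, Tk),
    field_on = isTRUE(cfg$field$enabled),
    rex_ohm_m = cfg$field$rex_ohm_cm / 100,
    gamma_scale = cfg$field$driving_force_scale,
    mg_mM = cfg$receptors$mg_mM,
    max_embed_nm = max(25, 3 * sqrt(6 * D_fast * dt)),
    release_step = as.integer(round(cfg$particles$release_time_ms / dt)),
    erev_ampar_mV = schemes$AMPAR$erev_mV,
    erev_nmdar_mV = schemes$NMDAR$erev_mV)

  list(config = cfg, geom = geom, layout = layout, schemes = schemes,
       params = params, pos = pos, alive = rep(TRUE, n), vm = vm,
       step = 0L, released = FALSE, L_prev = 0, vm_prev = vm[1],
       seed = as.integer(cfg$run$seed), groups = groups, ions = ion,
       n_steps_total = n_steps)
}

#' Advance the simulation by whole duty cycles
#'
#' One duty cycle performs, in order: (1) particle moves (Brownian step plus
#' electrodiffusive drift from the previous cycle's field), boundary
#' handling; (2) rebuild of the radial glutamate concentration profile;
#' (3) receptor occupancy updates from the local concentration and Vm(t);
#' (4) currents, intracleft ion update and the field for the next cycle.
#'
#' @param state state from [init_sim_state()] (or a previous call)
#' @param n_steps how many cycles to advance (default 1)
#' @return list with the advanced `state` and the per-step `traces` matrix
#' @export
step_duty_cycle <- function(state, n_steps = 1) {
  if (state$step + n_steps > state$n_steps_total)
    stop("run is over: extend run$duration_ms")
  cpp_engine_run(state, as.integer(n_steps),
                 as.integer(state$config$run$c_snapshot_every))
}

#' Run a complete simulation
#'
#' @param config a (partial) configuration; see [default_config()]
#' @return object of class `trace_set`: data.frame `traces` on the uniform
#'   time grid (currents in pA, open probabilities, mGluR1 activation,
#'   in-cleft glutamate count, ion perturbations in percent, Vm in mV, shunt
#'   parameter L), decimated concentration snapshots `c_bins` (mM), the
#'   resolved `config`, seed and wall-clock metadata
#' @export
run_simulation <- function(config = list()) {
  t0 <- proc.time()[["elapsed"]]
  state <- init_sim_state(config)
  res <- cpp_engine_run(state, state$n_steps_total,
                        as.integer(state$config$run$c_snapshot_every))
  tr <- as.data.frame(res$traces)
  # initial row: state at t = 0 before the first duty cycle
  first <- tr[1, ]
  first$t_ms <- 0; first$vm_mV <- state$vm[1]; first$L <- 0
  first$cleft_count <- 0; first$i_ampar_pA <- 0; first$i_nmdar_pA <- 0
  first$p_open_ampar <- 0; first$p_open_nmdar <- 0
  first$mglur_active <- 0
  first$na_dev_pct <- 0; first$k_dev_pct <- 0; first$cl_dev_pct <- 0
  tr <- rbind(first, tr)
  rownames(tr) <- NULL
  structure(list(
    traces = tr,
    c_bins = res$c_bins, c_t_ms = res$c_t_ms,
    config = state$config, seed = state$config$run$seed,
    layout = state$layout,
    final_state = res$state,
    wall_s = proc.time()[["elapsed"]] - t0,
    version = as.character(utils::packageVersion("cleftsim"))
  ), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  tr <- x$traces
  cat(sprintf("TraceSet: %d steps of %g us (%.3g ms), seed %d, %.2f s wall\n",
              nrow(tr) - 1, x$config$run$dt_ms * 1000,
              max(tr$t_ms), x$seed, x$wall_s))
  cat(sprintf("  peak |I_AMPAR| %.3g pA | peak |I_NMDAR| %.3g pA | peak mGluR1 activation %.3g\n",
              max(abs(tr$i_ampar_pA)), max(abs(tr$i_nmdar_pA)),
              max(tr$mglur_active)))
  cat(sprintf("  cleft count %d -> %d | max ion perturbation %.3g%%\n",
              max(tr$cleft_count), tr$cleft_count[nrow(tr)],
              max(tr[, c("na_dev_pct", "k_dev_pct", "cl_dev_pct")])))
  invisible(x)
}
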