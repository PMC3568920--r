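#' @keywords internal
.average_traces <- function(trace_list) {
  out <- trace_list[[1]]
  num <- vapply(out, is.numeric, logical(1))
  for (cn in names(out)[num])
    out[[cn]] <- rowMeans(vapply(trace_list, function(d) d[[cn]],
                                 numeric(nrow(out))))
  out
}

.run_seeds <- function(config, seeds) {
  lapply(seeds, function(s) {
    cfg <- config
    cfg$run$seed <- s
    run_simulation(cfg)$traces
  })
}

#' Spike-release pairing protocol
#'
#' Paired simulations with and without a single postsynaptic action
#' potential whose onset precedes glutamate release by `ap_lead_ms`
#' (default 0.5 ms, the pairing protocol of the physiological experiments),
#' at a holding potential of -70 mV. Reports the tail fold-change of the
#' in-cleft glutamate count (the AP-retarded escape), the AP effect on peak
#' AMPAR/NMDAR open probability relative to the seed-to-seed scatter, and
#' the mGluR1 activation boost.
#'
#' @param config partial configuration (holding voltage etc.)
#' @param seeds integer vector of seeds (>= 10 for publication-grade
#'   averages)
#' @param ap_lead_ms AP onset time before release (ms)
#' @param post_ms simulated time after release (ms)
#' @param tail_window_ms tail window after AP onset for the fold-change
#' @return list with mean traces per condition, `fold` (tail fold-change of
#'   the seed-averaged count curves), `fold_per_seed`, peak open
#'   probabilities and mGluR1 activation per condition and seed
#' @export
protocol_ap_pairing <- function(config = list(), seeds = 1:10,
                                ap_lead_ms = 0.5, post_ms = 5,
                                tail_window_ms = c(0.5, 3)) {
  cfg <- resolve_config(config)
  cfg$particles$release_time_ms <- ap_lead_ms
  cfg$run$duration_ms <- ap_lead_ms + post_ms
  cfg$membrane$ap_onset_ms <- 0

  cfg_ap <- cfg; cfg_ap$membrane$ap_enabled <- TRUE
  cfg_ct <- cfg; cfg_ct$membrane$ap_enabled <- FALSE

  runs_ap <- .run_seeds(cfg_ap, seeds)
  runs_ct <- .run_seeds(cfg_ct, seeds)
  mean_ap <- .average_traces(runs_ap)
  mean_ct <- .average_traces(runs_ct)

  tfc <- tail_fold_change(mean_ap, mean_ct, tail_window = tail_window_ms)
  fold_per_seed <- mapply(function(a, c)
    tail_fold_change(a, c, tail_window = tail_window_ms)$fold,
    runs_ap, runs_ct)

  peak_of <- function(runs, col) vapply(runs, function(d) max(d[[col]]),
                                        numeric(1))
  list(
    traces_ap = mean_ap, traces_ctrl = mean_ct,
    fold = tfc$fold, t_at_max_ms = tfc$t_at_max_ms,
    fold_per_seed = fold_per_seed,
    peak_p_ampar = cbind(ap = peak_of(runs_ap, "p_open_ampar"),
                         ctrl = peak_of(runs_ct, "p_open_ampar")),
    peak_p_nmdar = cbind(ap = peak_of(runs_ap, "p_open_nmdar"),
                         ctrl = peak_of(runs_ct, "p_open_nmdar")),
    peak_mglur = cbind(ap = peak_of(runs_ap, "mglur_active"),
                       ctrl = peak_of(runs_ct, "mglur_active")),
    seeds = seeds)
}

#' Voltage-sweep protocol
#'
#' Runs the release simulation at each holding voltage and fits the
#' mono-exponential decay of the AMPAR current, reporting per-voltage decay
#' constants and the decay ratio between the first two voltages (by
#' convention positive/negative, the voltage-asymmetry readout).
#'
#' @param config partial configuration
#' @param voltages holding voltages (mV); the ratio reported is tau at the
#'   first voltage over tau at the second
#' @param seeds seeds averaged per voltage
#' @return list with per-voltage mean traces, per-seed tau values, mean
#'   taus and the decay ratio (with its propagated scatter)
#' @export
protocol_voltage_sweep <- function(config = list(), voltages = c(40, -70),
                                   seeds = 1:10) {
  cfg <- resolve_config(config)
  res <- lapply(voltages, function(v) {
    c2 <- cfg
    c2$membrane$v_hold_mV <- v
    runs <- .run_seeds(c2, seeds)
    tau_seed <- vapply(runs, function(d) fit_decay_tau(d)$tau_ms, numeric(1))
    mean_tr <- .average_traces(runs)
    list(v = v, traces = mean_tr, tau_per_seed = tau_seed,
         tau_mean_trace = fit_decay_tau(mean_tr)$tau_ms)
  })
  names(res) <- paste0("v_", voltages)
  dr <- decay_ratio(res[[1]]$tau_per_seed, res[[2]]$tau_per_seed)
  list(per_voltage = res, voltages = voltages,
       tau = vapply(res, function(r) mean(r$tau_per_seed), numeric(1)),
       ratio = dr$ratio, ratio_se = dr$se, seeds = seeds)
}

#' Driving-force scaling protocol
#'
#' Mimics partial replacement of extracellular sodium (reduced current at
#' unchanged voltage) by scaling the effective open-channel conductance,
#' and reports how the voltage asymmetry of the decay shrinks with the
#' current.
#'
#' @param config partial configuration
#' @param scales conductance scale factors (1 = control; 0.5 = halved free
#'   sodium)
#' @param voltages passed to [protocol_voltage_sweep()]
#' @param seeds seeds per condition
#' @return list of voltage-sweep results per scale plus the tau-ratio per
#'   scale
#' @export
protocol_nmdg <- function(config = list(), scales = c(1, 0.5),
                          voltages = c(40, -70), seeds = 1:10) {
  cfg <- resolve_config(config)
  res <- lapply(scales, function(sc) {
    c2 <- cfg
    c2$field$driving_force_scale <- sc
    protocol_voltage_sweep(c2, voltages, seeds)
  })
  names(res) <- paste0("scale_", scales)
  list(per_scale = res, scales = scales,
       ratio = vapply(res, `[[`, numeric(1), "ratio"))
}

#' Antagonist protocol
#'
#' gamma-DGG mode: paired runs with and without the competitive antagonist
#' at each voltage; the relative block of the peak AMPAR current reports the
#' intracleft glutamate transient (a smaller block means a larger
#' transient). NBQX mode: non-competitive fractional block, whose relative
#' effect is voltage independent by construction.
#'
#' @param config partial configuration
#' @param antagonist `"dgg"` or `"nbqx"`
#' @param conc_mM gamma-DGG concentration (mM; dgg mode)
#' @param nbqx_fraction blocked fraction (nbqx mode)
#' @param voltages holding voltages
#' @param seeds seeds per condition
#' @return list with per-voltage peak currents (control/antagonist) and the
#'   relative block in percent
#' @export
protocol_antagonist <- function(config = list(), antagonist = c("dgg", "nbqx"),
                                conc_mM = 1, nbqx_fraction = 0.3,
                                voltages = c(-70, 40), seeds = 1:10) {
  antagonist <- match.arg(antagonist)
  cfg <- resolve_config(config)
  res <- lapply(voltages, function(v) {
    c_ct <- cfg; c_ct$membrane$v_hold_mV <- v
    c_an <- c_ct
    if (antagonist == "dgg") c_an$receptors$dgg_mM <- conc_mM
    else c_an$receptors$nbqx_block <- nbqx_fraction
    peak <- function(cf) {
      runs <- .run_seeds(cf, seeds)
      vapply(runs, function(d) max(abs(d$i_ampar_pA)), numeric(1))
    }
    p_ct <- peak(c_ct); p_an <- peak(c_an)
    list(v = v, peak_ctrl = p_ct, peak_ant = p_an,
         block_pct = (1 - mean(p_an) / mean(p_ct)) * 100)
  })
  names(res) <- paste0("v_", voltages)
  list(per_voltage = res, voltages = voltages, antagonist = antagonist,
       block_pct = vapply(res, `[[`, numeric(1), "block_pct"))
}

#' Timestep-convergence protocol
#'
#' Two runs with shared per-particle random streams at the default and a
#' 10-fold reduced time step; reports the relative change of the peak AMPAR
#' current, the accuracy measure of the discretized duty cycle.
#'
#' @param config partial configuration
#' @param dt_ms coarse time step (ms)
#' @param factor reduction factor for the fine run
#' @param window_ms simulated window (ms)
#' @param seeds seeds averaged per time step
#' @return list with per-dt mean peak currents and `change_pct`
#' @export
protocol_convergence <- function(config = list(), dt_ms = 1e-4, factor = 10,
                                 window_ms = 2, seeds = 1:3) {
  cfg <- resolve_config(config)
  cfg$run$duration_ms <- window_ms
  peak_at_dt <- function(dt) {
    c2 <- cfg
    c2$run$dt_ms <- dt
    runs <- .run_seeds(c2, seeds)
    mean(vapply(runs, function(d) max(abs(d$i_ampar_pA)), numeric(1)))
  }
  p_coarse <- peak_at_dt(dt_ms)
  p_fine <- peak_at_dt(dt_ms / factor)
  list(dt_coarse_ms = dt_ms, dt_fine_ms = dt_ms / factor,
       peak_coarse_pA = p_coarse, peak_fine_pA = p_fine,
       change_pct = abs(p_fine - p_coarse) / abs(p_fine) * 100, seeds = seeds)
}

#' mGluR1 pairing readout
#'
#' Convenience wrapper around [protocol_ap_pairing()] returning the
#' perisynaptic mGluR1 activation time courses and their AP-driven boost.
#'
#' @inheritParams protocol_ap_pairing
#' @return list with mean activation traces per condition and the ratio of
#'   peak activations (AP / control)
#' @export
protocol_mglur_pairing <- function(config = list(), seeds = 1:10, ...) {
  pr <- protocol_ap_pairing(config, seeds, ...)
  list(activation_ap = pr$traces_ap[, c("t_ms", "mglur_active")],
       activation_ctrl = pr$traces_ctrl[, c("t_ms", "mglur_active")],
       boost = max(pr$traces_ap$mglur_active) /
         max(pr$traces_ctrl$mglur_active),
       peak_mglur = pr$peak_mglur, seeds = seeds)
}

#' Run a named virtual-experiment protocol
#'
#' Dispatcher over the registered protocols: `voltage_sweep`, `ap_pairing`,
#' `nmdg`, `antagonist`, `mglur_pairing`, `convergence`.
#'
#' @param name protocol name
#' @param config partial configuration
#' @param ... protocol-specific arguments (e.g. `seeds`)
#' @return the protocol's report (a named list)
#' @export
run_protocol <- function(name, config = list(), ...) {
  fns <- list(voltage_sweep = protocol_voltage_sweep,
              ap_pairing = protocol_ap_pairing,
              nmdg = protocol_nmdg,
              antagonist = protocol_antagonist,
              mglur_pairing = protocol_mglur_pairing,
              convergence = protocol_convergence)
  if (!name %in% names(fns))
    stop("unknown protocol '", name, "'; registered: ",
         paste(names(fns), collapse = ", "))
  fns[[name]](config, ...)
}
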