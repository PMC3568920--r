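#' Define the postsynaptic membrane-voltage protocol
#'
#' The membrane potential Vm(t) equals the holding voltage `Vo_mV` except
#' during action-potential events, when it follows either a closed-form
#' biexponential template spike or a Hodgkin-Huxley waveform integrated once
#' at construction time. The granule cell is electrically compact, so a
#' single-compartment description of the spike is adequate.
#'
#' @param Vo_mV holding/resting voltage (mV)
#' @param ap_onsets_ms numeric vector of AP onset times (ms); empty for a
#'   pure voltage-clamp protocol
#' @param mode `"template"` (default) or `"hh"`
#' @param template list: `peak_mV` (absolute peak, default +30),
#'   `rise_ms` (0.2), `decay_ms` (0.6), `duration_ms` (2.5)
#' @param hh list of Hodgkin-Huxley parameters, see [ap_waveform()]
#' @param dt_ms sampling step used to precompute the waveform
#' @return object of class `membrane_protocol`
#' @export
membrane_protocol <- function(Vo_mV = -70, ap_onsets_ms = numeric(0),
                              mode = c("template", "hh"),
                              template = list(), hh = list(), dt_ms = 1e-4) {
  mode <- match.arg(mode)
  wf <- NULL
  if (length(ap_onsets_ms)) {
    wf <- ap_waveform(params = list(Vo_mV = Vo_mV, mode = mode,
                                    template = template, hh = hh,
                                    dt_ms = dt_ms))
  }
  structure(list(Vo_mV = Vo_mV, ap_onsets_ms = sort(ap_onsets_ms),
                 mode = mode, waveform = wf, dt_ms = dt_ms),
            class = "membrane_protocol")
}

#' Single action-potential waveform
#'
#' `template` mode returns the closed-form biexponential surrogate
#' `Vo + A (exp(-t/decay) - exp(-t/rise))`, scaled so its maximum equals
#' `peak_mV`; `hh` mode integrates the standard single-compartment
#' Hodgkin-Huxley equations (RK4, fixed step) driven by a brief
#' suprathreshold current pulse, then offsets the spike so that it starts
#' from `Vo_mV`. Errors if the HH parameters do not produce a spike
#' overshooting 0 mV.
#'
#' @param params list with `Vo_mV`, `mode` ("template"/"hh"), `dt_ms`, and a
#'   `template` and/or `hh` sublist. HH entries (with defaults):
#'   `gna = 120`, `gk = 36`, `gl = 0.3` (mS/cm^2), `ena = 50`, `ek = -77`,
#'   `el = -54.4` (mV), `cm = 1` (uF/cm^2), `i_amp = 15` (uA/cm^2),
#'   `i_dur_ms = 0.5`.
#' @return list with `t_ms` and `v_mV` (waveform samples, starting at AP
#'   onset and ending back at `Vo_mV`) and `duration_ms`
#' @export
ap_waveform <- function(params) {
  Vo <- if (is.null(params$Vo_mV)) -70 else params$Vo_mV
  dt <- if (is.null(params$dt_ms)) 1e-4 else params$dt_ms
  mode <- if (is.null(params$mode)) "template" else params$mode

  if (mode == "template") {
    tp <- utils::modifyList(
      list(peak_mV = 30, rise_ms = 0.2, decay_ms = 0.6, duration_ms = 2.5),
      if (is.null(params$template)) list() else params$template)
    if (tp$rise_ms <= 0 || tp$decay_ms <= tp$rise_ms)
      stop("template needs 0 < rise_ms < decay_ms")
    t <- seq(0, tp$duration_ms, by = dt)
    shape <- exp(-t / tp$decay_ms) - exp(-t / tp$rise_ms)
    # linear taper so the event ends exactly at the holding level
    shape <- shape - (t / tp$duration_ms) * shape[length(shape)]
    v <- Vo + (tp$peak_mV - Vo) * shape / max(shape)
    return(list(t_ms = t, v_mV = v, duration_ms = tp$duration_ms))
  }

  hh <- utils::modifyList(
    list(gna = 120, gk = 36, gl = 0.3, ena = 50, ek = -77, el = -54.4,
         cm = 1, i_amp = 15, i_dur_ms = 0.5, max_ms = 10),
    if (is.null(params$hh)) list() else params$hh)

  alpha_n <- function(v) ifelse(abs(v + 55) < 1e-7, 0.1,
                                0.01 * (v + 55) / (1 - exp(-(v + 55) / 10)))
  beta_n  <- function(v) 0.125 * exp(-(v + 65) / 80)
  alpha_m <- function(v) ifelse(abs(v + 40) < 1e-7, 1,
                                0.1 * (v + 40) / (1 - exp(-(v + 40) / 10)))
  beta_m  <- function(v) 4 * exp(-(v + 65) / 18)
  alpha_h <- function(v) 0.07 * exp(-(v + 65) / 20)
  beta_h  <- function(v) 1 / (1 + exp(-(v + 35) / 10))

  deriv <- function(y, t) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    i_stim <- if (t < hh$i_dur_ms) hh$i_amp else 0
    dv <- (i_stim - hh$gna * m^3 * h * (v - hh$ena) -
             hh$gk * n^4 * (v - hh$ek) - hh$gl * (v - hh$el)) / hh$cm
    c(dv, alpha_m(v) * (1 - m) - beta_m(v) * m,
      alpha_h(v) * (1 - h) - beta_h(v) * h,
      alpha_n(v) * (1 - n) - beta_n(v) * n)
  }
  v0 <- -65  # HH resting potential for the default parameter set
  y <- c(v0, alpha_m(v0) / (alpha_m(v0) + beta_m(v0)),
         alpha_h(v0) / (alpha_h(v0) + beta_h(v0)),
         alpha_n(v0) / (alpha_n(v0) + beta_n(v0)))
  nstep <- ceiling(hh$max_ms / dt)
  vtrace <- numeric(nstep + 1)
  vtrace[1] <- y[1]
  for (k in seq_len(nstep)) {
    t <- (k - 1) * dt
    k1 <- deriv(y, t)
    k2 <- deriv(y + dt / 2 * k1, t + dt / 2)
    k3 <- deriv(y + dt / 2 * k2, t + dt / 2)
    k4 <- deriv(y + dt * k3, t + dt)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    vtrace[k + 1] <- y[1]
  }
  if (max(vtrace) < 0) stop("no AP generated: HH parameters are non-spiking")
  v <- vtrace - v0 + Vo                  # spike rides on the holding level
  # truncate once the spike has returned within 0.5 mV of Vo (after the peak)
  ipk <- which.max(v)
  back <- which(abs(v[ipk:length(v)] - Vo) < 0.5)
  iend <- if (length(back)) ipk + back[1] - 1 else length(v)
  t <- seq(0, by = dt, length.out = iend)
  list(t_ms = t, v_mV = v[seq_len(iend)], duration_ms = t[iend])
}

#' Membrane potential at given times
#'
#' Piecewise: the holding voltage, overridden by the precomputed AP waveform
#' during spike events.
#'
#' @param protocol a `membrane_protocol`
#' @param t_ms time(s) since run start (ms)
#' @return Vm in mV, one value per time
#' @export
vm_at <- function(protocol, t_ms) {
  stopifnot(inherits(protocol, "membrane_protocol"))
  v <- rep(protocol$Vo_mV, length(t_ms))
  wf <- protocol$waveform
  for (onset in protocol$ap_onsets_ms) {
    inside <- t_ms >= onset & t_ms <= onset + wf$duration_ms
    if (any(inside))
      v[inside] <- stats::approx(wf$t_ms, wf$v_mV, xout = t_ms[inside] - onset,
                                 rule = 2)$y
  }
  v
}
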