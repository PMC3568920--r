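#' Mono-exponential decay constant of a current trace
#'
#' Least-squares mono-exponential fit of |I(t)| from its peak: an initial
#' tau is estimated from the 1/e crossing, the fit window is then peak to
#' peak + 5 tau with one re-fit iteration (nonlinear least squares seeded by
#' the log-linear estimate). Errors when the trace does not decay after its
#' extremum.
#'
#' @param trace data.frame with a time column `t_ms` and a signal column
#' @param signal name of the signal column (default `i_ampar_pA`)
#' @param fit_window optional `c(t_from, t_to)` (ms) overriding the
#'   automatic peak -> peak + 5 tau window
#' @return list with `tau_ms`, `peak`, `t_peak_ms`, `resid_rms`
#' @export
fit_decay_tau <- function(trace, signal = "i_ampar_pA", fit_window = NULL) {
  stopifnot(is.data.frame(trace), all(c("t_ms", signal) %in% names(trace)))
  t <- trace$t_ms
  y <- abs(trace[[signal]])
  ipk <- which.max(y)
  if (ipk >= length(y) - 2 || max(y) <= 0)
    stop("trace has no decaying phase after its extremum")
  peak <- y[ipk]

  one_fit <- function(t_end) {
    sel <- which(t >= t[ipk] & t <= t_end & y > 0)
    if (length(sel) < 5) stop("trace has no decaying phase after its extremum")
    ts <- t[sel] - t[ipk]
    # log-linear seed, then nonlinear refinement
    co <- stats::coef(stats::lm(log(y[sel]) ~ ts))
    if (co[2] >= 0) stop("trace does not decay over the fit window")
    tau0 <- -1 / co[2]
    fit <- tryCatch(
      stats::nls(yy ~ A * exp(-ts / tau), data = list(yy = y[sel], ts = ts),
                 start = list(A = exp(co[1]), tau = tau0)),
      error = function(e) NULL)
    if (is.null(fit)) list(tau = unname(tau0), A = unname(exp(co[1])),
                           rms = sqrt(mean((y[sel] - exp(co[1]) * exp(-ts / tau0))^2)))
    else list(tau = stats::coef(fit)[["tau"]], A = stats::coef(fit)[["A"]],
              rms = sqrt(mean(stats::resid(fit)^2)))
  }

  if (is.null(fit_window)) {
    # initial tau from the 1/e crossing after the peak
    below <- which(y[ipk:length(y)] < peak / exp(1))
    tau_init <- if (length(below)) t[ipk + below[1] - 1] - t[ipk]
                else (t[length(t)] - t[ipk]) / 2
    f1 <- one_fit(min(t[ipk] + 5 * tau_init, max(t)))
    f2 <- one_fit(min(t[ipk] + 5 * f1$tau, max(t)))   # one re-fit iteration
  } else {
    f2 <- one_fit(fit_window[2])
  }
  if (f2$tau <= 0) stop("non-positive decay constant: trace does not decay")
  list(tau_ms = unname(f2$tau), peak = unname(peak), t_peak_ms = t[ipk],
       resid_rms = unname(f2$rms))
}

#' Tail fold-change of the in-cleft glutamate count
#'
#' Maximum over a tail window of the ratio (count with AP)/(count control),
#' with a floor on the denominator (minimum 5 molecules) so that empty-cleft
#' tails cannot produce 0/0 artifacts. The traces must share their time
#' grid.
#'
#' @param trace_ap,trace_ctrl data.frames with `t_ms` and a count column
#' @param tail_window `c(from, to)` in ms (absolute run time); the default
#'   0.5-3 ms after the start covers the brief post-spike tail
#' @param count_col name of the count column
#' @param floor_count denominator floor
#' @return list with `fold` (the maximum ratio), `t_at_max_ms` and the
#'   per-time ratio vector
#' @export
tail_fold_change <- function(trace_ap, trace_ctrl, tail_window = c(0.5, 3),
                             count_col = "cleft_count", floor_count = 5) {
  if (nrow(trace_ap) != nrow(trace_ctrl) ||
      max(abs(trace_ap$t_ms - trace_ctrl$t_ms)) > 1e-9)
    stop("traces do not share a time grid")
  sel <- trace_ap$t_ms >= tail_window[1] & trace_ap$t_ms <= tail_window[2]
  if (!any(sel)) stop("empty tail window")
  num <- trace_ap[[count_col]][sel]
  den <- pmax(trace_ctrl[[count_col]][sel], floor_count)
  ratio <- num / den
  i <- which.max(ratio)
  list(fold = ratio[i], t_at_max_ms = trace_ap$t_ms[sel][i], ratio = ratio)
}

#' Decay-constant ratio between two conditions
#'
#' Ratio tau_pos/tau_neg of two fitted decay constants, e.g. the EPSC decay
#' asymmetry between +40 and -70 mV. With per-seed fits supplied, the
#' seed-to-seed scatter is propagated to the ratio by the delta method.
#'
#' @param stats_pos,stats_neg either results of [fit_decay_tau()] or numeric
#'   vectors of per-seed tau values
#' @return list with `ratio` and, when per-seed values are given, `se`
#' @export
decay_ratio <- function(stats_pos, stats_neg) {
  tpos <- if (is.list(stats_pos)) stats_pos$tau_ms else stats_pos
  tneg <- if (is.list(stats_neg)) stats_neg$tau_ms else stats_neg
  if (any(!is.finite(c(tpos, tneg))) || any(c(tpos, tneg) <= 0))
    stop("invalid decay fits")
  ratio <- mean(tpos) / mean(tneg)
  se <- NA_real_
  if (length(tpos) > 1 && length(tneg) > 1) {
    se <- ratio * sqrt(stats::var(tpos) / length(tpos) / mean(tpos)^2 +
                         stats::var(tneg) / length(tneg) / mean(tneg)^2)
  }
  list(ratio = ratio, se = se)
}

#' Peak amplitude and charge transfer of a trace
#'
#' Signed extremum and trapezoidal integral (area under the curve); for a
#' current in pA over ms the AUC is in fC/1000 = pC.
#'
#' @param trace data.frame with `t_ms` and the signal column
#' @param signal signal column name
#' @return list with `peak` and `auc`
#' @export
peak_and_auc <- function(trace, signal = "i_ampar_pA") {
  y <- trace[[signal]]
  t <- trace$t_ms
  if (!all(is.finite(y))) stop("trace must be finite")
  peak <- y[which.max(abs(y))]
  auc <- sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  list(peak = peak, auc = auc)
}
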