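# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: Bessel functions by power series, master
# equations by Matrix::expm, HH by deSolve, unit bookkeeping by literal
# SI arithmetic.

# modified Bessel function of the first kind, integer order, power series
bessel_i_series <- function(nu, x, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
}

# reference voltage profile evaluated only with the series oracle
profile_series <- function(r, L, Vo, ra, R_out) {
  lambda <- ra / L
  den <- bessel_i_series(0, L) + L * bessel_i_series(1, L) * log(R_out / ra)
  if (r < ra) Vo * bessel_i_series(0, r / lambda) / den
  else Vo * (bessel_i_series(0, L) + L * bessel_i_series(1, L) * log(r / ra)) / den
}

# quick two-state ligand-binding scheme for closed-form checks
two_state_scheme <- function(kon = 5, koff = 2) {
  kinetic_scheme(
    name = "two-state", states = c("C", "O"), n_bound = c(0, 1), n_sites = 1,
    transitions = data.frame(from = c("C", "O"), to = c("O", "C"),
                             rate = c(kon, koff), ligand = c("glu", "none")),
    resting_state = "C", open_states = "O", conductance_pS = 10)
}

three_state_scheme <- function() {
  kinetic_scheme(
    name = "three-state", states = c("C", "B", "O"),
    n_bound = c(0, 1, 1), n_sites = 1,
    transitions = data.frame(
      from  = c("C", "B", "B", "O"),
      to    = c("B", "C", "O", "B"),
      rate  = c(8, 3, 4, 1.5),
      ligand = c("glu", "none", "none", "none")),
    resting_state = "C", open_states = "O", conductance_pS = 10)
}

# tiny run configurations for engine-level tests
mini_config <- function(...) {
  base <- list(
    run = list(dt_ms = 1e-3, duration_ms = 1, seed = 1),
    particles = list(n_released = 200),
    receptors = list(n_ampar = 25, n_nmdar = 10, n_mglur = 6))
  utils::modifyList(base, list(...))
}
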