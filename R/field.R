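#' Physical constants used by the electrodiffusion model
#'
#' @param temperature_K absolute temperature (default 307 K, i.e. 33-35 C
#'   recording conditions)
#' @param valence glutamate net charge at physiological pH (default -1)
#' @return list with Faraday constant `F_C_mol` (C/mol), gas constant
#'   `R_J_molK` (J/(mol K)), `temperature_K` and `valence`
#' @export
physical_constants <- function(temperature_K = 307, valence = -1) {
  if (temperature_K <= 0) stop("temperature must be positive (K)")
  if (valence != round(valence)) stop("valence must be an integer")
  list(F_C_mol = 96485.33212, R_J_molK = 8.314462618,
       temperature_K = temperature_K, valence = valence)
}

#' Dimensionless shunt parameter of the cleft voltage profile
#'
#' `L = sqrt(gamma_open_total * Rex / (pi * delta))`: the lumped open-channel
#' conductance inside the active zone, the extracellular resistivity and the
#' cleft height set how strongly the receptor currents polarize the cleft
#' interior relative to the bulk. `L = 0` iff no channel is open.
#'
#' @param gamma_open_total total instantaneous open conductance (S), i.e.
#'   sum over receptors of unitary conductance times open probability
#' @param rex_ohm_cm extracellular resistivity (Ohm cm; default 250)
#' @param delta_nm cleft height (nm)
#' @return dimensionless L >= 0
#' @export
shunt_parameter <- function(gamma_open_total, rex_ohm_cm = 250, delta_nm = 16) {
  if (any(gamma_open_total < 0)) stop("negative conductance")
  if (rex_ohm_cm < 0 || delta_nm <= 0) stop("Rex must be >= 0 and delta > 0")
  rex_ohm_m <- rex_ohm_cm / 100
  delta_m   <- delta_nm * 1e-9
  sqrt(gamma_open_total * rex_ohm_m / (pi * delta_m))
}

.profile_denominator <- function(L, ra_nm, R_out_nm) {
  besselI(L, 0) + L * besselI(L, 1) * log(R_out_nm / ra_nm)
}

#' Radial voltage profile in the synaptic cleft
#'
#' Steady-state two-branch solution of the thin-disc cable problem under
#' rotational symmetry: inside the active zone (r < ra) the profile follows
#' the modified Bessel function I0(r/lambda) with lambda = ra/L; between ra
#' and the cleft edge R_out it continues logarithmically; V(R_out) = Vo.
#' V(r) is the local transmembrane driving potential; the extracellular
#' cleft potential is phi(r) = Vo - V(r).
#'
#' @param r_nm radial coordinate(s), 0 <= r <= R_out (nm)
#' @param L dimensionless shunt parameter from [shunt_parameter()]
#' @param Vo_mV membrane voltage outside the cleft (mV)
#' @param ra_nm active-zone (PSD) radius (nm)
#' @param R_out_nm outer cleft radius (nm)
#' @return voltage V(r) in mV
#' @export
voltage_profile <- function(r_nm, L, Vo_mV, ra_nm, R_out_nm) {
  if (ra_nm <= 0 || R_out_nm <= ra_nm) stop("need 0 < ra < R_out")
  if (any(r_nm < 0) || any(r_nm > R_out_nm))
    stop("r outside [0, R_out]: the field is defined only inside the cleft")
  if (L < 0) stop("L must be >= 0")
  if (L == 0) return(rep(Vo_mV, length(r_nm)))
  lambda <- ra_nm / L
  den <- .profile_denominator(L, ra_nm, R_out_nm)
  inner <- r_nm < ra_nm
  v <- numeric(length(r_nm))
  v[inner]  <- Vo_mV * besselI(r_nm[inner] / lambda, 0) / den
  v[!inner] <- Vo_mV * (besselI(L, 0) +
                          L * besselI(L, 1) * log(r_nm[!inner] / ra_nm)) / den
  v
}

#' Radial gradient of the cleft voltage profile
#'
#' Analytic derivative dV/dr of [voltage_profile()], using
#' d/dx I0(x) = I1(x) inside the active zone and the logarithmic branch
#' outside. E(0) = 0 by symmetry; E = 0 everywhere when no channel is open.
#'
#' @inheritParams voltage_profile
#' @return gradient dV/dr in mV/nm
#' @export
radial_field <- function(r_nm, L, Vo_mV, ra_nm, R_out_nm) {
  if (ra_nm <= 0 || R_out_nm <= ra_nm) stop("need 0 < ra < R_out")
  if (any(r_nm < 0) || any(r_nm > R_out_nm))
    stop("r outside [0, R_out]: the field is defined only inside the cleft")
  if (L < 0) stop("L must be >= 0")
  if (L == 0) return(rep(0, length(r_nm)))
  lambda <- ra_nm / L
  den <- .profile_denominator(L, ra_nm, R_out_nm)
  inner <- r_nm < ra_nm
  e <- numeric(length(r_nm))
  e[inner]  <- Vo_mV * besselI(r_nm[inner] / lambda, 1) / (lambda * den)
  e[!inner] <- Vo_mV * L * besselI(L, 1) / (r_nm[!inner] * den)
  e
}

#' Electrophoretic mobility of a charged solute
#'
#' `mu = D q F / (R T)`, the Nernst-Einstein mobility relating the drift
#' velocity to the potential gradient. Returned in nm^2/(ms mV) so that
#' `mu * dV/dr [mV/nm] * dt [ms]` is a displacement in nm.
#'
#' @param D_um2_ms diffusion coefficient (um^2/ms)
#' @param q valence (signed integer; -1 for glutamate)
#' @param T_K absolute temperature (K)
#' @return mobility in nm^2/(ms mV); its sign follows the sign of q
#' @export
mobility <- function(D_um2_ms, q = -1, T_K = 307) {
  if (any(D_um2_ms < 0)) stop("D must be >= 0")
  if (T_K <= 0) stop("temperature must be positive (K)")
  pc <- physical_constants(T_K, q)
  D_nm2_ms <- D_um2_ms * 1e6
  # F/(R T) is per volt; divide by 1000 for per millivolt
  D_nm2_ms * q * pc$F_C_mol / (pc$R_J_molK * T_K) / 1000
}

#' In-plane electrodiffusive drift displacement over one time step
#'
#' The in-plane force on a charged particle in the cleft derives from the
#' extracellular cleft potential phi(r) = Vo - V(r), so the radial drift
#' velocity is `v_r = -mu * dphi/dr = mu * dV/dr`. For glutamate (q = -1)
#' this retains the transmitter when the cleft interior is relatively
#' depolarized (positive Vo, or a depolarizing spike) and expels it when the
#' interior is relatively hyperpolarized; flipping the sign of Vo flips the
#' drift exactly.
#'
#' @param xy n x 2 matrix of in-plane positions (nm) of in-cleft particles
#' @param E_at_r radial voltage gradient dV/dr at each particle (mV/nm),
#'   from [radial_field()]
#' @param mu mobility (nm^2/(ms mV)) from [mobility()]
#' @param dt_ms time step (ms)
#' @return n x 2 matrix of displacements (nm), directed radially
#' @export
drift_displacement <- function(xy, E_at_r, mu, dt_ms) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  v <- mu * E_at_r * dt_ms               # radial displacement magnitude, nm
  scale <- ifelse(r > 0, v / r, 0)       # E(0) = 0 by symmetry anyway
  cbind(xy[, 1] * scale, xy[, 2] * scale)
}
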