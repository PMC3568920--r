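#' Initialize the intracleft ion state
#'
#' Pre-equilibrated Na+, K+ and Cl- concentrations on the radial bin grid of
#' the cleft, at the bath values of the recording solution. Defaults follow
#' the standard slice recording solution (124 NaCl + 26 NaHCO3 +
#' 1.25 NaH2PO4 + 3 KCl + divalent chlorides): Na 151.25, K 3, Cl 135 mM.
#' In-cleft ion diffusion coefficients default to half their free-solution
#' values to reflect macromolecular crowding (same spirit as the reduced
#' glutamate D inside the cleft); all are config-exposed.
#'
#' @param geom a `cleft_geometry`
#' @param baseline_mM named vector `c(na = , k = , cl = )` of bath
#'   concentrations (mM)
#' @param D_um2_ms named vector of in-cleft diffusion coefficients
#' @param bin_width_nm radial bin width (default: geometry's)
#' @return object of class `ion_state`
#' @export
ion_state_init <- function(geom,
                           baseline_mM = c(na = 151.25, k = 3, cl = 135),
                           D_um2_ms = c(na = 0.66, k = 0.98, cl = 1.0),
                           bin_width_nm = geom$bin_width_nm) {
  stopifnot(inherits(geom, "cleft_geometry"), all(baseline_mM >= 0))
  R <- geom$outer_radius_nm
  edges <- seq(0, R, by = bin_width_nm)
  if (edges[length(edges)] < R) edges <- c(edges, R)
  nb <- length(edges) - 1
  conc <- matrix(rep(baseline_mM, each = nb), nb, 3,
                 dimnames = list(NULL, c("na", "k", "cl")))
  structure(list(
    geom = geom, edges = edges,
    vol_nm3 = pi * diff(edges^2) * geom$cleft_height_nm,
    conc_mM = conc, baseline_mM = baseline_mM, D_um2_ms = D_um2_ms
  ), class = "ion_state")
}

#' Advance the intracleft ion concentrations by one duty cycle
#'
#' Each channel's per-ion current is converted to a molar flux `I/(z F)`,
#' added to (outward current) or removed from (inward current) the channel's
#' radial bin, Cl- is redistributed electroneutrally (its concentration
#' change tracks the net cation change), and the bins then exchange by
#' radial diffusion (conservative finite-volume update, with the edge bin
#' clamped to the bath values).
#'
#' @param ion_state an `ion_state`
#' @param per_receptor_currents data.frame with columns `bin` (1-based
#'   radial bin index) and per-ion currents `i_na_pA`, `i_k_pA` (signed,
#'   positive = outward = into the cleft), one row per channel or per
#'   channel group
#' @param dt_ms time step (ms)
#' @param substeps diffusion substeps (stability margin)
#' @return the updated `ion_state`
#' @export
ion_update <- function(ion_state, per_receptor_currents, dt_ms, substeps = 2) {
  stopifnot(inherits(ion_state, "ion_state"), dt_ms > 0)
  st <- ion_state
  nb <- nrow(st$conc_mM)
  FARADAY <- 96485.33212
  # explicit diffusion stability: substep until h <= bin_width^2/(4 D_max)
  binw <- diff(st$edges[1:2])
  substeps <- max(substeps,
                  ceiling(dt_ms * 4e6 * max(st$D_um2_ms) / binw^2))

  if (nrow(per_receptor_currents)) {
    pc <- per_receptor_currents
    if (any(pc$bin < 1 | pc$bin > nb)) stop("channel bin index out of range")
    # pA * ms / (z F V) -> mM ; 1e12 folds the pico/ms/L unit conversions
    to_mM <- function(i_pA, bin, z) i_pA * dt_ms * 1e12 / (z * FARADAY * st$vol_nm3[bin])
    dna <- dk <- numeric(nb)
    add <- function(acc, bin, val) { for (j in seq_along(bin)) acc[bin[j]] <- acc[bin[j]] + val[j]; acc }
    dna <- add(dna, pc$bin, to_mM(pc$i_na_pA, pc$bin, 1))
    dk  <- add(dk,  pc$bin, to_mM(pc$i_k_pA,  pc$bin, 1))
    st$conc_mM[, "na"] <- st$conc_mM[, "na"] + dna
    st$conc_mM[, "k"]  <- st$conc_mM[, "k"]  + dk
    st$conc_mM[, "cl"] <- st$conc_mM[, "cl"] + dna + dk  # electroneutral
  }

  # radial diffusion, finite volume on the annular grid
  r_e <- st$edges[2:nb]                     # interior interface radii
  dr  <- diff((st$edges[-length(st$edges)] + st$edges[-1]) / 2)
  area <- 2 * pi * r_e * st$geom$cleft_height_nm
  h <- dt_ms / substeps
  for (ion in colnames(st$conc_mM)) {
    D <- st$D_um2_ms[[ion]] * 1e6           # nm^2/ms
    C <- st$conc_mM[, ion]
    for (s in seq_len(substeps)) {
      J <- -D * diff(C) / dr * area         # mM * nm^3 / ms across interfaces
      C <- C + h * (c(0, J) - c(J, 0)) / st$vol_nm3
      C[nb] <- st$baseline_mM[[ion]]        # edge clamped to bath
    }
    if (any(C < 0))
      stop("negative ", ion, " concentration after update: time step too large")
    st$conc_mM[, ion] <- C
  }
  st
}

#' Maximum relative ion perturbation over a run
#'
#' `max over time and bins of |C - C_baseline| / C_baseline * 100`, per ion.
#'
#' @param ion_history either a 3-D array `[time, bin, ion]` of
#'   concentrations (mM) with dimnames ions `na`, `k`, `cl`, or a list of
#'   `ion_state` snapshots
#' @param baseline_mM named baseline concentrations; taken from the first
#'   snapshot when a list is given
#' @return named vector of maximal perturbations, percent per ion
#' @export
max_perturbation <- function(ion_history, baseline_mM = NULL) {
  if (is.list(ion_history) && inherits(ion_history[[1]], "ion_state")) {
    baseline_mM <- ion_history[[1]]$baseline_mM
    ion_history <- aperm(simplify2array(lapply(ion_history, `[[`, "conc_mM")),
                         c(3, 1, 2))
    dimnames(ion_history)[[3]] <- c("na", "k", "cl")
  }
  if (is.null(baseline_mM)) stop("baseline concentrations required")
  ions <- dimnames(ion_history)[[3]]
  out <- stats::setNames(numeric(length(ions)), ions)
  for (ion in ions) {
    b <- baseline_mM[[ion]]
    out[ion] <- if (b > 0) max(abs(ion_history[, , ion] - b)) / b * 100 else 0
  }
  out
}
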