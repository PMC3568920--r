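#' Build the glomerular geometry of a mossy-fiber to granule-cell synapse
#'
#' Constructs the cuboid synaptic environment: a narrow cleft of height
#' `cleft_height_nm` between the pre- and postsynaptic cuboids (square
#' footprint of side `apposition_width_nm`), a postsynaptic density (PSD)
#' disc of width `psd_width_nm` carrying the ionotropic receptors, a
#' perisynaptic annulus carrying mGluR1s, and a square lattice of identical
#' neighboring cuboid pairs separated by `neighbor_gap_nm` that stand in for
#' the surrounding glomerular structures. An absorbing sphere at
#' `escape_radius_nm` removes glutamate that has diffused out of the
#' neighborhood (standing in for uptake/dilution in the glomerulus).
#'
#' The electric-field solution assumes rotational symmetry, so the field is
#' evaluated in the equivalent radial coordinate r (in-plane distance from
#' the PSD center) with `ra = psd_width/2` and `R_out = apposition_width/2`.
#'
#' @param config optional named list overriding any of the defaults below
#'   (lengths in nm): `cleft_height_nm` (16), `apposition_width_nm` (600),
#'   `psd_width_nm` (160), `neighbor_gap_nm` (50), `mglur_ring_inner_nm`
#'   (172.5), `mglur_ring_outer_nm` (187.5), `escape_radius_nm` (1500),
#'   `structure_height_nm` (1500), `bin_width_nm` (20).
#' @return object of class `cleft_geometry` with the fields above plus the
#'   derived radii `active_zone_radius_nm` (ra) and `outer_radius_nm` (R_out)
#'   and the lattice pitch.
#' @export
build_geometry <- function(config = list()) {
  g <- list(
    cleft_height_nm     = 16,
    apposition_width_nm = 600,
    psd_width_nm        = 160,
    neighbor_gap_nm     = 50,
    mglur_ring_inner_nm = 172.5,
    mglur_ring_outer_nm = 187.5,
    escape_radius_nm    = 1500,
    structure_height_nm = 1500,
    bin_width_nm        = 20
  )
  unknown <- setdiff(names(config), names(g))
  if (length(unknown))
    stop("unknown geometry key(s): ", paste(unknown, collapse = ", "))
  g[names(config)] <- config

  num <- vapply(g, is.numeric, logical(1))
  if (!all(num)) stop("all geometry entries must be numeric")
  if (any(unlist(g) <= 0)) stop("all geometry dimensions must be positive")
  if (g$psd_width_nm > g$apposition_width_nm)
    stop("non-physical geometry: PSD wider than the apposition area (psd_width_nm > apposition_width_nm)")
  if (g$mglur_ring_outer_nm <= g$mglur_ring_inner_nm)
    stop("non-physical geometry: mGluR ring outer radius must exceed inner radius")

  g$active_zone_radius_nm <- g$psd_width_nm / 2
  g$outer_radius_nm       <- g$apposition_width_nm / 2
  g$lattice_pitch_nm      <- g$apposition_width_nm + g$neighbor_gap_nm

  if (!(g$active_zone_radius_nm <= g$outer_radius_nm))
    stop("non-physical geometry: ra must not exceed R_out")
  if (g$outer_radius_nm >= g$escape_radius_nm)
    stop("non-physical geometry: escape radius must lie beyond the apposition (R_out < escape_radius)")

  structure(g, class = "cleft_geometry")
}

#' @export
print.cleft_geometry <- function(x, ...) {
  cat("Synaptic cleft geometry (nm):\n")
  cat(sprintf("  cleft height (delta) %.4g | apposition %.4g (R_out %.4g) | PSD %.4g (ra %.4g)\n",
              x$cleft_height_nm, x$apposition_width_nm, x$outer_radius_nm,
              x$psd_width_nm, x$active_zone_radius_nm))
  cat(sprintf("  mGluR annulus [%.4g, %.4g] | neighbor gap %.4g | escape shell %.4g\n",
              x$mglur_ring_inner_nm, x$mglur_ring_outer_nm,
              x$neighbor_gap_nm, x$escape_radius_nm))
  invisible(x)
}

#' Scatter receptor populations over their placement zones
#'
#' AMPARs and NMDARs are placed uniformly at random inside the PSD disc
#' (radius `ra`); mGluR1s inside the perisynaptic annulus. Placement is
#' reproducible for a fixed seed and does not disturb the caller's RNG state.
#'
#' @param geom a `cleft_geometry`
#' @param counts numeric vector `c(ampar, nmdar, mglur)`, each >= 0
#'   (defaults 125, 50, 30)
#' @param seed integer seed (mandatory; no silent entropy)
#' @param conductance_pS unitary conductances for AMPAR and NMDAR (pS);
#'   mGluR1 is metabotropic and carries 0 pS
#' @return data.frame of class `receptor_layout` with columns
#'   `type` (factor AMPAR/NMDAR/mGluR1), `x_nm`, `y_nm`, `conductance_pS`
#' @export
place_receptors <- function(geom, counts = c(125, 50, 30), seed,
                            conductance_pS = c(AMPAR = 10, NMDAR = 25)) {
  stopifnot(inherits(geom, "cleft_geometry"))
  if (missing(seed)) stop("an explicit seed is required")
  if (length(counts) != 3 || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be three non-negative integers (AMPAR, NMDAR, mGluR1)")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  disc <- function(n, r_in, r_out) {
    if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
    if (r_out <= r_in && n > 0) stop("placement zone of zero area with nonzero count")
    r  <- sqrt(stats::runif(n, r_in^2, r_out^2))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(x = r * cos(th), y = r * sin(th))
  }
  ra <- geom$active_zone_radius_nm
  a  <- disc(counts[1], 0, ra)
  n  <- disc(counts[2], 0, ra)
  m  <- disc(counts[3], geom$mglur_ring_inner_nm, geom$mglur_ring_outer_nm)

  out <- data.frame(
    type = factor(rep(c("AMPAR", "NMDAR", "mGluR1"), counts),
                  levels = c("AMPAR", "NMDAR", "mGluR1")),
    x_nm = c(a[, 1], n[, 1], m[, 1]),
    y_nm = c(a[, 2], n[, 2], m[, 2]),
    conductance_pS = rep(c(unname(conductance_pS["AMPAR"]),
                           unname(conductance_pS["NMDAR"]), 0), counts)
  )
  class(out) <- c("receptor_layout", class(out))
  out
}

#' Classify a point of space with respect to the synaptic environment
#'
#' Partition of space used by the particle engine: `cleft` is the slab
#' between the central pre- and postsynaptic membranes (inside the central
#' apposition footprint, 0 < z < delta); `escaped` is beyond the absorbing
#' shell; everything else (gaps between cuboids, space above/below the
#' structures, neighboring clefts) is `extracleft`. Points inside a solid
#' cuboid are never produced by a correct particle update and are reported
#' as `solid`.
#'
#' @param geom a `cleft_geometry`
#' @param xyz numeric vector of length 3 or an n x 3 matrix, coordinates in
#'   nm (origin at the PSD center on the postsynaptic membrane, z up across
#'   the cleft)
#' @return character vector of regions, one per point
#' @export
classify_position <- function(geom, xyz) {
  stopifnot(inherits(geom, "cleft_geometry"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  if (ncol(xyz) != 3 || !all(is.finite(xyz))) stop("xyz must be finite n x 3 coordinates")
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  half  <- geom$apposition_width_nm / 2
  delta <- geom$cleft_height_nm
  H     <- geom$structure_height_nm
  pitch <- geom$lattice_pitch_nm

  out <- rep("extracleft", nrow(xyz))
  out[x^2 + y^2 + z^2 > geom$escape_radius_nm^2] <- "escaped"

  cx <- pitch * round(x / pitch)
  cy <- pitch * round(y / pitch)
  in_foot  <- abs(x - cx) <= half & abs(y - cy) <= half
  central  <- in_foot & cx == 0 & cy == 0
  in_slab  <- z >= 0 & z <= delta
  in_solid <- in_foot & ((z < 0 & z >= -H) | (z > delta & z <= delta + H))

  out[out != "escaped" & central & in_slab] <- "cleft"
  out[out != "escaped" & in_solid] <- "solid"
  out
}
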