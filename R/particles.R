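#' Release a glutamate ensemble at the cleft center
#'
#' All molecules start as a point source at the cleft mid-height above the
#' PSD center, the release site of the mossy-fiber terminal.
#'
#' @param geom a `cleft_geometry`
#' @param n number of molecules (default 3000)
#' @param t_release_ms release time stamp (ms)
#' @param D_cleft_um2_ms diffusion coefficient inside the immediate cleft
#'   (default 0.25 um^2/ms, macromolecule-crowded)
#' @param D_out_um2_ms diffusion coefficient outside (default 0.4 um^2/ms,
#'   intraglomerular)
#' @param seed integer seed driving the per-particle random streams
#' @return object of class `particle_ensemble`: positions (nm), alive flags,
#'   region labels, diffusion coefficients, step counter
#' @export
release <- function(geom, n = 3000, t_release_ms = 0,
                    D_cleft_um2_ms = 0.25, D_out_um2_ms = 0.4, seed = 1) {
  stopifnot(inherits(geom, "cleft_geometry"), n >= 0)
  pos <- matrix(rep(c(0, 0, geom$cleft_height_nm / 2), each = n), ncol = 3)
  colnames(pos) <- c("x", "y", "z")
  structure(list(
    pos = pos, alive = rep(TRUE, n), geom = geom,
    D_cleft_um2_ms = D_cleft_um2_ms, D_out_um2_ms = D_out_um2_ms,
    t_ms = t_release_ms, step = 0L, seed = as.integer(seed)
  ), class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("Particle ensemble: %d molecules (%d alive, %d in cleft), t = %.4g ms\n",
              nrow(x$pos), sum(x$alive), cleft_count(x), x$t_ms))
  invisible(x)
}

#' One Brownian step of the glutamate ensemble
#'
#' Each alive molecule moves by exactly `sqrt(6 D dt)` in a uniformly random
#' 3-D direction, with D chosen by the molecule's current region (cleft vs
#' glomerular space). Directions come from counter-based per-particle random
#' streams, so a fixed seed reproduces the walk bit-identically and the
#' same particle consumes the same stream regardless of ensemble order.
#' `mode = "gaussian"` replaces the fixed-length step by independent
#' Gaussian increments of standard deviation `sqrt(2 D dt)` per axis.
#'
#' @param ensemble a `particle_ensemble`
#' @param dt_ms time step (ms)
#' @param mode "fixed" (default) or "gaussian"
#' @return the ensemble with positions and step counter advanced (boundary
#'   conditions are applied separately by [apply_boundaries()])
#' @export
brownian_step <- function(ensemble, dt_ms, mode = c("fixed", "gaussian")) {
  mode <- match.arg(mode)
  stopifnot(dt_ms > 0, inherits(ensemble, "particle_ensemble"))
  n <- nrow(ensemble$pos)
  if (n == 0) { ensemble$step <- ensemble$step + 1L; return(ensemble) }
  region <- classify_position(ensemble$geom, ensemble$pos)
  D <- ifelse(region == "cleft", ensemble$D_cleft_um2_ms, ensemble$D_out_um2_ms)
  D_nm2 <- D * 1e6
  idx <- which(ensemble$alive)
  if (length(idx)) {
    if (mode == "fixed") {
      dirs <- cpp_unit_directions(n, ensemble$seed, ensemble$step)
      step_len <- sqrt(6 * D_nm2[idx] * dt_ms)
      ensemble$pos[idx, ] <- ensemble$pos[idx, , drop = FALSE] +
        dirs[idx, , drop = FALSE] * step_len
    } else {
      g <- cpp_gaussian_increments(n, ensemble$seed, ensemble$step)
      sd_len <- sqrt(2 * D_nm2[idx] * dt_ms)
      ensemble$pos[idx, ] <- ensemble$pos[idx, , drop = FALSE] +
        g[idx, , drop = FALSE] * sd_len
    }
  }
  ensemble$step <- ensemble$step + 1L
  ensemble$t_ms <- ensemble$t_ms + dt_ms
  ensemble
}

#' Apply reflective and absorbing boundaries
#'
#' Specular reflection off every solid cuboid face (central and neighboring
#' pre/postsynaptic structures); absorption (death) at the escape shell.
#' Escaped molecules never return. Errors if a molecule is embedded deeper
#' inside a solid than `max_embed_nm` (a symptom of an oversized time step).
#'
#' @param ensemble a `particle_ensemble`
#' @param geom geometry (defaults to the ensemble's own)
#' @param max_embed_nm deepest tolerated penetration before erroring
#' @return the ensemble with legal positions and updated alive flags
#' @export
apply_boundaries <- function(ensemble, geom = ensemble$geom,
                             max_embed_nm = 25) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  n <- nrow(ensemble$pos)
  if (n == 0) return(ensemble)
  alive <- ensemble$alive
  pos <- ensemble$pos
  half  <- geom$apposition_width_nm / 2
  delta <- geom$cleft_height_nm
  H     <- geom$structure_height_nm
  pitch <- geom$lattice_pitch_nm
  esc2  <- geom$escape_radius_nm^2

  for (iter in 1:5) {
    x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
    cx <- pitch * round(x / pitch); cy <- pitch * round(y / pitch)
    dxc <- x - cx; dyc <- y - cy
    in_foot <- abs(dxc) <= half & abs(dyc) <= half
    lower <- alive & in_foot & z < 0 & z > -H
    upper <- alive & in_foot & z > delta & z < delta + H
    bad <- which(lower | upper)
    if (!length(bad)) break
    for (i in bad) {
      px <- half - abs(dxc[i]); py <- half - abs(dyc[i])
      if (lower[i]) { pz_near <- -z[i]; z_near <- 0; z_far <- -H }
      else          { pz_near <- z[i] - delta; z_near <- delta; z_far <- delta + H }
      pz_far <- abs(z[i] - z_far)
      pen <- c(px, py, pz_near, pz_far)
      if (min(pen) > max_embed_nm)
        stop("particle embedded ", round(min(pen), 2),
             " nm inside a solid: time step too large")
      face <- which.min(pen)
      if (face == 1) pos[i, 1] <- cx[i] + sign(dxc[i]) * (2 * half - abs(dxc[i]))
      else if (face == 2) pos[i, 2] <- cy[i] + sign(dyc[i]) * (2 * half - abs(dyc[i]))
      else if (face == 3) pos[i, 3] <- 2 * z_near - z[i]
      else pos[i, 3] <- 2 * z_far - z[i]
    }
  }
  r2 <- rowSums(pos^2)
  newly_dead <- alive & r2 > esc2
  alive[newly_dead] <- FALSE
  ensemble$pos <- pos
  ensemble$alive <- alive
  ensemble
}

#' Radial glutamate concentration profile inside the cleft
#'
#' Annular binning of the in-cleft molecules; concentrations in mM from the
#' bin volumes (annulus area times cleft height). Molecules in the cleft
#' corners beyond `R_out` (the apposition is square, the radial grid is
#' round) land in a final overflow bin whose volume is the corner area times
#' the cleft height, so the total count is conserved. An optional moving
#' average over adjacent bins smooths counting noise.
#'
#' @param ensemble a `particle_ensemble`
#' @param bin_width_nm radial bin width (default: geometry's, 20 nm)
#' @param smooth_bins half-width of a moving-average smoothing kernel in
#'   bins (0 = no smoothing)
#' @return object of class `concentration_field`: data.frame with bin
#'   edges (nm), counts and concentration (mM)
#' @export
concentration_field <- function(ensemble, bin_width_nm = ensemble$geom$bin_width_nm,
                                smooth_bins = 0) {
  geom <- ensemble$geom
  if (bin_width_nm <= 0) stop("zero-volume bin")
  R <- geom$outer_radius_nm
  edges <- seq(0, R, by = bin_width_nm)
  if (edges[length(edges)] < R) edges <- c(edges, R)
  nb <- length(edges) - 1

  region <- classify_position(geom, ensemble$pos)
  incleft <- ensemble$alive & region == "cleft"
  r <- sqrt(ensemble$pos[incleft, 1]^2 + ensemble$pos[incleft, 2]^2)

  counts <- numeric(nb + 1)
  main <- r <= R
  if (any(main))
    counts[1:nb] <- tabulate(pmin(findInterval(r[main], edges,
                                               rightmost.closed = TRUE), nb), nb)
  counts[nb + 1] <- sum(!main)            # square-corner overflow

  delta <- geom$cleft_height_nm
  vol <- c(pi * diff(edges^2), geom$apposition_width_nm^2 - pi * R^2) * delta
  conc <- 1e27 / 6.02214076e23 * counts / vol   # molecules/nm^3 -> mM

  if (smooth_bins > 0) {
    k <- 2 * smooth_bins + 1
    sm <- stats::filter(conc[1:nb], rep(1 / k, k), sides = 2)
    conc[1:nb] <- ifelse(is.na(sm), conc[1:nb], sm)
  }
  structure(data.frame(
    r_lo_nm = c(edges[-length(edges)], R), r_hi_nm = c(edges[-1], NA),
    count = counts, volume_nm3 = vol, conc_mM = conc
  ), class = c("concentration_field", "data.frame"))
}

#' Number of molecules currently inside the synaptic cleft
#'
#' @param ensemble a `particle_ensemble`
#' @return integer count
#' @export
cleft_count <- function(ensemble) {
  if (nrow(ensemble$pos) == 0) return(0L)
  sum(ensemble$alive &
        classify_position(ensemble$geom, ensemble$pos) == "cleft")
}
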