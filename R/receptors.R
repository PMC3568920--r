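#' Construct a receptor kinetic scheme
#'
#' A Markov state graph for a ligand-gated receptor. Transition rates are in
#' ms^-1; rates tagged `ligand = "glu"` (or `"ant"`) are second-order and
#' multiplied at run time by the local glutamate (or antagonist)
#' concentration in mM, so their unit is mM^-1 ms^-1.
#'
#' @param name human-readable name
#' @param states character vector of state names
#' @param n_bound integer per state: number of agonist molecules bound
#' @param n_sites total number of agonist binding sites
#' @param transitions data.frame with columns `from`, `to`, `rate`,
#'   `ligand` (one of "none", "glu", "ant")
#' @param resting_state name of the unbound closed state receptors start in
#' @param open_states states that conduct (weight 1 each)
#' @param active_states states counted as "active" for metabotropic readout
#'   (for channels, the open states)
#' @param conductance_pS unitary conductance (pS; 0 for metabotropic)
#' @param erev_mV reversal potential of the conducted current (mV)
#' @param q10 temperature sensitivity of all rates
#' @param t_ref_K temperature the shipped rates refer to
#' @return object of class `kinetic_scheme`
#' @export
kinetic_scheme <- function(name, states, n_bound, n_sites, transitions,
                           resting_state, open_states, active_states = open_states,
                           conductance_pS = 0, erev_mV = 0, q10 = 2,
                           t_ref_K = 307) {
  stopifnot(is.character(states), length(states) >= 2,
            length(n_bound) == length(states),
            all(c("from", "to", "rate", "ligand") %in% names(transitions)))
  if (anyDuplicated(states)) stop("duplicate state names")
  if (any(transitions$rate < 0)) stop("rates must be >= 0")
  if (!all(transitions$ligand %in% c("none", "glu", "ant")))
    stop("ligand must be one of 'none', 'glu', 'ant'")
  if (!all(c(transitions$from, transitions$to) %in% states))
    stop("transition endpoints must be named states")
  if (!resting_state %in% states || n_bound[match(resting_state, states)] != 0 ||
      resting_state %in% open_states)
    stop("resting_state must be an unbound, closed state")
  if (!all(open_states %in% states) || !all(active_states %in% states))
    stop("open/active states must be named states")

  # connectivity of the undirected transition graph
  adj <- matrix(FALSE, length(states), length(states),
                dimnames = list(states, states))
  adj[cbind(transitions$from, transitions$to)] <- TRUE
  adj <- adj | t(adj)
  reach <- states[1]
  repeat {
    nxt <- unique(c(reach, states[apply(adj[reach, , drop = FALSE], 2, any)]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (length(reach) != length(states)) stop("scheme graph is not connected")

  structure(list(
    name = name, states = states, n_bound = as.integer(n_bound),
    n_sites = as.integer(n_sites),
    transitions = data.frame(from = as.character(transitions$from),
                             to = as.character(transitions$to),
                             rate = as.numeric(transitions$rate),
                             ligand = as.character(transitions$ligand),
                             stringsAsFactors = FALSE),
    resting_state = resting_state, open_states = open_states,
    active_states = active_states, conductance_pS = conductance_pS,
    erev_mV = erev_mV, q10 = q10, t_ref_K = t_ref_K
  ), class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme '%s': %d states, %d transitions, %d binding site(s)\n",
              x$name, length(x$states), nrow(x$transitions), x$n_sites))
  cat(sprintf("  open: %s | conductance %g pS | Q10 %g @ %g K\n",
              paste(x$open_states, collapse = ","), x$conductance_pS,
              x$q10, x$t_ref_K))
  invisible(x)
}

#' Load a kinetic scheme from a JSON parameter file
#'
#' @param path file path, or one of the shipped scheme names
#'   `"ampar"`, `"nmdar"`, `"mglur1"`
#' @return a `kinetic_scheme`
#' @export
load_scheme <- function(path) {
  if (path %in% c("ampar", "nmdar", "mglur1"))
    path <- system.file("extdata", "schemes", paste0(path, ".json"),
                        package = "cleftsim", mustWork = TRUE)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  kinetic_scheme(name = j$name, states = j$states, n_bound = j$n_bound,
                 n_sites = j$n_sites, transitions = j$transitions,
                 resting_state = j$resting_state,
                 open_states = as.character(unlist(j$open_states)),
                 active_states = as.character(unlist(j$active_states)),
                 conductance_pS = j$conductance_pS, erev_mV = j$erev_mV,
                 q10 = j$q10, t_ref_K = j$t_ref_K)
}

#' Infinitesimal generator of a scheme at given ligand concentrations
#'
#' @param scheme a `kinetic_scheme`
#' @param C_glu_mM local glutamate concentration (mM)
#' @param C_ant_mM antagonist concentration (mM), for schemes carrying
#'   antagonist transitions
#' @return n x n rate matrix Q (ms^-1) with rows summing to zero; the
#'   off-diagonal entry in row i, column j is the i -> j rate
#' @export
rate_matrix <- function(scheme, C_glu_mM, C_ant_mM = 0) {
  if (C_glu_mM < 0 || C_ant_mM < 0) stop("concentrations must be >= 0")
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  mult <- ifelse(tr$ligand == "glu", C_glu_mM,
                 ifelse(tr$ligand == "ant", C_ant_mM, 1))
  for (k in seq_len(nrow(tr)))
    Q[tr$from[k], tr$to[k]] <- Q[tr$from[k], tr$to[k]] + tr$rate[k] * mult[k]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Resting-state probability vector of a scheme
#'
#' All probability in the resting (unbound, closed) state; with a nonzero
#' pre-equilibrated antagonist concentration, the stationary distribution of
#' the zero-glutamate generator is returned instead (bath-applied antagonist
#' binds before release).
#'
#' @inheritParams rate_matrix
#' @return probability vector over states
#' @export
resting_occupancy <- function(scheme, C_ant_mM = 0) {
  p <- stats::setNames(numeric(length(scheme$states)), scheme$states)
  p[scheme$resting_state] <- 1
  if (C_ant_mM > 0 && any(scheme$transitions$ligand == "ant")) {
    Q <- rate_matrix(scheme, 0, C_ant_mM)
    # stationary distribution restricted to states reachable at C_glu = 0
    A <- rbind(t(Q), rep(1, ncol(Q)))
    b <- c(numeric(ncol(Q)), 1)
    p[] <- pmax(stats::setNames(qr.solve(A, b), scheme$states), 0)
    p <- p / sum(p)
  }
  p
}

# exact action of exp(Q*dt) on a probability row-vector by uniformization
.uniformization_step <- function(Q, p, dt_ms, tol = 1e-14) {
  lam <- max(-diag(Q))
  if (lam * dt_ms == 0) return(p)
  n_sub <- max(1L, ceiling(lam * dt_ms / 100))
  h <- dt_ms / n_sub
  M <- diag(nrow(Q)) + Q / lam
  for (s in seq_len(n_sub)) {
    w <- exp(-lam * h)
    v <- p
    acc <- w * v
    remaining <- 1 - w
    k <- 0
    while (remaining > tol) {
      k <- k + 1
      v <- v %*% M
      w <- w * lam * h / k
      acc <- acc + w * v
      remaining <- remaining - w
    }
    p <- as.numeric(acc) / sum(acc)
  }
  p
}

#' Advance receptor state probabilities by one time step
#'
#' Mean-field master-equation propagation of a state-probability vector
#' under a frozen local glutamate concentration. The default propagator is
#' the uniformization expansion of `exp(Q dt)`, exact to machine precision
#' for the frozen generator and unconditionally stable (it tolerates the
#' enormous binding rates seen in the first microseconds after a point
#' release). `method = "euler"` is the plain forward-Euler update with a
#' stability guard: it stops with an error naming the offending state when
#' `max total exit rate * dt >= 0.1`.
#'
#' @param state list with elements `scheme` (a `kinetic_scheme`) and `p`
#'   (probability vector over its states)
#' @param C_mM local glutamate concentration (mM)
#' @param dt_ms time step (ms)
#' @param method "uniformization" (default) or "euler"
#' @param C_ant_mM antagonist concentration (mM)
#' @return the state with `p` advanced by `dt_ms`
#' @export
step_occupancy <- function(state, C_mM, dt_ms,
                           method = c("uniformization", "euler"),
                           C_ant_mM = 0) {
  method <- match.arg(method)
  stopifnot(dt_ms > 0, inherits(state$scheme, "kinetic_scheme"))
  Q <- rate_matrix(state$scheme, C_mM, C_ant_mM)
  p <- state$p
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12))
    stop("state probabilities must be a distribution")
  if (method == "euler") {
    exit <- -diag(Q)
    if (max(exit) * dt_ms >= 0.1) {
      i <- which.max(exit)
      stop(sprintf(
        "stability guard violated: total exit rate %.4g/ms from state '%s' times dt = %.4g >= 0.1",
        exit[i], state$scheme$states[i], max(exit) * dt_ms))
    }
    p <- p + as.numeric(p %*% Q) * dt_ms
  } else {
    p <- .uniformization_step(Q, p, dt_ms)
  }
  state$p <- stats::setNames(p / sum(p), state$scheme$states)
  state
}

#' Augment a scheme with a competitive antagonist
#'
#' Builds the product scheme in which the antagonist competes with
#' glutamate for the same binding sites: every state with free sites gains
#' antagonist-bound (closed, non-conducting) counterparts. Agonist binding
#' rates at antagonist occupancy a are rescaled by the remaining free-site
#' count; conformational and unbinding rates are copied unchanged. This is
#' the transform used to model the low-affinity, fast-dissociating AMPAR
#' antagonist gamma-DGG, whose relative block reports the intracleft
#' glutamate transient.
#'
#' @param scheme a `kinetic_scheme`
#' @param kon_ant antagonist binding rate per site (mM^-1 ms^-1)
#' @param koff_ant antagonist unbinding rate per occupied site (ms^-1)
#' @param conc_ant_mM antagonist concentration (mM; stored on the scheme as
#'   `ant_mM` and applied wherever the scheme is propagated)
#' @return augmented `kinetic_scheme` with attribute `ant_mM`
#' @export
add_competitive_antagonist <- function(scheme, kon_ant, koff_ant, conc_ant_mM) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (conc_ant_mM < 0) stop("antagonist concentration must be >= 0")
  if (kon_ant < 0 || koff_ant < 0) stop("antagonist rates must be >= 0")
  ns <- scheme$n_sites
  g  <- stats::setNames(scheme$n_bound, scheme$states)

  lab <- function(s, a) if (a == 0) s else paste0(s, "_A", a)
  grid <- do.call(rbind, lapply(scheme$states, function(s) {
    data.frame(base = s, a = 0:(ns - g[[s]]), stringsAsFactors = FALSE)
  }))
  grid$state <- mapply(lab, grid$base, grid$a)

  tr <- scheme$transitions
  out_tr <- list()
  for (k in seq_len(nrow(tr))) {
    s1 <- tr$from[k]; s2 <- tr$to[k]
    amax <- min(ns - g[[s1]], ns - g[[s2]])
    for (a in 0:amax) {
      rate <- tr$rate[k]
      if (tr$ligand[k] == "glu" && g[[s2]] == g[[s1]] + 1 && a > 0) {
        free0 <- ns - g[[s1]]            # free sites the base rate assumed
        rate <- rate * (free0 - a) / free0
        if (rate <= 0) next
      }
      out_tr[[length(out_tr) + 1]] <-
        data.frame(from = lab(s1, a), to = lab(s2, a), rate = rate,
                   ligand = tr$ligand[k], stringsAsFactors = FALSE)
    }
  }
  # antagonist binding/unbinding with free-site statistics
  for (i in seq_len(nrow(grid))) {
    s <- grid$base[i]; a <- grid$a[i]
    free <- ns - g[[s]] - a
    if (free > 0)
      out_tr[[length(out_tr) + 1]] <-
        data.frame(from = grid$state[i], to = lab(s, a + 1),
                   rate = free * kon_ant, ligand = "ant",
                   stringsAsFactors = FALSE)
    if (a > 0)
      out_tr[[length(out_tr) + 1]] <-
        data.frame(from = grid$state[i], to = lab(s, a - 1),
                   rate = a * koff_ant, ligand = "none",
                   stringsAsFactors = FALSE)
  }

  aug <- kinetic_scheme(
    name = paste0(scheme$name, " + competitive antagonist"),
    states = grid$state, n_bound = g[grid$base], n_sites = ns,
    transitions = do.call(rbind, out_tr),
    resting_state = scheme$resting_state,
    open_states = scheme$open_states, active_states = scheme$active_states,
    conductance_pS = scheme$conductance_pS, erev_mV = scheme$erev_mV,
    q10 = scheme$q10, t_ref_K = scheme$t_ref_K)
  aug$ant_mM <- conc_ant_mM
  aug
}

#' Scale all rates of a scheme to a target temperature
#'
#' Multiplies every rate by `Q10^((T - T_ref)/10)`; the standard Q10
#' adjustment used to bring room-temperature literature rates to the
#' 33-35 C recording conditions.
#'
#' @param scheme a `kinetic_scheme`
#' @param T_K target temperature (K)
#' @param T_ref_K reference temperature (defaults to the scheme's own)
#' @param q10 Q10 factor (defaults to the scheme's own)
#' @return the scheme with rates rescaled and `t_ref_K` set to `T_K`
#' @export
q10_scale <- function(scheme, T_K, T_ref_K = scheme$t_ref_K, q10 = scheme$q10) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (q10 <= 0) stop("Q10 must be positive")
  f <- q10^((T_K - T_ref_K) / 10)
  scheme$transitions$rate <- scheme$transitions$rate * f
  scheme$t_ref_K <- T_K
  scheme
}

#' Non-competitive fractional block of a receptor population
#'
#' Deterministic scaling of the conducting population by `1 - fraction`,
#' modeling a high-affinity antagonist (e.g. NBQX at a non-saturating
#' concentration) whose inhibition does not depend on the local glutamate
#' concentration. Scales the current; the state-probability time course is
#' untouched, so the normalized decay is unchanged.
#'
#' @param population a `receptor_population` (list with `scheme`, `p`,
#'   optional `block`)
#' @param fraction blocked fraction between 0 and 1
#' @return the population with its `block` field set
#' @export
block_fraction <- function(population, fraction) {
  if (fraction < 0 || fraction > 1) stop("block fraction must be in [0, 1]")
  population$block <- fraction
  population
}

#' Total receptor-type currents from a layout and population states
#'
#' `I_type = N_type * gamma_type * P_open * (1 - block) * (Vm - Erev)`, in pA.
#'
#' @param layout a `receptor_layout` from [place_receptors()]
#' @param populations named list (by type) of lists with `scheme`, `p`
#'   (probability vector) and optional `block`
#' @param Vm_mV membrane potential (mV)
#' @param Erev_mV named or scalar reversal potential(s) (mV; default 0)
#' @return named numeric vector of currents per receptor type (pA)
#' @export
total_current <- function(layout, populations, Vm_mV, Erev_mV = 0) {
  counts <- table(layout$type)
  gam <- tapply(layout$conductance_pS, layout$type, function(x) if (length(x)) x[1] else 0)
  out <- stats::setNames(numeric(length(populations)), names(populations))
  for (ty in names(populations)) {
    pop <- populations[[ty]]
    if (!ty %in% names(counts) || counts[[ty]] == 0) next
    p_open <- sum(pop$p[pop$scheme$open_states])
    blk <- if (is.null(pop$block)) 0 else pop$block
    er <- if (length(Erev_mV) > 1) Erev_mV[[ty]] else Erev_mV
    out[ty] <- counts[[ty]] * gam[[ty]] * p_open * (1 - blk) *
      (Vm_mV - er) / 1000  # pS * mV = fA; /1000 -> pA
  }
  out
}

#' Mean active fraction of the mGluR1 population
#'
#' @param populations as in [total_current()]; uses the `mGluR1` entry
#' @return mean probability of the designated active conformational state(s)
#' @export
mglur_activation <- function(populations) {
  pop <- populations[["mGluR1"]]
  if (is.null(pop)) stop("no mGluR1 population present")
  sum(pop$p[pop$scheme$active_states])
}
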