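test_that("shipped schemes load, validate and start at rest", {
  for (nm in c("ampar", "nmdar", "mglur1")) {
    sc <- load_scheme(nm)
    expect_s3_class(sc, "kinetic_scheme")
    p <- resting_occupancy(sc)
    expect_equal(sum(p), 1)
    expect_equal(unname(p[sc$resting_state]), 1)
  }
  expect_equal(load_scheme("ampar")$conductance_pS, 10)
  expect_equal(load_scheme("nmdar")$conductance_pS, 25)
  expect_equal(load_scheme("mglur1")$conductance_pS, 0)
})

test_that("a resting scheme without ligand stays at rest forever", {
  sc <- load_scheme("ampar")
  st <- list(scheme = sc, p = resting_occupancy(sc))
  for (i in 1:50) st <- step_occupancy(st, C_mM = 0, dt_ms = 0.05)
  expect_equal(unname(st$p[sc$resting_state]), 1, tolerance = 1e-12)
})

test_that("two-state binding reaches the analytic equilibrium", {
  kon <- 5; koff <- 2; C <- 0.8
  sc <- two_state_scheme(kon, koff)
  st <- list(scheme = sc, p = resting_occupancy(sc))
  for (i in 1:400) st <- step_occupancy(st, C, dt_ms = 0.05)
  expect_equal(unname(st$p["O"]), kon * C / (kon * C + koff), tolerance = 1e-9)
})

test_that("propagation matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  sc <- three_state_scheme()
  C <- 0.5
  Q <- rate_matrix(sc, C)
  p_oracle <- as.numeric(
    matrix(c(1, 0, 0), 1) %*% Matrix::expm(Matrix::Matrix(Q * 1.0)))
  st <- list(scheme = sc, p = resting_occupancy(sc))
  for (i in 1:1000) st <- step_occupancy(st, C, dt_ms = 1e-3)
  expect_equal(unname(st$p), p_oracle, tolerance = 1e-6)
  # the uniformization step is exact for a frozen generator: one large step
  st1 <- step_occupancy(list(scheme = sc, p = resting_occupancy(sc)), C, 1.0)
  expect_equal(unname(st1$p), p_oracle, tolerance = 1e-9)
})

test_that("forward Euler agrees at small dt and guards against stiffness", {
  sc <- three_state_scheme()
  st_e <- st_u <- list(scheme = sc, p = resting_occupancy(sc))
  for (i in 1:200) {
    st_e <- step_occupancy(st_e, 0.5, 1e-3, method = "euler")
    st_u <- step_occupancy(st_u, 0.5, 1e-3, method = "uniformization")
  }
  # forward Euler is first order: agreement at the per-mille level here
  expect_equal(st_e$p, st_u$p, tolerance = 5e-3)
  expect_error(step_occupancy(st_e, C_mM = 1e4, dt_ms = 1e-3, method = "euler"),
               "stability guard")
})

test_that("probability is conserved through stiff release-like transients", {
  sc <- load_scheme("ampar")
  st <- list(scheme = sc, p = resting_occupancy(sc))
  # mimic the post-release spike: huge then collapsing concentration
  for (C in c(2e5, 5e4, 1e3, 50, 5, 0.5, 0)) {
    st <- step_occupancy(st, C, dt_ms = 1e-4)
    expect_equal(sum(st$p), 1, tolerance = 1e-9)
    expect_true(all(st$p >= 0))
  }
})

test_that("competitive antagonist transform preserves the null limit", {
  sc <- load_scheme("ampar")
  aug <- add_competitive_antagonist(sc, kon_ant = 5, koff_ant = 5,
                                    conc_ant_mM = 0)
  # with zero antagonist the open-probability time course is unchanged
  p1 <- list(scheme = sc, p = resting_occupancy(sc))
  p2 <- list(scheme = aug, p = resting_occupancy(aug))
  for (i in 1:80) {
    C <- 1 * exp(-i / 20)
    p1 <- step_occupancy(p1, C, 5e-3)
    p2 <- step_occupancy(p2, C, 5e-3, C_ant_mM = 0)
    expect_equal(sum(p2$p[aug$open_states]), sum(p1$p[sc$open_states]),
                 tolerance = 1e-9)
  }
  expect_error(add_competitive_antagonist(sc, 5, 5, -1), ">= 0")
})

test_that("antagonist equilibration and the saturating-block limit", {
  sc <- load_scheme("ampar")
  aug <- add_competitive_antagonist(sc, 5, 5, conc_ant_mM = 1)
  p0 <- resting_occupancy(aug, C_ant_mM = 1)
  # pre-equilibrated: stationary under the zero-glutamate generator
  Q <- rate_matrix(aug, 0, 1)
  expect_equal(max(abs(as.numeric(p0 %*% Q))), 0, tolerance = 1e-9)
  # Kd = koff/kon = 1 mM at 1 mM antagonist: per-site block fraction 1/2
  free <- unname(p0[sc$resting_state])
  expect_equal(free, 0.25, tolerance = 1e-6)  # (1/2)^2 for two sites

  # enormous affinity at fixed concentration silences the receptor
  hard <- add_competitive_antagonist(sc, kon_ant = 5e5, koff_ant = 5e-4,
                                     conc_ant_mM = 1)
  ph <- list(scheme = hard, p = resting_occupancy(hard, 1))
  for (i in 1:50) ph <- step_occupancy(ph, 1, 1e-2, C_ant_mM = 1)
  expect_lt(sum(ph$p[hard$open_states]), 1e-6)
})

test_that("fast-dissociating antagonist spares large transients (low-affinity block logic)", {
  # relative inhibition by the competitive antagonist decreases as the
  # glutamate transient grows: the principle that makes the low-affinity
  # blocker a reporter of the intracleft concentration
  sc <- load_scheme("ampar")
  aug <- add_competitive_antagonist(sc, 5, 5, conc_ant_mM = 1)
  run_pulse <- function(scheme, C_pulse, ant) {
    st <- list(scheme = scheme,
               p = resting_occupancy(scheme, if (ant) 1 else 0))
    peak <- 0
    for (i in 1:120) {
      C <- if (i <= 20) C_pulse else 0
      st <- step_occupancy(st, C, 5e-3, C_ant_mM = if (ant) 1 else 0)
      peak <- max(peak, sum(st$p[scheme$open_states]))
    }
    peak
  }
  rel_block <- vapply(c(0.3, 3), function(Cp) {
    1 - run_pulse(aug, Cp, TRUE) / run_pulse(sc, Cp, FALSE)
  }, numeric(1))
  expect_gt(rel_block[1], rel_block[2])   # small transient blocked more
  expect_true(all(rel_block > 0 & rel_block < 1))
})

test_that("Q10 scaling multiplies every rate by the Arrhenius factor", {
  sc <- load_scheme("nmdar")
  expect_equal(q10_scale(sc, sc$t_ref_K)$transitions$rate, sc$transitions$rate)
  up10 <- q10_scale(sc, sc$t_ref_K + 10)
  expect_equal(up10$transitions$rate, 2 * sc$transitions$rate)
  up5 <- q10_scale(sc, sc$t_ref_K + 5)
  expect_equal(up5$transitions$rate, 2^0.5 * sc$transitions$rate)
})

test_that("population currents follow N gamma P (Vm - Erev)", {
  g <- build_geometry()
  lay <- place_receptors(g, c(125, 50, 0), seed = 1)
  sc_a <- load_scheme("ampar"); sc_n <- load_scheme("nmdar")
  rest <- list(AMPAR = list(scheme = sc_a, p = resting_occupancy(sc_a)),
               NMDAR = list(scheme = sc_n, p = resting_occupancy(sc_n)))
  expect_equal(unname(total_current(lay, rest, -70)), c(0, 0))
  # 125 AMPARs fully open, 10 pS, Vm = -70, Erev = 0 -> -87.5 pA
  open_a <- rest
  open_a$AMPAR$p[] <- 0; open_a$AMPAR$p["O"] <- 1
  expect_equal(unname(total_current(lay, open_a, -70)["AMPAR"]), -87.5)
  expect_equal(unname(total_current(lay, open_a, 0)["AMPAR"]), 0)
  # non-competitive block scales the current linearly
  half <- open_a; half$AMPAR <- block_fraction(half$AMPAR, 0.5)
  expect_equal(unname(total_current(lay, half, -70)["AMPAR"]), -43.75)
  none <- open_a; none$AMPAR <- block_fraction(none$AMPAR, 1)
  expect_equal(unname(total_current(lay, none, -70)["AMPAR"]), 0)
  expect_error(block_fraction(open_a$AMPAR, 1.5), "must be in")
})

test_that("mGluR1 activation has the analytic saturating maximum", {
  sc <- load_scheme("mglur1")
  st <- list(scheme = sc, p = resting_occupancy(sc))
  for (i in 1:600) st <- step_occupancy(st, C_mM = 50, dt_ms = 0.05)
  rates <- sc$transitions
  k_act <- rates$rate[rates$from == "RG" & rates$to == "A"]
  k_de  <- rates$rate[rates$from == "A" & rates$to == "RG"]
  # at saturating glutamate R empties; RG/A balance k_act vs k_deact
  expect_equal(mglur_activation(list(mGluR1 = st)),
               k_act / (k_act + k_de), tolerance = 1e-3)
  # activation is non-decreasing under a uniformly scaled-up transient
  act_of <- function(scale) {
    s <- list(scheme = sc, p = resting_occupancy(sc))
    peak <- 0
    for (i in 1:200) {
      C <- scale * 0.05 * exp(-i / 60)
      s <- step_occupancy(s, C, 0.02)
      peak <- max(peak, mglur_activation(list(mGluR1 = s)))
    }
    peak
  }
  acts <- vapply(c(0.5, 1, 2, 4), act_of, numeric(1))
  expect_true(all(diff(acts) > 0))
})

test_that("scheme construction rejects malformed graphs", {
  expect_error(kinetic_scheme(
    "bad", states = c("A", "B", "Cx"), n_bound = c(0, 1, 0), n_sites = 1,
    transitions = data.frame(from = "A", to = "B", rate = 1, ligand = "glu"),
    resting_state = "A", open_states = "B"), "not connected")
  expect_error(kinetic_scheme(
    "bad", states = c("A", "B"), n_bound = c(0, 1), n_sites = 1,
    transitions = data.frame(from = "A", to = "B", rate = -1, ligand = "glu"),
    resting_state = "A", open_states = "B"), ">= 0")
})
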