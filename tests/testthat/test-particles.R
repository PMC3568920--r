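test_that("release puts the whole ensemble at the cleft-center point source", {
  g <- build_geometry()
  en <- release(g, n = 3000, seed = 1)
  expect_equal(nrow(en$pos), 3000)
  expect_true(all(en$pos[, 1] == 0 & en$pos[, 2] == 0 &
                    en$pos[, 3] == g$cleft_height_nm / 2))
  expect_equal(cleft_count(en), 3000)
  expect_true(all(classify_position(g, en$pos) == "cleft"))
  empty <- release(g, n = 0, seed = 1)
  expect_equal(cleft_count(empty), 0L)
})

test_that("Brownian step has the printed fixed length sqrt(6 D dt)", {
  g <- build_geometry()
  en <- release(g, n = 500, seed = 3)
  # D = 0.25 um^2/ms, dt = 0.1 us -> step length sqrt(150) ~ 12.25 nm
  en2 <- brownian_step(en, dt_ms = 1e-4)
  len <- sqrt(rowSums((en2$pos - en$pos)^2))
  expect_equal(len, rep(sqrt(150), 500), tolerance = 1e-12)
  expect_equal(sqrt(150), 12.2474, tolerance = 1e-4)
  # D = 0: no movement
  en0 <- release(g, n = 50, D_cleft_um2_ms = 0, D_out_um2_ms = 0, seed = 1)
  expect_equal(brownian_step(en0, 1e-4)$pos, en0$pos)
  # determinism: identical seeds give identical walks
  ena <- brownian_step(release(g, 100, seed = 9), 1e-4)
  enb <- brownian_step(release(g, 100, seed = 9), 1e-4)
  expect_identical(ena$pos, enb$pos)
})

test_that("free-space ensemble obeys the Einstein MSD law", {
  # huge open geometry: no boundary is reached during the walk
  g <- build_geometry(list(apposition_width_nm = 4e5, psd_width_nm = 100,
                           escape_radius_nm = 1e6, cleft_height_nm = 3e5))
  for (mode in c("fixed", "gaussian")) {
    en <- release(g, n = 10000, D_cleft_um2_ms = 0.3, D_out_um2_ms = 0.3,
                  seed = 11)
    en$pos[, 3] <- 1.5e5       # far from any wall
    p0 <- en$pos
    nst <- 60; dt <- 1e-3
    for (k in seq_len(nst)) en <- brownian_step(en, dt, mode = mode)
    msd <- mean(rowSums((en$pos - p0)^2))
    expect_equal(msd, 6 * 0.3e6 * nst * dt, tolerance = 0.02)
  }
})

test_that("boundaries reflect specularly and the escape shell absorbs", {
  g <- build_geometry()
  en <- release(g, n = 3, seed = 1)
  # particle just below the postsynaptic membrane -> reflected to +eps
  en$pos[1, ] <- c(10, 10, -0.4)
  # particle beyond the escape shell -> dead
  en$pos[2, ] <- c(1600, 0, 5)
  # particle inside the cleft -> untouched
  en$pos[3, ] <- c(0, 0, 8)
  en <- apply_boundaries(en)
  expect_equal(unname(en$pos[1, 3]), 0.4)
  expect_false(en$alive[2])
  expect_true(en$alive[1] && en$alive[3])
  expect_equal(en$pos[3, ], c(0, 0, 8), ignore_attr = TRUE)
  # deep embedding errors (time step too large)
  bad <- release(g, 1, seed = 1)
  bad$pos[1, ] <- c(0, 0, -200)
  expect_error(apply_boundaries(bad), "too large")
})

test_that("particle number is conserved until absorption and never returns", {
  g <- build_geometry()
  en <- release(g, n = 400, seed = 21)
  dead_seen <- rep(FALSE, 400)
  for (k in 1:300) {
    # steps of ~69 nm out in the glomerular space: allow penetrations up to
    # one step length before calling the configuration unphysical
    en <- apply_boundaries(brownian_step(en, 2e-3), max_embed_nm = 80)
    expect_equal(length(en$alive), 400)
    # once dead, always dead
    expect_true(all(!en$alive[dead_seen]))
    dead_seen <- dead_seen | !en$alive
    lab <- classify_position(g, en$pos[en$alive, , drop = FALSE])
    expect_true(all(lab != "solid"))
  }
  expect_gt(sum(dead_seen), 0)  # some particles have escaped by 0.6 ms
})

test_that("concentration field conserves counts and matches molarity", {
  g <- build_geometry()
  en <- release(g, n = 1, seed = 1)
  # one molecule in the annulus 40-60 nm: C = 1/(NA * V)
  en$pos[1, ] <- c(50, 0, 8)
  cf <- concentration_field(en, bin_width_nm = 20)
  vol_L <- pi * (60^2 - 40^2) * 16 * 1e-24          # nm^3 -> L
  oracle_mM <- 1 / (6.02214076e23 * vol_L) * 1000
  expect_equal(cf$conc_mM[3], oracle_mM, tolerance = 1e-9)
  expect_equal(sum(cf$count), 1)

  # uniform in-cleft cloud: flat profile within counting noise, full count
  set.seed(5)
  n <- 60000
  r <- sqrt(runif(n)) * g$outer_radius_nm
  th <- runif(n, 0, 2 * pi)
  enu <- release(g, n, seed = 2)
  enu$pos <- cbind(r * cos(th), r * sin(th), runif(n, 0, 16))
  cfu <- concentration_field(enu, bin_width_nm = 20)
  expect_equal(sum(cfu$count), cleft_count(enu))
  inner <- cfu$conc_mM[1:15]
  expect_lt(stats::sd(inner) / mean(inner), 0.1)
  expect_error(concentration_field(enu, bin_width_nm = 0), "zero-volume")
})

test_that("R particle operations and the C++ engine are bit-identical", {
  # the engine path (receptors absent, field off) must reproduce the
  # R-level release -> brownian_step -> apply_boundaries loop exactly:
  # both sides draw from the same counter-based streams
  cfg <- mini_config(
    run = list(dt_ms = 2e-4, duration_ms = 0.2, seed = 13),
    particles = list(n_released = 300),
    receptors = list(n_ampar = 0, n_nmdar = 0, n_mglur = 0),
    field = list(enabled = FALSE),
    ions = list(enabled = FALSE))
  ts <- run_simulation(cfg)

  g <- build_geometry()
  en <- release(g, n = 300, seed = 13)
  counts <- integer(0)
  for (k in 1:1000) {
    en <- apply_boundaries(brownian_step(en, 2e-4))
    counts <- c(counts, cleft_count(en))
  }
  expect_identical(ts$traces$cleft_count[-1], as.numeric(counts))
})
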