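test_that("a run with no release and no AP is a fixed point", {
  ts <- run_simulation(mini_config(particles = list(n_released = 0)))
  tr <- ts$traces
  expect_equal(nrow(tr), 1001)           # duration/dt + 1
  expect_true(all(tr$cleft_count == 0))
  expect_true(all(tr$i_ampar_pA == 0 & tr$i_nmdar_pA == 0))
  expect_true(all(tr$p_open_ampar == 0 & tr$mglur_active == 0))
  expect_true(all(tr$vm_mV == -70))
  expect_true(all(tr$na_dev_pct == 0 & tr$k_dev_pct == 0 & tr$cl_dev_pct == 0))
})

test_that("identical seed and config give bit-identical TraceSets", {
  a <- run_simulation(mini_config())
  b <- run_simulation(mini_config())
  expect_identical(a$traces, b$traces)
  expect_identical(a$c_bins, b$c_bins)
  c2 <- mini_config(); c2$run$seed <- 2
  d <- run_simulation(c2)
  expect_false(isTRUE(all.equal(a$traces$cleft_count, d$traces$cleft_count)))
})

test_that("stepping the duty cycle piecewise equals one continuous run", {
  full <- run_simulation(mini_config())
  st <- init_sim_state(mini_config())
  r1 <- step_duty_cycle(st, 400)
  r2 <- step_duty_cycle(r1$state, 600)
  stepped <- rbind(r1$traces, r2$traces)
  expect_equal(unname(as.matrix(full$traces[-1, ])), unname(stepped),
               tolerance = 1e-12)
  expect_error(step_duty_cycle(r2$state, 1), "over")
})

test_that("with field feedback off, receptor kinetics are Vm-invariant", {
  # isolates electrodiffusion as the only voltage dependence of the kinetics
  base <- mini_config(field = list(enabled = FALSE))
  neg <- base; neg$membrane <- list(v_hold_mV = -70)
  pos <- base; pos$membrane <- list(v_hold_mV = 40)
  a <- run_simulation(neg); b <- run_simulation(pos)
  expect_identical(a$traces$p_open_ampar, b$traces$p_open_ampar)
  expect_identical(a$traces$cleft_count, b$traces$cleft_count)
  # currents still scale with the driving force
  expect_equal(b$traces$i_ampar_pA, a$traces$i_ampar_pA * (40 / -70),
               tolerance = 1e-9)
})

test_that("engine receptor propagation replays exactly in R", {
  # feed the engine's own per-step concentration profile through the R-level
  # master-equation stepper: the group states must match to numerical noise
  cfg <- mini_config(run = list(dt_ms = 1e-3, duration_ms = 0.25, seed = 4,
                                c_snapshot_every = 1))
  ts <- run_simulation(cfg)
  st <- init_sim_state(cfg)
  dt <- cfg$run$dt_ms
  n_steps <- nrow(ts$c_bins)
  for (g in st$groups) {
    sc_states <- g$n_states
    p <- g$p
    Qbuild <- function(C) {
      Q <- matrix(0, sc_states, sc_states)
      r <- g$tr_rate * ifelse(g$tr_lig == 1, C, ifelse(g$tr_lig == 2, g$ant_mM, 1))
      for (k in seq_along(r))
        Q[g$tr_from[k] + 1, g$tr_to[k] + 1] <-
          Q[g$tr_from[k] + 1, g$tr_to[k] + 1] + r[k]
      diag(Q) <- diag(Q) - rowSums(Q)
      Q
    }
    for (s in seq_len(n_steps))
      p <- cleftsim:::.uniformization_step(Qbuild(ts$c_bins[s, g$bin + 1]), p, dt)
    final <- ts$final_state$groups[[which(vapply(st$groups, function(x)
      x$type == g$type && x$bin == g$bin, logical(1)))]]$p
    expect_equal(p, final, tolerance = 1e-9)
  }
})

test_that("time grid and release timing follow the configuration", {
  cfg <- mini_config(run = list(dt_ms = 1e-3, duration_ms = 1, seed = 1),
                     particles = list(n_released = 200,
                                      release_time_ms = 0.4))
  tr <- run_simulation(cfg)$traces
  expect_equal(tr$t_ms, seq(0, 1, by = 1e-3))
  # release at step 400: rows 1..401 (t = 0 .. 0.400) are pre-release
  expect_true(all(tr$cleft_count[1:401] == 0))
  expect_equal(tr$cleft_count[402], 200)
})

test_that("configuration validation rejects broken inputs before compute", {
  expect_error(run_simulation(list(run = list(dt_ms = 0))), "dt_ms")
  expect_error(run_simulation(list(run = list(seed = 1, typo_key = 2))),
               "unknown config key")
  expect_error(resolve_config(list(receptors = list(nbqx_block = 2))),
               "nbqx")
  expect_error(resolve_config(list(geometry = list(psd_width_nm = 900))),
               "PSD")
})

test_that("unknown protocol names are rejected, known ones dispatch", {
  expect_error(run_protocol("warp_drive"), "unknown protocol")
  pr <- run_protocol("convergence", mini_config(), dt_ms = 1e-3, factor = 2,
                     window_ms = 0.3, seeds = 1)
  expect_true(is.finite(pr$change_pct))
})
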