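test_that("shunt parameter obeys its limits and unit-tracked value", {
  expect_equal(shunt_parameter(0), 0)
  # quadrupling the open conductance doubles L (square-root scaling)
  L1 <- shunt_parameter(1e-9); L4 <- shunt_parameter(4e-9)
  expect_equal(L4, 2 * L1, tolerance = 1e-12)
  # independent dimensional-analysis oracle in SI units:
  # L = sqrt(1.25e-9 S * 2.5 Ohm m / (pi * 16e-9 m)) = 0.2493385...
  oracle <- sqrt(1.25e-9 * 2.5 / (pi * 16e-9))
  expect_equal(shunt_parameter(1.25e-9, 250, 16), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.24934, tolerance = 1e-5)
  expect_error(shunt_parameter(-1e-9), "negative")
})

test_that("voltage profile limits, boundary value and series oracle", {
  ra <- 80; R <- 300
  expect_equal(voltage_profile(c(0, 40, 299), 0, -70, ra, R), rep(-70, 3))
  expect_equal(voltage_profile(R, 1.3, -70, ra, R), -70, tolerance = 1e-12)
  # L = 1, R/ra = e: V(0)/Vo = 1/(I0(1)+I1(1)) ~ 0.546, by power series
  v0 <- voltage_profile(0, 1, -70, 100, 100 * exp(1))
  expect_equal(v0 / -70, 1 / (bessel_i_series(0, 1) + bessel_i_series(1, 1)),
               tolerance = 1e-9)
  expect_equal(v0 / -70, 0.546, tolerance = 1e-3)
  # arbitrary interior points against the series oracle, both branches
  for (L in c(0.05, 0.4, 2)) {
    for (r in c(10, 60, 79, 81, 150, 280)) {
      expect_equal(voltage_profile(r, L, 40, ra, R),
                   profile_series(r, L, 40, ra, R), tolerance = 1e-9)
    }
  }
  expect_error(voltage_profile(301, 1, -70, ra, R), "R_out")
})

test_that("profile is continuous at ra and monotone in |V|", {
  ra <- 80; R <- 300
  for (L in c(0.01, 0.1, 0.5, 1, 2, 5)) {
    vin <- voltage_profile(ra - 1e-9, L, -70, ra, R)
    vout <- voltage_profile(ra + 1e-9, L, -70, ra, R)
    expect_equal(vin, vout, tolerance = 1e-9)
    r <- seq(0, R, length.out = 400)
    v <- voltage_profile(r, L, -70, ra, R)
    expect_true(all(diff(abs(v)) >= -1e-12))
    expect_true(all(abs(v) <= 70 + 1e-12))
    expect_true(all(abs(v) >= abs(v[1]) - 1e-12))
  }
})

test_that("radial field matches a finite-difference oracle", {
  ra <- 80; R <- 300
  expect_equal(radial_field(c(0, 50, 200), 0, -70, ra, R), rep(0, 3))
  expect_equal(radial_field(0, 1.2, -70, ra, R), 0)  # I1(0) = 0
  h <- 1e-4
  for (L in c(0.05, 0.7, 3)) {
    for (r in c(20, 70, 120, 290)) {
      fd <- (voltage_profile(r + h, L, -70, ra, R) -
               voltage_profile(r - h, L, -70, ra, R)) / (2 * h)
      expect_equal(radial_field(r, L, -70, ra, R), fd, tolerance = 1e-6)
    }
  }
})

test_that("mobility follows the Nernst-Einstein relation in tracked units", {
  expect_equal(mobility(0.25, q = 0), 0)
  expect_equal(mobility(0.5, -1, 307), 2 * mobility(0.25, -1, 307))
  # SI oracle: mu = D q F/(R T); with D = 0.25 um^2/ms = 2.5e5 nm^2/ms,
  # F/(RT) = 96485.33212/(8.314462618*307) V^-1
  mu_oracle <- 2.5e5 * (-1) * (96485.33212 / (8.314462618 * 307)) / 1000
  expect_equal(mobility(0.25, -1, 307), mu_oracle, tolerance = 1e-12)
  expect_lt(mu_oracle, 0)       # sign follows the charge
  expect_gt(mobility(0.25, +1, 307), 0)
  expect_error(mobility(0.25, -1, 0), "temperature")
})

test_that("drift displacement is radial, linear in Vo, and sign-correct", {
  ra <- 80; R <- 300; L <- 0.5; mu <- mobility(0.25, -1, 307)
  expect_equal(drift_displacement(cbind(30, 40), 0, mu, 1e-4),
               cbind(0, 0), ignore_attr = TRUE)
  # magnitude |mu E| dt at r = ra/2
  xy <- cbind(ra / 2, 0)
  E <- radial_field(ra / 2, L, -70, ra, R)
  d <- drift_displacement(xy, E, mu, 1e-4)
  expect_equal(abs(d[1]), abs(mu * E * 1e-4), tolerance = 1e-12)
  expect_equal(d[2], 0)
  # flipping the sign of Vo flips the drift exactly
  d_neg <- drift_displacement(xy, radial_field(ra / 2, L, -70, ra, R), mu, 1e-4)
  d_pos <- drift_displacement(xy, radial_field(ra / 2, L, +70, ra, R), mu, 1e-4)
  expect_equal(d_neg, -d_pos)
  # glutamate (q < 0) at positive Vo drifts inward: retention upon
  # depolarization, the sign structure behind the EPSC decay asymmetry
  expect_lt(d_pos[1], 0)
  expect_gt(d_neg[1], 0)
})
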