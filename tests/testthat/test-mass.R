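zero_drive <- function(n, dt = 0.1) {
  drive_series(numeric(n), numeric(n), numeric(n), dt)
}

const_drive <- function(n, phi_e = 0, phi_i = 0, phi_x = 0, dt = 0.1) {
  drive_series(rep(phi_e, n), rep(phi_i, n), rep(phi_x, n), dt)
}

test_that("zero drive relaxes along the closed-form bi-exponential", {
  d <- zero_drive(3000)
  cfg <- mass_config("CFM", v_bar = -60, v0 = -60)
  t <- (1:3000) * 0.1
  ref <- oracle_biexp(t, -60, -80, 20, 5)
  for (m in c("euler", "exact")) {
    v <- integrate_cfm(d, cfg, method = m)$values
    expect_lt(max(abs(v - ref)), 0.05)
    # monotone decay toward the leak, no undershoot
    expect_true(all(diff(v) <= 1e-12))
    expect_gt(min(v), -80 - 1e-9)
  }
})

test_that("CFM steady state matches the algebraic fixed point", {
  phi0 <- 1.5
  cfg <- mass_config("CFM", v_bar = -60, v0 = -60)
  vstar <- -80 - cfg$g_ratio_exc * (-60 - 0) * phi0
  d <- const_drive(2500, phi_e = phi0)      # 250 ms = 10 (tau_m + tau_s)
  for (m in c("euler", "exact")) {
    v <- integrate_cfm(d, cfg, method = m)$values
    expect_lt(abs(v[2500] - vstar), 0.01 * abs(vstar - (-60)))
  }
})

test_that("MFM fixed point solves the parametric balance", {
  phi0 <- 0.08    # modest drive: frozen system overdamped, envelope applies
  cfg <- mass_config("MFM", v0 = -70)
  a <- (cfg$g_ratio_exc + cfg$g_ratio_inh + cfg$g_ratio_ext) * phi0
  b <- (cfg$g_ratio_exc * 0 + cfg$g_ratio_inh * -70 + cfg$g_ratio_ext * 0) *
    phi0
  vstar <- (-80 + b) / (1 + a)
  d <- const_drive(4000, phi_e = phi0, phi_i = phi0, phi_x = phi0)
  for (m in c("euler", "exact")) {
    v <- integrate_mfm(d, cfg, method = m)$values
    expect_lt(abs(v[4000] - vstar), 0.02)
  }
})

test_that("impulse response matches the bi-exponential convolution kernel", {
  # one unit-area pulse through the exc channel at fine dt; the linear
  # response is (amp) * (e^{-t/tau_m} - e^{-t/tau_s}) / (tau_m - tau_s)
  dt <- 0.01
  n <- 20000
  phi <- numeric(n)
  phi[1] <- 1 / dt                       # unit-area impulse
  d <- drive_series(phi, numeric(n), numeric(n), dt)
  cfg <- mass_config("CFM", v_bar = -60, v0 = -80, dt = dt)
  v <- integrate_cfm(d, cfg, method = "euler")$values
  amp <- -cfg$g_ratio_exc * (-60 - 0)    # forcing integral of J - v_leak
  t <- (1:n) * dt
  kernel <- -80 + amp * (exp(-t / 20) - exp(-t / 5)) / (20 - 5)
  expect_lt(max(abs(v - kernel)), 0.01 * max(abs(kernel + 80)))
  # peak near the analytic argmax t* = ln(tau_m/tau_s) tau_m tau_s/(tau_m-tau_s)
  tstar <- log(20 / 5) * 20 * 5 / 15
  expect_lt(abs(t[which.max(v)] - tstar), 0.2)
})

test_that("MFM with frozen forcing reproduces the CFM bit-exactly", {
  set.seed(1)
  n <- 5000
  d <- drive_series(abs(rnorm(n, 0.5, 0.2)), abs(rnorm(n, 0.3, 0.1)),
                    abs(rnorm(n, 0.4, 0.1)), 0.1)
  for (m in c("euler", "exact")) {
    cfgc <- mass_config("CFM", v_bar = -62.5, v0 = -61)
    cfgm <- mass_config("MFM", v_bar = -62.5, v0 = -61)
    cfm <- integrate_cfm(d, cfgc, method = m)
    frozen <- integrate_mfm(d, cfgm, freeze_at = -62.5, method = m)
    expect_identical(cfm$values, frozen$values)
  }
  # at zero drive CFM and true MFM coincide as trajectories
  d0 <- zero_drive(2000)
  v1 <- integrate_cfm(d0, mass_config("CFM", v_bar = -55, v0 = -60))$values
  v2 <- integrate_mfm(d0, mass_config("MFM", v0 = -60))$values
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("CFM is linear in the drive", {
  set.seed(2)
  n <- 3000
  cfg <- mass_config("CFM", v_bar = -60, v0 = -60)
  mk <- function(phi) drive_series(phi, numeric(n), numeric(n), 0.1)
  p1 <- abs(rnorm(n)); p2 <- abs(rnorm(n))
  va <- integrate_cfm(mk(p1), cfg)$values
  vb <- integrate_cfm(mk(p2), cfg)$values
  vh <- integrate_cfm(mk(numeric(n)), cfg)$values   # homogeneous part
  vab <- integrate_cfm(mk(2 * p1 + 3 * p2), cfg)$values
  expect_equal(vab, 2 * va + 3 * vb - 4 * vh, tolerance = 1e-9)
})

test_that("MFM trajectories stay in the reversal-potential envelope for
           overdamped nonnegative drive", {
  set.seed(3)
  n <- 20000
  # a(t) <= 0.55 keeps the frozen cascade overdamped (bound (am+as)^2 >=
  # 4 (1+a) am as at tau = 20, 5 gives a <= 0.5625)
  cfg <- mass_config("MFM", v0 = -60)
  rtot <- cfg$g_ratio_exc + cfg$g_ratio_inh + cfg$g_ratio_ext
  phi <- abs(rnorm(n, 0.05, 0.03))
  phi <- pmin(phi, 0.55 / rtot)
  d <- drive_series(phi, phi, phi, 0.1)
  for (m in c("euler", "exact")) {
    v <- integrate_mfm(d, cfg, method = m)$values
    expect_true(all(v <= 0 + 1e-6))          # v_rev_exc envelope
    expect_true(all(v >= -80 - 1e-6))        # min(v_leak, v_rev_inh)
  }
})

test_that("halving dt changes Euler trajectories by O(dt)", {
  mk <- function(dt) {
    n <- round(200 / dt)
    t <- (1:n) * dt
    phi <- 0.5 + 0.4 * sin(2 * pi * 17 * t / 1000)
    d <- drive_series(phi, numeric(n), numeric(n), dt)
    cfg <- mass_config("CFM", v_bar = -60, v0 = -60, dt = dt)
    integrate_cfm(d, cfg, method = "euler")$values
  }
  v1 <- mk(0.2)
  v2 <- mk(0.1)[seq(2, 2000, by = 2)]
  v4 <- mk(0.05)[seq(4, 4000, by = 4)]
  e12 <- max(abs(v1 - v2))
  e24 <- max(abs(v2 - v4))
  expect_gt(e12, 0)
  expect_lt(e24 / e12, 0.7)   # ~0.5 for a first-order scheme
})

test_that("analytic response is a DC-pass second-order low-pass", {
  cfg <- mass_config("CFM", v_bar = -60)
  expect_equal(Mod(analytic_response(0, cfg)), 1)
  # corner frequencies: single-pole residual factors
  f_m <- 1000 / (2 * pi * 20)
  g <- Mod(analytic_response(f_m, cfg))
  expect_equal(g, (1 / sqrt(2)) * 1 / Mod(1 + 1i * 5 / 20), tolerance = 1e-12)
  # asymptotic 1/f^2 roll-off
  f <- c(2000, 4000)
  gains <- Mod(analytic_response(f, cfg))
  expect_equal(gains[1] / gains[2], 4, tolerance = 0.01)
  expect_error(analytic_response(-1, cfg))
})

test_that("malformed drives and configs are rejected", {
  d <- zero_drive(10)
  expect_error(mass_config("CFM"), "v_bar")
  cfg <- mass_config("MFM")
  expect_error(integrate_cfm(d, cfg), "variant")
  bad <- drive_series(rep(1, 10), rep(1, 10), rep(1, 10), 0.1)
  bad$phi_exc[3] <- NaN
  expect_error(integrate_mfm(bad, cfg), "non-finite")
  d2 <- zero_drive(10, dt = 0.2)
  expect_error(integrate_mfm(d2, cfg), "bin width")
})
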