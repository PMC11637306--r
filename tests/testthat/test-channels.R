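# independent transcription of the squid rate equations for cross-checking
ref_rates <- function(v, gate) {
  vtrap <- function(num, vv, th, q) {
    x <- (vv - th) / q
    if (abs(x) < 1e-7) num * q * (1 + x / 2) else num * q * x / (1 - exp(-x))
  }
  switch(gate,
         m = list(alpha = vtrap(0.1, v, -40, 10),
                  beta = 4 * exp(-(v + 65) / 18)),
         h = list(alpha = 0.07 * exp(-(v + 65) / 20),
                  beta = 1 / (1 + exp(-(v + 35) / 10))),
         n = list(alpha = vtrap(0.01, v, -55, 10),
                  beta = 0.125 * exp(-(v + 65) / 80)))
}

test_that("HH rates match an independent transcription and behave at the
           removable singularity", {
  for (g in c("m", "h", "n")) {
    got <- hh_rates(-65, g)
    want <- ref_rates(-65, g)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
    expect_equal(got$beta, want$beta, tolerance = 1e-12)
  }
  # alpha_m at v = -40 (0/0 form): analytic limit 0.1 * 10 / 10 = 1
  expect_equal(hh_rates(-40, "m")$alpha, 1, tolerance = 1e-6)
  # continuity just around the singularity
  eps <- 1e-7
  expect_equal(hh_rates(-40 + eps, "m")$alpha,
               hh_rates(-40 - eps, "m")$alpha, tolerance = 1e-5)
  # steady state in (0, 1) across the physiological range
  for (v in seq(-100, 60, by = 5)) {
    r <- hh_rates(v, "m")
    minf <- r$alpha / (r$alpha + r$beta)
    expect_gt(minf, 0); expect_lt(minf, 1)
  }
  # voltage shift moves the curves, rate scale multiplies them
  expect_equal(hh_rates(-60, "n", vshift = 5)$alpha,
               hh_rates(-65, "n")$alpha)
  expect_equal(hh_rates(-65, "n", rate_scale = 3)$alpha,
               3 * hh_rates(-65, "n")$alpha)
})

test_that("GHK current obeys its limits and is smooth through 0 mV", {
  # equal concentrations at 0 mV: zero current
  expect_equal(ghk_current(0, p = 1e-4, c_in = 1, c_out = 1), 0)
  # v = 0 limit: i = z F P (c_in - c_out), converted to mA/cm^2 with mM
  p <- 2e-4; ci <- 1e-4; co <- 2
  want <- 96485 * 2 * p * (ci - co) * 1e-6 * 1e3   # A/cm2 * 1e3 = mA/cm2
  expect_equal(ghk_current(0, p, c_in = ci, c_out = co), want,
               tolerance = 1e-9)
  # series-expansion oracle: evaluate the full expression at v +- 1e-6 mV
  # and compare the midpoint to the direct value at +10 mV
  full <- function(v) {
    xi <- 2 * 96485.332 * v * 1e-3 / (8.314462 * (273.15 + 35))
    96.485 * 2 * xi * (ci - co * exp(-xi)) / (1 - exp(-xi)) * p
  }
  direct <- ghk_current(10, p, c_in = ci, c_out = co)
  expect_equal(direct, (full(10 + 1e-6) + full(10 - 1e-6)) / 2,
               tolerance = 1e-9)
  # inward whenever c_out * exp(-zvF/RT) > c_in
  expect_lt(direct, 0)
  # continuity and differentiability across v = 0 (1e-6 relative)
  vs <- c(-1e-3, -1e-5, 1e-5, 1e-3)
  ys <- ghk_current(vs, p, c_in = ci, c_out = co)
  slope1 <- (ys[2] - ys[1]) / (vs[2] - vs[1])
  slope2 <- (ys[4] - ys[3]) / (vs[4] - vs[3])
  expect_equal(slope1, slope2, tolerance = 1e-4)
  expect_equal(ghk_current(1e-9, p, c_in = ci, c_out = co),
               ghk_current(-1e-9, p, c_in = ci, c_out = co),
               tolerance = 1e-6)
})

test_that("Q10 scaling multiplies rates as q10^(dT/10)", {
  expect_equal(q10_scale(3, 24, 24, 2.5), 3)
  expect_equal(q10_scale(3, 34, 24, 2.5), 3 * 2.5)
  expect_equal(q10_scale(3, 14, 24, 2.5), 3 / 2.5)
  expect_equal(q10_scale(1, 35, 24, 2.5), 2.5^1.1)
})

test_that("membrane current decomposition matches hand evaluation", {
  # all gates closed: only leak remains
  mc0 <- membrane_current(-60, list(m = 0, h = 0, n = 0))
  expect_equal(mc0$i_na, 0)
  expect_equal(mc0$i_k, 0)
  expect_equal(mc0$i_leak, (1 / 50) * (-60 + 80) * 1e-3)
  expect_equal(mc0$i_total, mc0$i_leak + mc0$i_ca)
  # at the K reversal the K current vanishes even with n = 1
  mck <- membrane_current(-90, list(m = 0, h = 0, n = 1))
  expect_equal(mck$i_k, 0)
  # spot check at v = -20 with the stated defaults
  gt <- list(m = 0.6, h = 0.3, n = 0.4, ca = c(0.2, 0.2, 0.2))
  mc <- membrane_current(-20, gt)
  expect_equal(mc$i_na, 290 * 0.6^3 * 0.3 * (-20 - 70) * 1e-3,
               tolerance = 1e-12)
  expect_equal(mc$i_k, 17 * 0.4^4 * (-20 + 90) * 1e-3, tolerance = 1e-12)
  i_ca_want <- sum(ghk_current(-20, 2e-4 * c(6.5, 2.5, 1) / 10 * 0.2^2))
  expect_equal(mc$i_ca, i_ca_want, tolerance = 1e-12)
})

test_that("gates relax monotonically to steady state at fixed voltage", {
  # discrete Rush-Larsen updates at constant voltage approach m_inf
  r <- hh_rates(-20, "m")
  minf <- r$alpha / (r$alpha + r$beta)
  x <- 0.01
  xs <- numeric(400)
  for (k in 1:400) {
    x <- minf + (x - minf) * exp(-0.01 * (r$alpha + r$beta))
    xs[k] <- x
  }
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs < minf))
  expect_equal(xs[400], minf, tolerance = 0.01)
})
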