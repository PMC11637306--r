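test_that("cell-attached subtraction removes the instrumental component", {
  t <- seq(-2, 20, by = 0.004)
  membrane <- two_compartment_transient(t)
  artifact <- membrane
  artifact$current <- ifelse(t < 0, 0, -0.05 * exp(-pmax(t, 0) / 0.05))
  whole <- membrane
  whole$current <- membrane$current + artifact$current
  clean <- subtract_cell_attached(whole, artifact)
  expect_equal(clean$current, membrane$current, tolerance = 1e-12)
  # identical traces cancel to zero
  zero <- subtract_cell_attached(whole, whole)
  expect_true(all(zero$current == 0))
  # mismatched grids are refused
  shifted <- artifact
  shifted$time <- shifted$time + 0.002
  expect_error(subtract_cell_attached(whole, shifted), "time grid")
})

test_that("noise-free exponentials are recovered to high precision", {
  t <- seq(0, 30, by = 0.004)
  y1 <- -0.4 * exp(-t / 1) + 0.02
  tr1 <- tibble::tibble(time = t, current = y1)
  attr(tr1, "step_onset") <- 0
  f1 <- fit_exponentials(tr1, 1, window = c(0.2, 5))
  expect_equal(f1$taus[1], 1, tolerance = 1e-6)
  expect_equal(f1$amps[1], -0.4, tolerance = 1e-6)

  y2 <- -0.3 * exp(-t / 0.3) - 0.05 * exp(-t / 3) + 0.01
  tr2 <- tibble::tibble(time = t, current = y2)
  attr(tr2, "step_onset") <- 0
  f2 <- fit_exponentials(tr2, 2, window = c(0.2, 8))
  expect_equal(f2$taus, c(0.3, 3), tolerance = 1e-4)
  expect_equal(f2$amps, c(-0.3, -0.05), tolerance = 1e-3)

  # nested-model guarantee on an arbitrary noisy input
  set.seed(2)
  tr2$current <- tr2$current + rnorm(length(t), 0, 0.005)
  fits <- lapply(1:3, function(n) fit_exponentials(tr2, n,
                                                   window = c(0.2, 8)))
  expect_lte(fits[[2]]$sse, fits[[1]]$sse + 1e-12)
  expect_lte(fits[[3]]$sse, fits[[2]]$sse + 1e-12)
})

test_that("model selection follows the bi-default rule", {
  mkfit <- function(n, sse) structure(list(n_exp = n, sse = sse),
                                      class = "exp_fit")
  # the reported SSE pattern for mono/bi/tri transient fits selects bi
  expect_equal(select_model(list(mkfit(1, 7.81), mkfit(2, 2.37),
                                 mkfit(3, 2.16))), 2L)
  # mono within 10% of bi: mono wins
  expect_equal(select_model(list(mkfit(1, 2.4), mkfit(2, 2.3),
                                 mkfit(3, 2.2))), 1L)
  # tri improving bi by >10%: tri wins
  expect_equal(select_model(list(mkfit(1, 9), mkfit(2, 3),
                                 mkfit(3, 2))), 3L)
})

test_that("model selection identifies the generating circuit order", {
  t <- seq(-5, 60, by = 0.004)
  tr <- two_compartment_transient(t)
  set.seed(4)
  tr$current <- tr$current + rnorm(length(t), 0, 0.02 * max(abs(tr$current)))
  attr(tr, "step_onset") <- 0
  fits <- lapply(1:3, function(n) fit_exponentials(tr, n))
  expect_equal(select_model(fits), 2L)
  # single-RC data select the mono model
  rc <- tibble::tibble(time = t,
                       current = ifelse(t < 0, 0,
                                        -0.1 * exp(-pmax(t, 0) / 1.5) - 0.01))
  set.seed(5)
  rc$current <- rc$current + rnorm(length(t), 0, 0.002)
  attr(rc, "step_onset") <- 0
  fits_rc <- lapply(1:3, function(n) fit_exponentials(rc, n))
  expect_equal(select_model(fits_rc), 1L)
})

test_that("structure capacitance recovers the circuit value", {
  t <- seq(-5, 60, by = 0.004)
  for (c_local in c(2, 5)) {
    tr <- two_compartment_transient(t, c_local_pf = c_local)
    attr(tr, "step_onset") <- 0
    f <- fit_exponentials(tr, 2)
    expect_equal(structure_capacitance(f), c_local,
                 tolerance = 0.05 * c_local)
    # doubling the step amplitude leaves the estimate unchanged
    tr2 <- two_compartment_transient(t, dv = -40, c_local_pf = c_local)
    attr(tr2, "step_onset") <- 0
    f2 <- fit_exponentials(tr2, 2)
    expect_equal(structure_capacitance(f2, dv = -40),
                 structure_capacitance(f, dv = -20),
                 tolerance = 0.01 * c_local)
  }
  f1 <- fit_exponentials({
    tr <- two_compartment_transient(t); attr(tr, "step_onset") <- 0; tr
  }, 1)
  expect_error(structure_capacitance(f1), ">=2")
})

test_that("input resistance and membrane time constant match circuits", {
  # input resistance of the analytic circuit: Rs + R1 || (Rx + R2)
  t <- seq(-5, 100, by = 0.004)
  tr <- two_compartment_transient(t)
  attr(tr, "step_onset") <- 0
  attr(tr, "dv") <- -20
  attr(tr, "step_width") <- 95
  rin <- input_resistance(tr)
  rin_true <- 150 + 1 / (1 / 25000 + 1 / (1500 + 30000))
  expect_lt(abs(rin - rin_true) / rin_true, 0.01)

  # single RC relaxation: tau_m = R C
  tt <- seq(0, 60, by = 0.01)
  v <- -80 + 10 * (1 - exp(-tt / 12))
  cc <- tibble::tibble(time = tt, v = v)
  expect_equal(membrane_time_constant(cc), 12, tolerance = 0.01)

  # two-compartment circuit: the late relaxation is the slow eigenmode
  a <- two_compartment_transient(t)
  taus <- attr(a, "taus_ms")
  # voltage relaxation built from the circuit's own eigen time constants;
  # the late-phase fit must recover the slow one
  t3 <- seq(0, 12, by = 0.01)
  v2 <- 5 * (0.3 * exp(-t3 / taus[1]) + 0.7 * exp(-t3 / taus[2]))
  cc2 <- tibble::tibble(time = t3, v = -80 + 5 - v2)
  expect_equal(membrane_time_constant(cc2, late_frac = 0.5), taus[2],
               tolerance = 0.05 * taus[2])
})

test_that("capacitance recovery is robust across noisy replicates", {
  t <- seq(-5, 60, by = 0.004)
  clean <- two_compartment_transient(t)
  peak <- max(abs(clean$current))
  errs <- vapply(1:30, function(s) {
    nz <- add_recording_noise(clean, noise_sd = 0.02 * peak,
                              headstage_khz = 10, seed = s)
    attr(nz, "step_onset") <- 0
    f <- fit_exponentials(nz, 2)
    abs(suppressWarnings(structure_capacitance(f)) - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  expect_lt(max(errs), 0.30)
})
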