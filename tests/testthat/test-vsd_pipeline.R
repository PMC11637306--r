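# small synthetic stack: n_px pixels, double-exponential bleach, optional
# AP-locked transient at a given fractional amplitude
toy_stack <- function(n_frames = 1200, n_px = 24, frame_khz = 10,
                      bleach = TRUE, signal_frac = 0, seed = 1,
                      noise_sd = 0) {
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) / frame_khz
  f0 <- seq(500, 3000, length.out = n_px)
  ev <- 60                      # one AP at 60 ms
  bl <- if (bleach) {
    1 - 0.05 * (1 - exp(-t / 50)) - 0.15 * (1 - exp(-t / 500))
  } else rep(1, length(t))
  ap <- signal_frac * exp(-pmax(t - ev, 0) / 0.4) * (t >= ev)
  frames <- outer(bl * (1 + ap), f0) +
    matrix(rnorm(n_frames * n_px, 0, noise_sd), n_frames)
  frames <- pmax(frames, 0)
  pixels <- tibble::tibble(px = seq_len(n_px), x = seq_len(n_px), y = 1,
                           path_pos = (seq_len(n_px) - 0.5) * 0.79)
  vsd_stack(frames, pixels, frame_khz = frame_khz, events = ev)
}

test_that("bleach correction flattens decaying baselines and preserves
           transients", {
  # no bleaching: correction is close to the identity
  st0 <- toy_stack(bleach = FALSE)
  c0 <- bleach_correct(st0)
  expect_lt(max(abs(c0$frames - st0$frames) / st0$frames), 0.001)

  # pure double-exponential decay: corrected trace constant within 0.5%
  st <- toy_stack(bleach = TRUE, signal_frac = 0)
  cc <- bleach_correct(st)
  flat <- apply(cc$frames, 2, function(y) diff(range(y)) / mean(y))
  expect_lt(max(flat), 0.005)

  # a 1% AP-locked transient on the bleaching background survives
  st1 <- toy_stack(bleach = TRUE, signal_frac = 0.01)
  c1 <- bleach_correct(st1)
  amp_of <- function(stk) {
    tr <- rowMeans(stk$frames / rep(colMeans(stk$frames[1:50, ]),
                                    each = nrow(stk$frames)))
    max(tr[stk$time >= 59 & stk$time <= 62]) -
      stats::median(tr[stk$time < 55])
  }
  expect_equal(amp_of(c1), 0.01, tolerance = 0.05 * 0.01 + 5e-4)
})

test_that("the activity map reports fractional AP-locked changes", {
  # a +10% plateau covering the whole +-0.2 ms peak window
  st <- toy_stack(bleach = FALSE, signal_frac = 0)
  st$frames <- st$frames * (1 + 0.10 * (abs(st$time - 60) <= 0.25))
  am <- activity_map(st, peak_window_ms = 0.2)
  expect_equal(mean(am$dff), 0.10, tolerance = 0.01)
  # event-free pixels sit at the noise floor
  stq <- toy_stack(bleach = FALSE, signal_frac = 0, noise_sd = 1)
  amq <- activity_map(stq)
  expect_lt(max(abs(amq$dff)), 0.01)
  # graded signal along the mask stays monotone in the map
  stg <- toy_stack(bleach = FALSE, signal_frac = 0)
  grad <- seq(0, 0.05, length.out = ncol(stg$frames))
  ev <- 60
  gain <- 1 + outer(exp(-pmax(stg$time - ev, 0) / 0.4) *
                      (stg$time >= ev), grad)
  stg$frames <- stg$frames * gain
  amg <- activity_map(stg)
  expect_true(all(diff(amg$dff) > -1e-6))
})

test_that("segment averaging partitions the mask and gains SNR", {
  st <- toy_stack(n_px = 16)       # 16 px * 0.79 um = 12.6 um of axon
  segs <- segment_average(st, 5)
  expect_equal(length(unique(segs$segment)), 3)
  expect_true(all(segs$n_px >= 1))
  # uniform signal: all segment traces equal
  stu <- toy_stack(bleach = FALSE)
  stu$frames[] <- rep(rowMeans(stu$frames), ncol(stu$frames))
  su <- segment_average(stu, 5)
  su_wide <- split(su$f, su$segment)
  for (j in 2:length(su_wide)) expect_equal(su_wide[[j]], su_wide[[1]])
  # averaging reduces noise relative to a single pixel
  stn <- toy_stack(bleach = FALSE, noise_sd = 20, seed = 7)
  sn <- segment_average(stn, 50)   # one segment with all pixels
  noise_seg <- stats::sd(sn$f) / mean(sn$f)
  noise_px <- stats::sd(stn$frames[, 1]) / mean(stn$frames[, 1])
  expect_lt(noise_seg, noise_px)
})

test_that("shift-and-mean reduces to the plain waveform without jitter and
           beats naive averaging with jitter", {
  shape <- function(t) exp(-(t - 5)^2 / (2 * 0.04))   # 0.2 ms-SD bump
  frame_t <- seq(0, 10, by = 0.1)                     # 10 kHz
  # zero jitter: identical trials pool onto the refined grid unchanged
  trials0 <- lapply(1:8, function(i) {
    tibble::tibble(time = frame_t, f = shape(frame_t))
  })
  sm0 <- shift_and_mean(trials0, rep(5, 8), resample_factor = 8)
  expect_equal(sm0$f, shape(sm0$time + 5), tolerance = 1e-9)

  # jittered trials: aligned pooling recovers the waveform better than
  # naive frame-wise averaging
  set.seed(11)
  jit <- runif(24, -0.05, 0.05)
  trials <- lapply(jit, function(j) {
    tibble::tibble(time = frame_t, f = shape(frame_t - j))
  })
  sm <- shift_and_mean(trials, 5 + jit, resample_factor = 8)
  rmse_sm <- sqrt(mean((sm$f - shape(sm$time + 5))^2))
  naive <- rowMeans(vapply(trials, function(tr) tr$f,
                           numeric(length(frame_t))))
  rmse_naive <- sqrt(mean((naive - shape(frame_t))^2))
  expect_lt(rmse_sm, rmse_naive)

  # trials without a reference peak are dropped, not fatal
  expect_message(
    sm2 <- shift_and_mean(trials[1:4], c(5 + jit[1:3], NA)),
    "dropping")
  expect_equal(attr(sm2, "n_trials"), 3)
})

test_that("pooled 10 kHz trials block-averaged by 8 land in the expected
           effective-rate band", {
  frame_t <- seq(0, 10, by = 0.1)
  for (n_trials in c(20, 21)) {
    set.seed(n_trials)
    jit <- runif(n_trials, 0, 0.1)
    trials <- lapply(jit, function(j)
      tibble::tibble(time = frame_t + j, f = rnorm(length(frame_t))))
    sm <- shift_and_mean(trials, rep(5, n_trials), resample_factor = 8)
    eff <- attr(sm, "effective_rate_khz")
    expect_gte(eff, 24.5)
    expect_lte(eff, 27.5)
  }
})

test_that("the two-step low-pass is zero-phase, attenuating, and
           near-idempotent", {
  fs <- 250                          # kHz
  t <- seq(0, 20, by = 1 / fs)
  dc <- tibble::tibble(time = t, f = rep(2, length(t)))
  mid <- t > 2 & t < 18           # away from filtfilt edge transients
  expect_equal(lowpass_two_step(dc, c(10, 100))$f[mid], dc$f[mid],
               tolerance = 1e-6)
  # a 40 kHz tone is attenuated by > 20 dB by the 10 kHz step
  tone <- tibble::tibble(time = t, f = sin(2 * pi * 40 * t))
  out <- lowpass_two_step(tone, c(10, 100))
  midt <- t > 5 & t < 15
  expect_lt(stats::sd(out$f[midt]) / stats::sd(tone$f[midt]), 0.1)
  # filtering twice changes the signal by < 1%
  sig <- tibble::tibble(time = t,
                        f = exp(-(t - 10)^2 / 2) + 0.3 * sin(2 * pi * 3 * t))
  once <- lowpass_two_step(sig, c(10, 100))
  twice <- lowpass_two_step(once, c(10, 100))
  midt <- t > 2 & t < 18
  expect_lt(sqrt(mean((twice$f[midt] - once$f[midt])^2)) /
              stats::sd(once$f[midt]), 0.01)
  # cutoffs above Nyquist are skipped with a message
  slow <- tibble::tibble(time = seq(0, 10, by = 0.1), f = rnorm(101))
  expect_message(lowpass_two_step(slow, c(10, 100)), "Nyquist")
})

test_that("the VSD AP area matches its closed form and normalization
           contract", {
  # normalized exponential decay tau = 0.3 ms from the peak:
  # integral over [peak+0.05, peak+0.65] = tau (e^(-0.05/tau) - e^(-0.65/tau))
  dt <- 1 / 250
  t <- seq(0, 5, by = dt)
  tau <- 0.3
  f <- ifelse(t < 1, 0, exp(-(t - 1) / tau))
  w <- tibble::tibble(time = t, f = f)
  want <- tau * (exp(-0.05 / tau) - exp(-0.65 / tau))
  expect_equal(vsd_ap_area(w, 0.05, 0.6), want, tolerance = 1e-3 * want)
  # raw amplitude rescaling leaves the area unchanged
  w2 <- w; w2$f <- 37 * w$f + 100
  expect_equal(vsd_ap_area(w2, 0.05, 0.6), vsd_ap_area(w, 0.05, 0.6),
               tolerance = 1e-9)
  # flat zero after the peak
  w3 <- tibble::tibble(time = t, f = ifelse(abs(t - 1) < 2 * dt, 1, 0))
  expect_equal(vsd_ap_area(w3, 0.05, 0.6), 0, tolerance = 1e-6)
  # window beyond the trace is an error
  expect_error(vsd_ap_area(w[t < 1.2, ], 0.05, 0.6),
               class = "axonwave_window_error")
})
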