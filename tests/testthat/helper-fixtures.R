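# shared in-code fixtures

# straight cylindrical axon: length um, diameter um
cylinder_morph <- function(length_um = 100, diam_um = 1, step_um = 10) {
  x <- seq(0, length_um, by = step_um)
  morphology(data.frame(
    id = seq_along(x), parent_id = c(NA, head(seq_along(x), -1)),
    x = x, y = 0, z = 0, radius = diam_um / 2, label = "axon"))
}

cylinder_grid <- function(length_um = 100, diam_um = 1, max_seg = 1,
                          ra = 150) {
  discretize(cylinder_morph(length_um, diam_um), max_seg, ra = ra)
}

# single iso-potential compartment with a given membrane area (um^2)
sphere_grid <- function(area_um2 = 1000) {
  axonwave:::single_compartment_grid(area_um2)
}

# uniform-grid triangle waveform: rise to peak and back, in mV
triangle_wave <- function(base_mv = -80, peak_mv = 20, rise_ms = 1,
                          decay_ms = 1, dt = 0.001, pad_ms = 0.5) {
  t <- seq(0, pad_ms + rise_ms + decay_ms + pad_ms, by = dt)
  v <- rep(base_mv, length(t))
  up <- t > pad_ms & t <= pad_ms + rise_ms
  v[up] <- base_mv + (peak_mv - base_mv) * (t[up] - pad_ms) / rise_ms
  dn <- t > pad_ms + rise_ms & t <= pad_ms + rise_ms + decay_ms
  v[dn] <- peak_mv - (peak_mv - base_mv) *
    (t[dn] - pad_ms - rise_ms) / decay_ms
  as_ap_waveform(data.frame(time = t, v = v), source = "sim")
}

# composite Simpson's rule for an independent quadrature oracle
simpson <- function(x, y) {
  n <- length(x)
  if (n %% 2 == 0) { n <- n - 1 }  # need odd number of points
  h <- x[2] - x[1]
  idx <- seq_len(n)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  sum(w * y[idx]) * h / 3
}

# default active AP simulation on a uniform cylinder, recorded mid-axon
default_ap_sim <- function(dt = 0.004, length_um = 100, diam_um = 1,
                           max_seg = 1, record_i = NULL) {
  g <- cylinder_grid(length_um, diam_um, max_seg)
  cfg <- sim_config(duration = 8, settle_ms = 10, dt = dt,
                    record_i = record_i,
                    record_species = if (is.null(record_i)) character(0)
                    else "ca",
                    stimuli = list(stim_current_step(2, 0.3, 0.3, 0.5)))
  simulate_cable(g, passive_params(), active_densities(),
                 if (is.null(record_i)) NULL else ca_mixture(), cfg)
}

# waveform at path position p, time-aligned at the sub-sample -20 mV
# upstroke crossing (half-sample peak jitter would otherwise dominate
# comparisons on steep upstrokes), resampled onto grid_t
aligned_wave <- function(sim, p, grid_t = seq(-0.4, 1.5, by = 0.004)) {
  w <- sim_waveform(sim, p)
  ip <- which.max(w$v)
  pre <- which(w$v[1:ip] < -20)
  i <- pre[length(pre)]
  f <- (-20 - w$v[i]) / (w$v[i + 1] - w$v[i])
  t0 <- w$time[i] + f * (w$time[i + 1] - w$time[i])
  approx(w$time - t0, w$v, grid_t)$y
}
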