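test_that("a single passive compartment charges like its RC circuit", {
  g <- sphere_grid(1000)                  # 10 pF at 1 uF/cm^2
  # R = rm / area = 50 kOhm cm^2 / 1000 um^2 = 5 GOhm; tau = 50 ms
  cfg <- sim_config(duration = 300, settle_ms = 1, dt = 0.05,
                    record_species = "leak",
                    stimuli = list(stim_current_step(0, 0.002, 1, 300)))
  sim <- simulate_cable(g, passive_params(),
                        active_densities(g_na = 0, g_k = 0), NULL, cfg)
  v <- sim$v[, 1]
  t <- sim$time
  r_mohm <- 50 * 1e3 / (1000 * 1e-8) / 1e6      # 5e3 MOhm
  expect_equal(v[length(v)] + 80, 0.002 * r_mohm, tolerance = 0.01)
  # voltage at onset + tau is 63.2% of the plateau
  i_tau <- which.min(abs(t - (1 + 50)))
  expect_equal((v[i_tau] + 80) / (0.002 * r_mohm), 1 - exp(-1),
               tolerance = 0.01)
})

test_that("passive input resistance matches the finite-cable closed form", {
  g <- cylinder_grid(100, 1, 1)
  cfg <- sim_config(duration = 320, settle_ms = 2, dt = 0.02,
                    record_species = "leak",
                    stimuli = list(stim_current_step(50, 0.005, 5, 320)))
  sim <- simulate_cable(g, passive_params(),
                        active_densities(g_na = 0, g_k = 0), NULL, cfg)
  vss <- sim$v[nrow(sim$v), which.min(abs(g$path_pos - 50))]
  rin_sim <- (vss + 80) / 0.005
  # two sealed half-cables of 50 um in parallel: R_inf coth(l/lambda) / 2
  d_cm <- 1e-4
  lambda <- sqrt(50e3 * d_cm / (4 * 150))
  r_inf <- 2 / (pi * d_cm^1.5) * sqrt(50e3 * 150)
  rin_theory <- r_inf / tanh(50e-4 / lambda) / 2 / 1e6
  expect_lt(abs(rin_sim - rin_theory) / rin_theory, 0.01)
})

test_that("the propagating AP is translation-invariant on a uniform
           cylinder", {
  # initiation transients and sealed-end boundary effects both reach on
  # the order of 100 um at these kinetics, so the comparison window sits
  # deep inside a long cylinder
  sim <- default_ap_sim(dt = 0.004, length_um = 800)
  waves <- lapply(seq(300, 500, by = 50), function(p) aligned_wave(sim, p))
  for (j in 2:length(waves)) {
    rmsd <- sqrt(mean((waves[[j]] - waves[[1]])^2))
    expect_lt(rmsd, 0.5)
  }
})

test_that("voltage clamp reproduces RC charge and series-resistance tau", {
  # ideal clamp on a single compartment: charge = C dV
  g <- sphere_grid(1000)                  # C = 10 pF
  vc <- voltage_clamp(g, config = sim_config(duration = 40, settle_ms = 2,
                                             dt = 0.004,
                                             record_species = "leak"),
                      v_hold = -70, v_step = -90, step_onset = 2,
                      step_width = 30, access_mohm = 0)
  sel <- vc$time > 2 & vc$time < 20
  base <- mean(vc$i_clamp[vc$time > 25 & vc$time < 30])
  q_nc <- sum((vc$i_clamp[sel] - base)) * vc$dt    # nA ms = pC
  expect_equal(abs(q_nc), 10 * 20 * 1e-3, tolerance = 0.02) # C dV in pC
  # with access resistance the transient tau is Rs C (rm-dominated cell)
  vc2 <- voltage_clamp(g, config = sim_config(duration = 40, settle_ms = 2,
                                              dt = 0.004,
                                              record_species = "leak"),
                       v_hold = -70, v_step = -90, step_onset = 2,
                       step_width = 30, access_mohm = 50)
  tr <- tibble::tibble(time = vc2$time - 2, current = vc2$i_clamp)
  attr(tr, "step_onset") <- 0
  fit <- fit_exponentials(tr[tr$time > -1 & tr$time < 20, ], 1,
                          window = c(0.02, 3))
  expect_equal(fit$taus[1], 50 * 10 * 1e-3, tolerance = 0.02) # Rs C ms
})

test_that("train protocol counts APs and flags failures", {
  g <- cylinder_grid(100, 1, 1)
  tr <- train_protocol(g, site_um = 10, n_aps = 5, frequency = 20,
                       amplitude = 0.05, pulse_width = 3,
                       config = sim_config(dt = 0.01, settle_ms = 10,
                                           duration = 1,
                                           record_species = character(0)))
  expect_true(tr$train_ok)
  expect_equal(tr$n_detected, 5)
  expect_equal(diff(tr$ap_times), rep(50, 4), tolerance = 0.02)
  sub <- train_protocol(g, site_um = 10, n_aps = 3, frequency = 20,
                        amplitude = 0.005, pulse_width = 3,
                        config = sim_config(dt = 0.01, settle_ms = 10,
                                            duration = 1,
                                            record_species = character(0)))
  expect_false(sub$train_ok)
  expect_equal(sub$n_detected, 0)
})

test_that("slow K inactivation broadens APs monotonically across a train", {
  g <- cylinder_grid(60, 1, 1)
  cfg <- sim_config(dt = 0.01, settle_ms = 10, duration = 1,
                    record_species = character(0),
                    kslow = list(vh = -45, k = 8, tau = 80))
  tr <- train_protocol(g, site_um = 10, n_aps = 6, frequency = 40,
                       amplitude = 0.03, pulse_width = 3, config = cfg)
  expect_true(tr$train_ok)
  w <- sim_waveform(tr, 30)
  waves <- lapply(tr$ap_times, function(tp) {
    as_ap_waveform(w[w$time > tp - 2 & w$time < tp + 8, ], "sim")
  })
  br <- broadening(waves)
  expect_equal(br$ratio[1], 1)
  expect_true(all(diff(br$ratio) > -1e-6))
  expect_gt(br$ratio[6], br$ratio[1])
})

test_that("charge is conserved in a passive run", {
  g <- cylinder_grid(60, 1, 2)
  cfg <- sim_config(duration = 60, settle_ms = 2, dt = 0.01,
                    record_i = "all", record_species = "leak",
                    stimuli = list(stim_current_step(30, 0.01, 5, 40)))
  sim <- simulate_cable(g, passive_params(),
                        active_densities(g_na = 0, g_k = 0), NULL, cfg)
  q_inj <- sum(sim$injected) * sim$dt
  # capacitive charge: C dV summed over compartments (nF mV = pC = nA ms)
  c_nf <- passive_params()$cm * g$area * 1e-5
  q_cap <- sum(c_nf * (sim$v[nrow(sim$v), ] - sim$v[1, ]))
  q_leak <- sum(colSums(sim$i_leak) * sim$dt)
  expect_equal(q_cap + q_leak, q_inj, tolerance = 1e-3 * q_inj)
})

test_that("waveforms converge under dt and dx refinement", {
  grid_t <- seq(-0.3, 1.5, by = 0.004)
  vb <- aligned_wave(default_ap_sim(dt = 0.004), 60, grid_t)
  v1 <- aligned_wave(default_ap_sim(dt = 0.002), 60, grid_t)
  v2 <- aligned_wave(default_ap_sim(dt = 0.004, max_seg = 0.5), 60, grid_t)
  amp <- diff(range(vb))
  expect_lt(sqrt(mean((v1 - vb)^2)) / amp, 0.01)
  expect_lt(sqrt(mean((v2 - vb)^2)) / amp, 0.01)
})

test_that("instability is flagged when voltages leave the physical range", {
  g <- cylinder_grid(40, 0.3, 1)
  cfg <- sim_config(duration = 5, settle_ms = 2, dt = 0.01,
                    record_species = character(0),
                    stimuli = list(stim_current_step(20, 5, 0.5, 3)))
  sim <- simulate_cable(g, passive_params(), active_densities(), NULL, cfg)
  expect_true(sim$unstable)
})
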