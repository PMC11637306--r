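#' Simulation configuration
#'
#' @param dt Time step in ms (default 0.004 ms, i.e. 250 kHz).
#' @param duration Simulated time after settling, ms.
#' @param stimuli A list of stimulus descriptions built with
#'   [stim_current_step()] or [stim_current_train()].
#' @param v_init Initial membrane potential, mV.
#' @param settle_ms Settling time simulated before the stimulus epoch and
#'   discarded from the output (default 20 ms).
#' @param record_v Compartment indices for voltage recording, or `"all"`.
#' @param record_i Compartment indices for current recording, or `"all"`,
#'   or `NULL` for none.
#' @param record_species Character subset of
#'   `c("na", "k", "k_comp", "ca", "leak")`.
#' @param theta Implicitness of the time stepping: 1 is backward Euler
#'   (default), 0.5 the trapezoid rule.
#' @param kslow Optional slow cumulative inactivation of the backbone K
#'   current: `NULL` (off) or a list with `vh`, `k`, `tau` (ms).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.004, duration = 15, stimuli = list(),
                       v_init = -80, settle_ms = 20,
                       record_v = "all", record_i = NULL,
                       record_species = c("na", "k", "k_comp", "ca", "leak"),
                       theta = 1, kslow = NULL) {
  stopifnot(dt > 0, duration >= dt, theta >= 0.5, theta <= 1)
  structure(list(dt = dt, duration = duration, stimuli = stimuli,
                 v_init = v_init, settle_ms = settle_ms,
                 record_v = record_v, record_i = record_i,
                 record_species = record_species, theta = theta,
                 kslow = kslow),
            class = "sim_config")
}

#' Current-step stimulus
#'
#' Stimulation sites are addressed by path distance from the root (um), so
#' stimulus placement is independent of the discretization.
#'
#' @param site_um Path position of the injection site, um.
#' @param amplitude Step amplitude, nA.
#' @param onset Step onset after settling, ms.
#' @param width Step width, ms.
#' @export
stim_current_step <- function(site_um, amplitude, onset, width) {
  list(kind = "current_step", site_um = site_um, amplitude = amplitude,
       onset = onset, width = width)
}

#' Current-pulse train stimulus
#'
#' @inheritParams stim_current_step
#' @param n_pulses Number of pulses.
#' @param frequency Pulse rate, Hz.
#' @export
stim_current_train <- function(site_um, amplitude, onset, width,
                               n_pulses, frequency) {
  stopifnot(n_pulses >= 1, frequency > 0)
  list(kind = "current_train", site_um = site_um, amplitude = amplitude,
       onset = onset, width = width, n_pulses = n_pulses,
       frequency = frequency)
}

site_index <- function(grid, site_um) {
  idx <- which.min(abs(grid$path_pos - site_um))
  if (abs(grid$path_pos[idx] - site_um) > max(grid$length) + 1e-6 &&
      site_um > max(grid$path_pos + grid$length / 2)) {
    abort("stimulus site beyond the end of the morphology")
  }
  idx
}

resolve_record <- function(spec_idx, n) {
  if (is.null(spec_idx)) return(integer(0))
  if (identical(spec_idx, "all")) return(seq_len(n))
  stopifnot(all(spec_idx >= 1 & spec_idx <= n))
  as.integer(spec_idx)
}

build_stim_trace <- function(stim, dt, n_steps, settle_ms) {
  tr <- numeric(n_steps)
  t <- (seq_len(n_steps)) * dt - settle_ms
  if (stim$kind == "current_step") {
    onsets <- stim$onset
  } else {
    onsets <- stim$onset + (seq_len(stim$n_pulses) - 1) * 1000 / stim$frequency
  }
  for (o in onsets) {
    tr[t > o & t <= o + stim$width] <- stim$amplitude
  }
  tr
}

# convert specific-unit membrane parameters + grid into the absolute-unit
# parameter list consumed by the C++ stepper
build_cable_pars <- function(grid, passive, densities, mixture, config,
                             vc = NULL, extra = NULL) {
  n <- nrow(grid)
  area <- grid$area                       # um^2
  c_nf <- passive$cm * area * 1e-5   # 1 uF/cm2 * um2 = 1e-5 nF
  g_leak_us <- (1 / passive$rm) * area * 1e-5
  e_leak_v <- rep(passive$e_leak, n)
  per_comp <- function(x) {
    if (length(x) == 1) rep(x, n) else {
      stopifnot(length(x) == n)
      as.numeric(x)
    }
  }
  g_na_us <- per_comp(densities$g_na) * area * 1e-5
  g_k_us <- per_comp(densities$g_k) * area * 1e-5
  g_kc_us <- per_comp(densities$g_k_comp) * area * 1e-5
  if (is.null(mixture)) {
    pa <- matrix(0, nrow = n, ncol = 3)
    mixture <- ca_mixture(p_total = 0)
  } else {
    p_sub <- mixture$p_total * mixture$ratio
    pa <- outer(area * 1e-2, p_sub)       # i_nA = pa * flux(mA/cm2 per cm/s)
  }
  # axial conductance to parent: 1 / (r_half_child + r_half_parent), uS.
  # The stored half resistances were computed at the discretize-time
  # resistivity; rescale them to the resistivity requested here so that
  # passive$ra is honoured (axial R is proportional to Ra).
  grid_ra <- attr(grid, "ra", exact = TRUE)
  ra_fac <- if (is.null(grid_ra)) 1 else passive$ra / grid_ra
  g_ax <- numeric(n)
  parent <- ifelse(is.na(grid$parent), -1L, as.integer(grid$parent) - 1L)
  for (i in seq_len(n)) {
    p <- grid$parent[i]
    if (!is.na(p)) {
      g_ax[i] <- 1 / (ra_fac * (grid$r_half[i] + grid$r_half[p]))
    }
  }

  n_steps <- as.integer(round((config$duration + config$settle_ms) / config$dt))
  stim_sites <- integer(0)
  stim_traces <- matrix(0, nrow = n_steps, ncol = 0)
  for (stim in config$stimuli) {
    stim_sites <- c(stim_sites, site_index(grid, stim$site_um) - 1L)
    stim_traces <- cbind(stim_traces,
                         build_stim_trace(stim, config$dt, n_steps,
                                          config$settle_ms))
  }

  kslow_on <- !is.null(config$kslow)
  ks <- if (kslow_on) config$kslow else list(vh = -45, k = 8, tau = 400)

  sp <- c("na", "k", "k_comp", "ca", "leak") %in% config$record_species

  pars <- list(
    n = n, parent = parent, c_nf = c_nf, g_axial_us = g_ax,
    g_leak_us = g_leak_us, e_leak = e_leak_v,
    g_na_us = g_na_us, g_k_us = g_k_us, g_kc_us = g_kc_us,
    pa_ca = as.numeric(pa),
    e_na = densities$e_na, e_k = densities$e_k,
    vshift = densities$vshift,
    vshift_k = if (is.null(densities$vshift_k)) 0 else densities$vshift_k,
    vshift_kc = if (is.null(densities$vshift_kc)) 0 else densities$vshift_kc,
    rate_scale_kc = if (is.null(densities$rate_scale_kc))
      densities$rate_scale_k else densities$rate_scale_kc,
    rate_scale_na = densities$rate_scale_na,
    rate_scale_h = if (is.null(densities$rate_scale_h))
      densities$rate_scale_na else densities$rate_scale_h,
    rate_scale_k = densities$rate_scale_k,
    ca_vh = mixture$vh, ca_slope = mixture$slope, ca_rate = mixture$rate,
    ca_tempfac = mixture$q10^((mixture$temp - mixture$temp_ref) / 10),
    ca_in = mixture$ca_in, ca_out = mixture$ca_out,
    temp_K = 273.15 + mixture$temp,
    kslow_on = kslow_on, kslow_vh = ks$vh, kslow_k = ks$k,
    kslow_tau = ks$tau,
    dt = config$dt, n_steps = n_steps, v_init = config$v_init,
    theta = config$theta,
    stim_sites = stim_sites, stim_traces = stim_traces,
    vc_site = if (is.null(vc)) -1L else site_index(grid, vc$site_um) - 1L,
    vc_rs_mohm = if (is.null(vc)) 0 else vc$access_mohm,
    vc_command = if (is.null(vc)) numeric(n_steps) else vc$command,
    record_v_idx = resolve_record(config$record_v, n) - 1L,
    record_i_idx = resolve_record(config$record_i, n) - 1L,
    record_species = as.integer(sp)
  )
  if (!is.null(extra)) pars[names(extra)] <- extra
  pars
}

finish_sim <- function(raw, grid, config, pars) {
  keep <- raw$t > config$settle_ms + 1e-9
  tt <- raw$t[keep] - config$settle_ms
  trim <- function(m) if (ncol(m) > 0) m[keep, , drop = FALSE] else m
  res <- list(
    time = tt,
    v = trim(raw$v),
    v_idx = pars$record_v_idx + 1L,
    i_na = trim(raw$i_na), i_k = trim(raw$i_k),
    i_k_comp = trim(raw$i_k_comp), i_ca = trim(raw$i_ca),
    i_leak = trim(raw$i_leak),
    i_idx = pars$record_i_idx + 1L,
    i_clamp = if (length(raw$i_clamp)) raw$i_clamp[keep] else NULL,
    injected = if (ncol(pars$stim_traces) > 0)
      rowSums(pars$stim_traces)[keep] else NULL,
    dt = config$dt,
    grid = grid,
    unstable = raw$unstable,
    config = config
  )
  class(res) <- "axon_sim"
  res
}

#' Run a cable simulation
#'
#' Integrates the branched cable equation
#' `C dV/dt = -I_ion + I_axial + I_inj` per compartment with an implicit
#' (unconditionally stable) scheme: voltages are advanced by a
#' backward-Euler (or trapezoid) step with the branched axial coupling
#' solved exactly at each step by a tree-structured elimination, and gate
#' variables are advanced by the exact exponential update at frozen voltage
#' (Rush-Larsen).
#'
#' @param grid A [discretize()] result.
#' @param passive A [passive_params()] object.
#' @param densities An [active_densities()] object (or `NULL` for passive).
#' @param mixture A [ca_mixture()] object (or `NULL` for no Ca current).
#' @param config A [sim_config()] object.
#' @return An `axon_sim` object: time grid (ms), voltage matrix
#'   (time x recorded compartments, mV), per-species current matrices (nA),
#'   the injected current trace, and an `unstable` flag set when any
#'   voltage leaves \[-150, 150\] mV.
#' @export
simulate_cable <- function(grid, passive = passive_params(),
                           densities = active_densities(),
                           mixture = ca_mixture(),
                           config = sim_config()) {
  stopifnot(inherits(grid, "compartment_grid"))
  if (is.null(densities)) densities <- active_densities(g_na = 0, g_k = 0)
  pars <- build_cable_pars(grid, passive, densities, mixture, config)
  raw <- cpp_cable_run(pars)
  finish_sim(raw, grid, config, pars)
}

#' Voltage-clamp simulation
#'
#' Clamps one site through a series access resistance (an ideal voltage
#' source in series with `access_mohm`) and returns the pipette current.
#'
#' @inheritParams simulate_cable
#' @param site_um Clamp site as path distance from the root, um.
#' @param v_hold Holding potential, mV.
#' @param v_step Step potential, mV.
#' @param step_onset,step_width Step timing after settling, ms.
#' @param access_mohm Access resistance, MOhm (0 gives a near-ideal clamp).
#' @return An `axon_sim` object whose `i_clamp` field holds the pipette
#'   current in nA.
#' @export
voltage_clamp <- function(grid, passive = passive_params(),
                          densities = NULL, mixture = NULL,
                          config = sim_config(duration = 120),
                          site_um = 0, v_hold = -70, v_step = -90,
                          step_onset = 5, step_width = 100,
                          access_mohm = 0) {
  stopifnot(access_mohm >= 0)
  if (is.null(densities)) densities <- active_densities(g_na = 0, g_k = 0)
  config$v_init <- v_hold
  n_steps <- as.integer(round((config$duration + config$settle_ms) /
                                config$dt))
  t <- seq_len(n_steps) * config$dt - config$settle_ms
  cmd <- rep(v_hold, n_steps)
  cmd[t > step_onset & t <= step_onset + step_width] <- v_step
  vc <- list(site_um = site_um, access_mohm = access_mohm, command = cmd)
  pars <- build_cable_pars(grid, passive, densities, mixture, config,
                           vc = vc)
  raw <- cpp_cable_run(pars)
  res <- finish_sim(raw, grid, config, pars)
  res$v_hold <- v_hold
  res$v_step <- v_step
  res$step_onset <- step_onset
  res$step_width <- step_width
  res
}

#' Pulse-train protocol
#'
#' Delivers `n_aps` brief current pulses and verifies that each elicits
#' exactly one action potential; runs where this fails are flagged.
#'
#' @inheritParams simulate_cable
#' @param site_um Injection site, um.
#' @param n_aps Number of pulses.
#' @param frequency Pulse rate, Hz.
#' @param amplitude Pulse amplitude, nA.
#' @param pulse_width Pulse width, ms (default 3).
#' @param detect_at_um Path position where APs are detected (defaults to
#'   the injection site).
#' @return An `axon_sim` object with extra fields `ap_times` (detected peak
#'   times, ms), `n_detected`, and `train_ok`.
#' @export
train_protocol <- function(grid, passive = passive_params(),
                           densities = active_densities(),
                           mixture = ca_mixture(), site_um = 0,
                           n_aps = 10, frequency = 20, amplitude = 0.3,
                           pulse_width = 3, detect_at_um = NULL,
                           config = NULL) {
  period <- 1000 / frequency
  duration <- n_aps * period + 10
  if (is.null(config)) {
    config <- sim_config(duration = duration,
                         record_species = c("na", "k"))
  }
  config$duration <- duration
  config$stimuli <- list(stim_current_train(site_um, amplitude, onset = 2,
                                            width = pulse_width,
                                            n_pulses = n_aps,
                                            frequency = frequency))
  res <- simulate_cable(grid, passive, densities, mixture, config)
  det_um <- if (is.null(detect_at_um)) site_um else detect_at_um
  det_idx <- match(site_index(grid, det_um), res$v_idx)
  vtr <- res$v[, det_idx]
  res$ap_times <- detect_ap_peaks(res$time, vtr)
  res$n_detected <- length(res$ap_times)
  res$train_ok <- res$n_detected == n_aps
  res
}

#' Detect AP peak times in a voltage trace
#'
#' Local maxima above `threshold` separated by at least `refractory` ms.
#'
#' @param time Time grid, ms.
#' @param v Voltage trace, mV.
#' @param threshold Peak threshold, mV.
#' @param refractory Minimum peak separation, ms.
#' @return Peak times in ms.
#' @export
detect_ap_peaks <- function(time, v, threshold = -10, refractory = 2) {
  n <- length(v)
  is_pk <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] &
               v[2:(n - 1)] >= v[3:n], FALSE) & v > threshold
  pk <- which(is_pk)
  if (length(pk) == 0) return(numeric(0))
  keep <- pk[1]
  for (p in pk[-1]) {
    if (time[p] - time[keep[length(keep)]] >= refractory) keep <- c(keep, p)
  }
  time[keep]
}

#' Extract one compartment's voltage trace as a waveform tibble
#'
#' @param sim An `axon_sim` object.
#' @param site_um Path position, um (nearest recorded compartment is used).
#' @param window Optional `c(t0, t1)` time window, ms.
#' @return An `ap_waveform` tibble with columns `time` and `v`.
#' @export
sim_waveform <- function(sim, site_um, window = NULL) {
  idx <- which.min(abs(sim$grid$path_pos[sim$v_idx] - site_um))
  w <- tibble::tibble(time = sim$time, v = sim$v[, idx])
  if (!is.null(window)) {
    w <- dplyr::filter(w, .data$time >= window[1], .data$time <= window[2])
  }
  as_ap_waveform(w, source = "sim")
}

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf(
    "<axon_sim> %d compartments, %.3g ms at dt = %g ms%s\n",
    nrow(x$grid), max(x$time), x$dt,
    if (isTRUE(x$unstable)) " [UNSTABLE]" else ""))
  invisible(x)
}
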