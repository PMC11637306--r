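#' Pipette and amplifier description
#'
#' The recording instrument is modelled as an N-segment RC ladder (patch
#' pipette) between the amplifier node and the cell, with the resistance
#' concentrated toward the tip, plus an access resistance from the tip into
#' the cell interior, a GOhm seal leak from the tip to the bath, and two
#' amplifier compensations: capacitance neutralization (a fraction of the
#' pipette capacitance is cancelled) and bridge balance (an IR term
#' subtracted from the recorded voltage in current clamp).
#'
#' @param n_seg Number of pipette segments.
#' @param r_total_mohm Total pipette resistance, MOhm.
#' @param c_total_pf Total pipette capacitance, pF.
#' @param r_profile Fractional resistance per segment, tip first
#'   (default 60/20/10/6/4%).
#' @param access_mohm Access (tip-to-cytoplasm) resistance, MOhm.
#' @param seal_gohm Seal resistance, GOhm (default 12).
#' @param neutralization Capacitance-neutralization fraction in \[0, 1).
#' @param bridge_mohm Bridge-balance resistance, MOhm; `NULL` balances the
#'   full pipette + access resistance.
#' @return A list of class `pipette_amplifier`.
#' @export
pipette_amplifier <- function(n_seg = 5, r_total_mohm = 40, c_total_pf = 6,
                              r_profile = c(0.6, 0.2, 0.1, 0.06, 0.04),
                              access_mohm = 150, seal_gohm = 12,
                              neutralization = 0.9, bridge_mohm = NULL) {
  stopifnot(n_seg >= 1, length(r_profile) == n_seg,
            abs(sum(r_profile) - 1) < 1e-6, r_total_mohm > 0,
            c_total_pf > 0, access_mohm >= 0, seal_gohm > 0,
            neutralization >= 0)
  if (neutralization >= 1) {
    abort("capacitance neutralization must stay below 1 (instability)",
          class = "axonwave_instability")
  }
  if (is.null(bridge_mohm)) bridge_mohm <- r_total_mohm + access_mohm
  structure(list(n_seg = n_seg, r_total_mohm = r_total_mohm,
                 c_total_pf = c_total_pf, r_profile = r_profile,
                 access_mohm = access_mohm, seal_gohm = seal_gohm,
                 neutralization = neutralization,
                 bridge_mohm = bridge_mohm),
            class = "pipette_amplifier")
}

#' Identity (fully transparent) instrument
#'
#' Zero pipette resistance and capacitance, zero access resistance: the
#' amplifier node sits directly on the membrane.
#'
#' @export
identity_instrument <- function() {
  pipette_amplifier(r_total_mohm = 1e-4, c_total_pf = 1e-6,
                    access_mohm = 0, seal_gohm = 1e6,
                    neutralization = 0, bridge_mohm = 0)
}

# append the pipette ladder to a cable parameter list; returns the
# augmented pars plus the amplifier compartment index (1-based)
attach_instrument <- function(pars, grid, instrument, site_um) {
  n0 <- pars$n
  ns <- instrument$n_seg
  site <- site_index(grid, site_um)
  # effective per-segment capacitance after neutralization
  c_seg_nf <- instrument$c_total_pf * 1e-3 *
    (1 - instrument$neutralization) / ns
  r_seg <- instrument$r_total_mohm * instrument$r_profile  # tip first
  # segment 1 (tip) couples to the cell through access + half its own R
  g_ax_new <- numeric(ns)
  parent_new <- integer(ns)
  for (j in seq_len(ns)) {
    if (j == 1) {
      parent_new[j] <- site - 1L                 # 0-based
      g_ax_new[j] <- 1 / (instrument$access_mohm + r_seg[1] / 2 + 1e-9)
    } else {
      parent_new[j] <- n0 + j - 2L
      g_ax_new[j] <- 1 / (r_seg[j - 1] / 2 + r_seg[j] / 2)
    }
  }
  g_leak_new <- numeric(ns)
  g_leak_new[1] <- 1 / (instrument$seal_gohm * 1000)  # uS, tip to bath
  pars$n <- n0 + ns
  pars$parent <- c(pars$parent, parent_new)
  pars$c_nf <- c(pars$c_nf, rep(c_seg_nf, ns))
  pars$g_axial_us <- c(pars$g_axial_us, g_ax_new)
  pars$g_leak_us <- c(pars$g_leak_us, g_leak_new)
  pars$e_leak <- c(pars$e_leak, rep(0, ns))           # bath potential
  pars$g_na_us <- c(pars$g_na_us, numeric(ns))
  pars$g_k_us <- c(pars$g_k_us, numeric(ns))
  pars$g_kc_us <- c(pars$g_kc_us, numeric(ns))
  pa <- matrix(pars$pa_ca, ncol = 3)
  pars$pa_ca <- as.numeric(rbind(pa, matrix(0, ns, 3)))
  list(pars = pars, amp_idx = n0 + ns)
}

#' Record a protocol through the pipette/amplifier model
#'
#' Runs the coupled membrane + pipette circuit: the ladder is appended at
#' the clamp site, current-clamp stimuli are injected at the amplifier
#' node, and the voltage at the amplifier node (after bridge-balance
#' subtraction of the injected-current IR drop) is returned alongside the
#' true membrane voltage at the site.
#'
#' @param grid A [discretize()] result.
#' @param instrument A [pipette_amplifier()].
#' @param site_um Recording site (path position, um).
#' @param config A [sim_config()]; its stimuli are re-routed to the
#'   amplifier node.
#' @param passive,densities,mixture Membrane parameters as in
#'   [simulate_cable()].
#' @return A tibble with `time`, `v_amp` (recorded, mV), `v_true` (membrane
#'   voltage at the site, mV), `i_inj` (nA); attribute `sim` holds the full
#'   `axon_sim`.
#' @export
forward_record <- function(grid, instrument = pipette_amplifier(),
                           site_um, config,
                           passive = passive_params(),
                           densities = active_densities(),
                           mixture = NULL) {
  stopifnot(inherits(instrument, "pipette_amplifier"))
  pars <- instrument_pars(grid, instrument, site_um, config, passive,
                          densities, mixture)
  run_instrument_pars(pars, grid, config, instrument, site_um)
}

# assemble the coupled membrane+pipette parameter list (reusable so that
# fitting loops can mutate densities without rebuilding)
instrument_pars <- function(grid, instrument, site_um, config, passive,
                            densities, mixture) {
  site <- site_index(grid, site_um)
  config$record_v <- "all"
  pars <- build_cable_pars(grid, passive, densities, mixture, config)
  att <- attach_instrument(pars, grid, instrument, site_um)
  pars <- att$pars
  if (length(pars$stim_sites) > 0) {
    pars$stim_sites <- rep(att$amp_idx - 1L, length(pars$stim_sites))
  }
  pars$record_v_idx <- c(site, att$amp_idx) - 1L
  attr(pars, "site") <- site
  attr(pars, "amp_idx") <- att$amp_idx
  pars
}

run_instrument_pars <- function(pars, grid, config, instrument, site_um) {
  raw <- cpp_cable_run(pars)
  res <- finish_sim(raw, grid, config, pars)
  i_inj <- if (is.null(res$injected)) numeric(length(res$time)) else
    res$injected
  v_amp <- res$v[, 2] - instrument$bridge_mohm * i_inj
  out <- tibble::tibble(time = res$time,
                        v_amp = v_amp,
                        v_true = res$v[, 1],
                        i_inj = i_inj)
  attr(out, "sim") <- res
  attr(out, "site_um") <- site_um
  out
}

#' Fit passive parameters through the instrument
#'
#' Recovers specific membrane capacitance, axial resistivity, and access
#' resistance from a recorded subthreshold response by derivative-free
#' least squares on the forward model; the specific membrane resistance is
#' held fixed (default 50 kOhm cm^2).
#'
#' @param recorded A tibble with `time` and `v_amp` from a subthreshold
#'   current-step protocol.
#' @param grid,instrument,site_um,config As used to produce the recording
#'   (the stimulus in `config` must match).
#' @param rm_fixed Fixed specific membrane resistance, kOhm cm^2.
#' @param start Named starting values `c(cm, ra, access)`.
#' @param maxit Optimizer iteration budget.
#' @return A list with `cm`, `ra`, `access_mohm`, `rms_mv`, and the
#'   optimizer object.
#' @export
fit_passive <- function(recorded, grid, instrument, site_um, config,
                        rm_fixed = 50, start = c(cm = 1, ra = 150,
                                                 access = 100),
                        maxit = 200) {
  target <- recorded$v_amp
  obj <- function(logp) {
    p <- exp(logp)
    inst <- instrument
    inst$access_mohm <- p[3]
    sim <- forward_record(grid, inst, site_um, config,
                          passive = passive_params(cm = p[1], ra = p[2],
                                                   rm = rm_fixed),
                          densities = active_densities(g_na = 0, g_k = 0),
                          mixture = NULL)
    sqrt(mean((sim$v_amp - target)^2))
  }
  o <- stats::optim(log(start), obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-10))
  for (rst in 1:2) {
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  }
  p <- exp(o$par)
  list(cm = unname(p[1]), ra = unname(p[2]), access_mohm = unname(p[3]),
       rm = rm_fixed, rms_mv = o$value, optim = o)
}

#' Fit active conductance parameters to recorded APs
#'
#' Multi-start derivative-free optimization of the Na/K conductance model
#' (densities, voltage shift, kinetic scale factors) so that the forward
#' model reproduces recorded AP waveforms through the instrument. Each
#' initialization is optimized against each target AP independently and
#' the resulting parameter sets are averaged, mirroring the
#' average-over-starts protocol used for instrument-corrected recordings.
#'
#' @param targets A list of recorded AP tibbles (`time`, `v_amp`), all from
#'   the same protocol.
#' @param grid,instrument,site_um,config Forward-model context; `config`
#'   must reproduce the stimulus used for the targets.
#' @param passive A [passive_params()] (e.g. from [fit_passive()]).
#' @param n_starts Number of random initializations (default 4).
#' @param base Reference [active_densities()]; densities are bounded to
#'   \[0, 5x\] base, the voltage shift to base +-20 mV, kinetic scales to
#'   \[0.2, 5\]x base.
#' @param max_eval Objective evaluation budget per start (default 2000).
#' @param seed Seed for the initializations.
#' @return A list of class `conductance_fit`: `params` (averaged), tibble
#'   `per_start` of all optimizations, `rms_mv` (mean goodness), and the
#'   context needed by [corrected_ap()].
#' @export
fit_conductances <- function(targets, grid, instrument, site_um, config,
                             passive = passive_params(), n_starts = 4,
                             base = active_densities(), max_eval = 2000,
                             seed = 1) {
  if (!is.list(targets) || is.data.frame(targets)) targets <- list(targets)
  lo <- c(g_na = 1e-3 * base$g_na, g_k = 1e-3 * base$g_k,
          vshift = base$vshift - 20, rs_na = 0.2 * base$rate_scale_na,
          rs_k = 0.2 * base$rate_scale_k)
  hi <- c(g_na = 5 * base$g_na, g_k = 5 * base$g_k,
          vshift = base$vshift + 20, rs_na = 5 * base$rate_scale_na,
          rs_k = 5 * base$rate_scale_k)
  make_dens <- function(p) {
    active_densities(g_na = p[1], g_k = p[2], vshift = p[3],
                     rate_scale_na = p[4],
                     rate_scale_h = p[4] * base$rate_scale_h /
                       base$rate_scale_na,
                     rate_scale_k = p[5])
  }
  pars0 <- instrument_pars(grid, instrument, site_um, config, passive,
                           make_dens(c(base$g_na, base$g_k, base$vshift,
                                       base$rate_scale_na,
                                       base$rate_scale_k)), NULL)
  n_bio <- nrow(grid)
  area <- grid$area
  keep <- attr(pars0, "keep_time", exact = TRUE)
  obj_for <- function(target) {
    function(p) {
      if (any(p < lo) || any(p > hi)) return(1e6)
      pars0$g_na_us[seq_len(n_bio)] <- p[1] * area * 1e-5
      pars0$g_k_us[seq_len(n_bio)] <- p[2] * area * 1e-5
      pars0$vshift <- p[3]
      pars0$rate_scale_na <- p[4]
      pars0$rate_scale_h <- p[4] * base$rate_scale_h / base$rate_scale_na
      pars0$rate_scale_k <- p[5]
      rec <- run_instrument_pars(pars0, grid, config, instrument, site_um)
      sqrt(mean((rec$v_amp - target$v_amp)^2))
    }
  }
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1) {
        c(base$g_na, base$g_k, base$vshift, base$rate_scale_na,
          base$rate_scale_k)
      } else {
        lo + runif(5) * (hi - lo) * c(0.4, 0.4, 1, 0.5, 0.5) +
          c(0.1, 0.1, 0, 0.1, 0.1) * c(base$g_na, base$g_k, 0,
                                       base$rate_scale_na,
                                       base$rate_scale_k)
      }
    })
  })
  rows <- list()
  for (ti in seq_along(targets)) {
    objf <- obj_for(targets[[ti]])
    for (k in seq_len(n_starts)) {
      # Nelder-Mead with simplex restarts: the budget is split into three
      # rounds, each restarted at the previous optimum (NM stalls on
      # narrow valleys; restarting rebuilds the simplex scale)
      o <- stats::optim(starts[[k]], objf, method = "Nelder-Mead",
                        control = list(maxit = ceiling(max_eval / 3),
                                       reltol = 1e-9))
      for (rst in 1:2) {
        o <- stats::optim(o$par, objf, method = "Nelder-Mead",
                          control = list(maxit = ceiling(max_eval / 3),
                                         reltol = 1e-9))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        target = ti, start = k, g_na = o$par[1], g_k = o$par[2],
        vshift = o$par[3], rate_scale_na = o$par[4],
        rate_scale_k = o$par[5], rms_mv = o$value,
        converged = o$convergence == 0)
    }
  }
  per_start <- dplyr::bind_rows(rows)
  if (all(!per_start$converged) && all(per_start$rms_mv >= 1e6)) {
    abort("all conductance-fit starts failed", class = "axonwave_fit_error")
  }
  avg <- colMeans(per_start[, c("g_na", "g_k", "vshift", "rate_scale_na",
                                "rate_scale_k")])
  out <- list(params = avg, per_start = per_start,
              rms_mv = mean(per_start$rms_mv),
              densities = make_dens(unname(avg)),
              passive = passive, grid = grid, config = config,
              site_um = site_um, instrument = instrument)
  class(out) <- "conductance_fit"
  out
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf(
    "<conductance_fit> g_na = %.1f, g_k = %.1f mS/cm^2 (rms %.3g mV, %d optimizations)\n",
    x$params["g_na"], x$params["g_k"], x$rms_mv, nrow(x$per_start)))
  invisible(x)
}

#' Predict the native AP from a conductance fit
#'
#' Reruns the fitted membrane model on the bare morphology — without the
#' pipette and amplifier circuit — and returns the predicted native AP at
#' the recording site.
#'
#' @param fit A `conductance_fit`.
#' @param grid Optional grid override.
#' @return An `ap_waveform` tibble of the native AP, with the waveform
#'   metrics in `attr(, "metrics")`.
#' @export
corrected_ap <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "conductance_fit"))
  if (is.null(grid)) grid <- fit$grid
  sim <- simulate_cable(grid, fit$passive, fit$densities, NULL, fit$config)
  w <- sim_waveform(sim, fit$site_um)
  attr(w, "metrics") <- ap_metrics(w)
  w
}

single_compartment_grid <- function(area_um2) {
  d <- sqrt(area_um2 / pi)              # sphere: area = pi d^2
  g <- tibble::tibble(index = 1L, parent = NA_integer_, path_pos = 0,
                      length = d, diameter = d, area = area_um2,
                      r_half = 0, label = "axon", branch_id = 1L)
  structure(g, class = c("compartment_grid", class(tibble::tibble())))
}

#' Outside-out patch I_Na / I_K two-step protocol
#'
#' Simulates a membrane patch under voltage clamp from a -110 mV holding
#' potential: a 0 mV / 0.4 ms step whose peak inward current gives I_Na,
#' and a +70 mV step whose late (last 20%) outward current gives I_K.
#' Optional P/4-style leak subtraction uses four quarter-amplitude
#' hyperpolarizing steps.
#'
#' @param densities An [active_densities()] for the patch.
#' @param area_um2 Patch area, um^2.
#' @param passive A [passive_params()].
#' @param v_hold Holding potential, mV (default -110).
#' @param na_step,k_step Step potentials, mV.
#' @param na_width,k_width Step widths, ms.
#' @param leak_subtract Apply P/4 leak subtraction (default TRUE).
#' @param dt Time step, ms.
#' @return A one-row tibble: `i_na_pa_um2`, `i_k_pa_um2` (current
#'   densities, pA/um^2, I_Na reported as inward-positive magnitude),
#'   `ratio` (I_Na/I_K).
#' @export
ina_ik_protocol <- function(densities = active_densities(),
                            area_um2 = 10, passive = passive_params(),
                            v_hold = -110, na_step = 0, k_step = 70,
                            na_width = 0.4, k_width = 5,
                            leak_subtract = TRUE, dt = 0.004) {
  if (area_um2 <= 0) abort("patch area must be positive")
  g <- single_compartment_grid(area_um2)
  run_step <- function(v_step, width, dens) {
    vc <- voltage_clamp(g, passive, dens, NULL,
                        config = sim_config(duration = width + 2,
                                            settle_ms = 10, dt = dt,
                                            record_species = character(0)),
                        site_um = 0, v_hold = v_hold, v_step = v_step,
                        step_onset = 1, step_width = width,
                        access_mohm = 0)
    # at clamped voltage the pipette current equals the total membrane
    # current (outward positive, inward negative)
    tibble::tibble(time = vc$time, current = vc$i_clamp)
  }
  leak_est <- function(step, width) {
    if (!leak_subtract) return(function(tr) tr)
    # P/4: four quarter-amplitude hyperpolarizing steps; their summed
    # passive response estimates (minus) the test-step leak
    pstep <- v_hold - (step - v_hold) / 4
    lk <- run_step(pstep, width, densities)   # gates stay shut below v_hold
    function(tr) {
      tr$current <- tr$current + 4 * lk$current
      tr
    }
  }
  na_tr <- leak_est(na_step, na_width)(run_step(na_step, na_width, densities))
  k_tr <- leak_est(k_step, k_width)(run_step(k_step, k_width, densities))
  in_step <- function(tr, width) tr$time > 1 & tr$time <= 1 + width
  i_na_peak <- -min(na_tr$current[in_step(na_tr, na_width)])   # inward magnitude
  late <- k_tr$time > 1 + 0.8 * k_width & k_tr$time <= 1 + k_width
  i_k_late <- mean(k_tr$current[late])
  # nA over um^2 -> pA/um^2
  tibble::tibble(
    i_na_pa_um2 = 1000 * i_na_peak / area_um2,
    i_k_pa_um2 = 1000 * i_k_late / area_um2,
    ratio = ifelse(i_k_late > 0, i_na_peak / i_k_late, NA_real_))
}
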