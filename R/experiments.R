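#' Named in-silico experiments
#'
#' Orchestrates the study's simulation experiments end-to-end as named,
#' seeded, reproducible runs:
#'
#' * `size_dependence` — one AP on a synthetic varicose axon with
#'   homogeneous conductances; per-compartment and per-bouton AP metrics,
#'   Ca2+ influx, and power-law release, with the regression of
#'   repolarization area on local capacitance and the release spread.
#' * `compensation` — adds a compensatory K conductance whose density
#'   scales with the inverse local capacitance; the scale is chosen by a
#'   golden-section search minimizing the across-bouton SD of the
#'   repolarization area.
#' * `dtx_in_silico` — the compensated model with the compensatory current
#'   zeroed (the in-silico analogue of blocking Kv1 with dendrotoxin);
#'   reports per-compartment half-width widening and its size dependence.
#' * `instrument_correction` — conductance fitting through the pipette
#'   model, native-AP prediction, and the pipette-parameter grid test of
#'   the area-vs-half-width robustness.
#' * `vsd_uniformity` — renders VSD trials from the simulated axon,
#'   processes them with the imaging pipeline, and correlates the
#'   per-segment VSD AP area with the local diameter.
#'
#' @param name Experiment name (see above).
#' @param seed Integer seed; fixes the morphology and all noise.
#' @param spec A [generator_spec()] (its `seed` is overridden by `seed`).
#' @param densities Baseline [active_densities()].
#' @param mixture A [ca_mixture()].
#' @param passive A [passive_params()].
#' @param dt Time step, ms (default 0.004: 250 kHz).
#' @param ... Experiment-specific options: `margin_um` (analysis margin at
#'   the stimulated end, default 30), `scale_range` and `n_search` for
#'   `compensation`, `n_starts`/`max_eval` for `instrument_correction`,
#'   `n_trials`/`duration_ms` for `vsd_uniformity`.
#' @return An `axon_experiment` report: list with `name`, `seed`,
#'   `summary` (one-row tibble of headline statistics), `tables` (named
#'   list of tibbles), and `config` (parameter snapshot).
#' @export
run_experiment <- function(name = c("size_dependence", "compensation",
                                    "dtx_in_silico",
                                    "instrument_correction",
                                    "vsd_uniformity"),
                           seed = 1, spec = NULL,
                           densities = active_densities(),
                           mixture = ca_mixture(),
                           passive = passive_params(), dt = 0.004, ...) {
  name <- match.arg(name)
  if (is.null(spec)) spec <- generator_spec(seed = seed)
  spec$seed <- seed
  fn <- switch(name,
               size_dependence = exp_size_dependence,
               compensation = exp_compensation,
               dtx_in_silico = exp_dtx,
               instrument_correction = exp_instrument,
               vsd_uniformity = exp_vsd)
  rep <- fn(spec = spec, densities = densities, mixture = mixture,
            passive = passive, dt = dt, ...)
  rep$name <- name
  rep$seed <- seed
  rep$config <- list(spec = spec, densities = densities,
                     mixture = mixture, passive = passive, dt = dt)
  class(rep) <- "axon_experiment"
  rep
}

# shared core: simulate one AP and compute the per-compartment and
# per-bouton metric tables
axon_ap_tables <- function(grid, passive, densities, mixture, dt,
                           margin_um = 30, duration = 8, stim_nA = 0.15) {
  cfg <- sim_config(duration = duration, settle_ms = 20, dt = dt,
                    record_i = "all", record_species = "ca",
                    stimuli = list(stim_current_step(5, stim_nA, 0.2, 1)))
  sim <- simulate_cable(grid, passive, densities, mixture, cfg)
  L <- max(grid$path_pos)
  sel <- which(grid$path_pos > margin_um & grid$path_pos < L - 10)
  per_comp <- purrr::map_dfr(sel, function(i) {
    w <- as_ap_waveform(tibble::tibble(time = sim$time, v = sim$v[, i]),
                        source = "sim")
    m <- tryCatch(ap_metrics(w), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(index = i, path_pos = grid$path_pos[i],
                     diameter = grid$diameter[i],
                     capacitance_pf = local_capacitance(grid,
                                                        passive$cm, i),
                     bouton_id = grid$bouton_id[i]),
      m)
  })
  influx <- integrate_influx(sim)
  influx <- influx[match(sel, influx$index), ]
  per_comp$influx_fc_um2 <- influx$influx_fc_um2
  per_comp$release <- release_from_influx(per_comp$influx_fc_um2)
  per_bouton <- per_comp %>%
    dplyr::filter(!is.na(.data$bouton_id)) %>%
    dplyr::group_by(.data$bouton_id) %>%
    dplyr::summarise(
      path_pos = mean(.data$path_pos),
      diameter = max(.data$diameter),
      capacitance_pf = sum(.data$capacitance_pf),
      repol_area = .data$repol_area[which.max(.data$diameter)],
      half_width = .data$half_width[which.max(.data$diameter)],
      influx_fc_um2 = sum(.data$influx_fc_um2 * .data$area) /
        sum(.data$area),
      .groups = "drop")
  per_bouton$release <- release_from_influx(per_bouton$influx_fc_um2)
  list(sim = sim, per_comp = per_comp, per_bouton = per_bouton)
}

size_summary <- function(tabs) {
  pc <- tabs$per_comp
  fit <- stats::lm(repol_area ~ capacitance_pf, data = pc)
  vb <- variability_summary(tabs$per_bouton$release)
  vc <- variability_summary(pc$release)
  tibble::tibble(
    slope_repol_cap = stats::coef(fit)[[2]],
    cor_repol_cap = stats::cor(pc$repol_area, pc$capacitance_pf),
    cor_hw_cap = stats::cor(pc$half_width, pc$capacitance_pf),
    sd_repol_bouton = stats::sd(tabs$per_bouton$repol_area),
    sd_repol_comp = stats::sd(pc$repol_area),
    release_rel_range_bouton = vb$rel_range,
    release_cv_bouton = vb$cv,
    release_rel_range_comp = vc$rel_range,
    n_comp = nrow(pc), n_bouton = nrow(tabs$per_bouton))
}

exp_size_dependence <- function(spec, densities, mixture, passive, dt,
                                margin_um = 30, ...) {
  grid <- find_boutons(discretize(make_axon(spec), 1, ra = passive$ra))
  tabs <- axon_ap_tables(grid, passive, densities, mixture, dt, margin_um)
  list(summary = size_summary(tabs),
       tables = list(per_comp = tabs$per_comp,
                     per_bouton = tabs$per_bouton),
       grid = grid)
}

# density profile proportional to 1 / local capacitance
comp_profile <- function(grid, passive, scale) {
  scale / (local_capacitance(grid, passive$cm, seq_len(nrow(grid))))
}

golden_search <- function(f, lower, upper, n_eval = 12) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c_ <- b - phi * (b - a); d <- a + phi * (b - a)
  fc <- f(c_); fd <- f(d)
  for (k in seq_len(n_eval - 2)) {
    if (fc < fd) {
      b <- d; d <- c_; fd <- fc
      c_ <- b - phi * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  if (fc < fd) list(x = c_, value = fc) else list(x = d, value = fd)
}

exp_compensation <- function(spec, densities, mixture, passive, dt,
                             margin_um = 30, scale_range = c(0.005, 2),
                             n_search = 10, ...) {
  grid <- find_boutons(discretize(make_axon(spec), 1, ra = passive$ra))
  run_scale <- function(scale) {
    d <- densities
    d$g_k_comp <- comp_profile(grid, passive, scale)
    axon_ap_tables(grid, passive, d, mixture, dt, margin_um)
  }
  objective <- function(log_scale) {
    tabs <- run_scale(exp(log_scale))
    stats::sd(tabs$per_bouton$repol_area)
  }
  opt <- golden_search(objective, log(scale_range[1]), log(scale_range[2]),
                       n_eval = n_search)
  best_scale <- exp(opt$x)
  tabs <- run_scale(best_scale)
  base <- axon_ap_tables(grid, passive, densities, mixture, dt, margin_um)
  s_comp <- size_summary(tabs)
  s_base <- size_summary(base)
  summary <- dplyr::bind_cols(
    s_comp,
    tibble::tibble(
      scale = best_scale,
      sd_reduction_bouton = s_base$sd_repol_bouton / s_comp$sd_repol_bouton,
      sd_reduction_comp = s_base$sd_repol_comp / s_comp$sd_repol_comp,
      rel_range_reduction =
        s_base$release_rel_range_bouton / s_comp$release_rel_range_bouton))
  list(summary = summary,
       tables = list(per_comp = tabs$per_comp,
                     per_bouton = tabs$per_bouton,
                     baseline_summary = s_base),
       grid = grid, scale = best_scale)
}

exp_dtx <- function(spec, densities, mixture, passive, dt,
                    margin_um = 30, scale = NULL, ...) {
  if (is.null(scale)) {
    comp <- exp_compensation(spec = spec, densities = densities,
                             mixture = mixture, passive = passive,
                             dt = dt, margin_um = margin_um, ...)
    grid <- comp$grid
    scale <- comp$scale
    comp_summary <- comp$summary
  } else {
    grid <- find_boutons(discretize(make_axon(spec), 1, ra = passive$ra))
    comp_summary <- tibble::tibble(scale = scale)
  }
  d_comp <- densities
  d_comp$g_k_comp <- comp_profile(grid, passive, scale)
  tabs_ctrl <- axon_ap_tables(grid, passive, d_comp, mixture, dt, margin_um)
  tabs_dtx <- axon_ap_tables(grid, passive, densities, mixture, dt,
                             margin_um)
  joined <- dplyr::inner_join(
    dplyr::select(tabs_ctrl$per_comp, "index", "capacitance_pf",
                  hw_ctrl = "half_width", ra_ctrl = "repol_area"),
    dplyr::select(tabs_dtx$per_comp, "index", hw_dtx = "half_width",
                  ra_dtx = "repol_area"),
    by = "index")
  joined$hw_increase <- joined$hw_dtx / joined$hw_ctrl - 1
  terts <- stats::quantile(joined$capacitance_pf, c(1 / 3, 2 / 3))
  small <- joined$capacitance_pf <= terts[1]
  large <- joined$capacitance_pf >= terts[2]
  fit_dtx <- stats::lm(ra_dtx ~ capacitance_pf, data = joined)
  summary <- tibble::tibble(
    hw_increase_small = mean(joined$hw_increase[small]),
    hw_increase_large = mean(joined$hw_increase[large]),
    ordering_ok = mean(joined$hw_increase[small]) >
      mean(joined$hw_increase[large]),
    slope_dtx = stats::coef(fit_dtx)[[2]],
    slope_ctrl = stats::coef(stats::lm(ra_ctrl ~ capacitance_pf,
                                       data = joined))[[2]],
    scale = scale)
  list(summary = summary,
       tables = list(per_comp = joined,
                     compensation_summary = comp_summary),
       grid = grid)
}

exp_instrument <- function(spec, densities, mixture, passive, dt,
                           n_starts = 4, max_eval = 800,
                           axon_len = 80, ...) {
  # a short uniform axon keeps each forward simulation cheap; the
  # instrument physics does not depend on the varicosities
  nodes <- tibble::tibble(id = 1:2, parent_id = c(NA, 1L),
                          x = c(0, axon_len), y = 0, z = 0, radius = 0.5,
                          label = "axon")
  grid <- discretize(morphology(nodes), 1, ra = passive$ra)
  site <- axon_len / 2
  cfg <- sim_config(duration = 8, settle_ms = 5, dt = dt,
                    record_species = character(0),
                    stimuli = list(stim_current_step(site, 0.03, 1, 3)))
  inst <- pipette_amplifier()
  rec <- forward_record(grid, inst, site, cfg, passive, densities, NULL)
  fit <- fit_conductances(list(rec), grid, inst, site, cfg,
                          passive = passive, n_starts = n_starts,
                          base = densities, max_eval = max_eval,
                          seed = spec$seed)
  native <- simulate_cable(grid, passive, densities, NULL, cfg)
  crop <- c(1.4, 8)
  w_native <- sim_waveform(native, site, window = crop)
  w_corr <- as_ap_waveform(dplyr::filter(corrected_ap(fit),
                                         .data$time >= crop[1]),
                           source = "sim")
  w_rec <- as_ap_waveform(
    tibble::tibble(time = rec$time, v = rec$v_amp)[rec$time >= crop[1], ],
    source = "sim")
  m_native <- ap_metrics(w_native)
  m_corr <- ap_metrics(w_corr)
  m_rec <- ap_metrics(w_rec)
  # pipette grid: relative change of area vs half-width
  grid_rows <- purrr::map_dfr(c(20, 40, 80), function(rp) {
    purrr::map_dfr(c(3, 6, 12), function(cp) {
      inst_g <- pipette_amplifier(r_total_mohm = rp, c_total_pf = cp)
      rg <- forward_record(grid, inst_g, site, cfg, passive, densities,
                           NULL)
      wg <- as_ap_waveform(
        tibble::tibble(time = rg$time, v = rg$v_amp)[rg$time >= crop[1], ],
        source = "sim")
      mg <- ap_metrics(wg)
      tibble::tibble(
        r_pipette = rp, c_pipette = cp,
        d_area = abs(mg$area - m_native$area) / m_native$area,
        d_hw = abs(mg$half_width - m_native$half_width) /
          m_native$half_width)
    })
  })
  summary <- tibble::tibble(
    g_na_fit = fit$params[["g_na"]], g_k_fit = fit$params[["g_k"]],
    g_na_err = abs(fit$params[["g_na"]] - densities$g_na) / densities$g_na,
    g_k_err = abs(fit$params[["g_k"]] - densities$g_k) / densities$g_k,
    hw_native = m_native$half_width, hw_corrected = m_corr$half_width,
    hw_recorded = m_rec$half_width,
    hw_corr_err = abs(m_corr$half_width - m_native$half_width) /
      m_native$half_width,
    rms_mv = fit$rms_mv,
    grid_area_lt_hw = all(grid_rows$d_area < grid_rows$d_hw))
  list(summary = summary,
       tables = list(per_start = fit$per_start, pipette_grid = grid_rows,
                     metrics = dplyr::bind_rows(
                       native = m_native, corrected = m_corr,
                       recorded = m_rec, .id = "which")),
       fit = fit)
}

exp_vsd <- function(spec, densities, mixture, passive, dt,
                    duration_ms = 20, compensated = FALSE,
                    scale = 0.05, ...) {
  morph <- make_axon(spec)
  d <- densities
  if (compensated) {
    grid <- find_boutons(discretize(morph, 1, ra = passive$ra))
    d$g_k_comp <- comp_profile(grid, passive, scale)
  }
  ds <- make_vsd_dataset(spec, morph, duration_ms = duration_ms,
                         densities = d, mixture = NULL, passive = passive)
  segs <- ds$segments
  per_segment <- purrr::map_dfr(unique(segs$segment), function(s) {
    sl <- segs[segs$segment == s, ]
    trl <- split(sl[, c("time", "f")], sl$trial)
    sm <- shift_and_mean(trl, ds$ref$peak_time, 8)
    area <- tryCatch(vsd_ap_area(sm), error = function(e) NA_real_)
    tibble::tibble(segment = s, path_mid = sl$path_mid[1],
                   vsd_area = area,
                   eff_khz = attr(sm, "effective_rate_khz"))
  })
  grid <- discretize(morph, 1, ra = passive$ra)
  per_segment$diameter <- vapply(per_segment$path_mid, function(p)
    grid$diameter[which.min(abs(grid$path_pos - p))], numeric(1))
  ok <- stats::complete.cases(per_segment[, c("vsd_area", "diameter")])
  summary <- tibble::tibble(
    cor_area_diam = stats::cor(per_segment$vsd_area[ok],
                               per_segment$diameter[ok]),
    mean_eff_khz = mean(per_segment$eff_khz, na.rm = TRUE),
    n_segments = sum(ok), n_trials = max(segs$trial),
    compensated = compensated)
  list(summary = summary, tables = list(per_segment = per_segment),
       dataset_ref = ds$ref)
}

#' Console digest of an experiment report
#'
#' Prints the headline statistics of a report with their definitions
#' (`rel_range` is `(max - min)/mean`; `cv` is the population SD over the
#' mean).
#'
#' @param report An `axon_experiment`.
#' @return The summary tibble, invisibly.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "axon_experiment"))
  cat(sprintf("Experiment: %s (seed %d)\n", report$name, report$seed))
  cat("definitions: rel_range = (max - min)/mean; cv = population sd/mean\n")
  print(as.data.frame(report$summary), digits = 4, row.names = FALSE)
  invisible(report$summary)
}

#' @export
print.axon_experiment <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
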