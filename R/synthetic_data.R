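#' Generator specification for synthetic study data
#'
#' One object holds every tunable of the synthetic-data generators, so that
#' each generated dataset is a pure function of `(spec, seed)`. Defaults
#' describe a mossy-fiber-like varicose axon: a 400 um unbranched shaft of
#' 0.3 um diameter carrying en passant boutons with log-normally distributed
#' diameters (mode near 1 um, clipped to 0.5-4 um) and one giant bouton,
#' all diameters within the 0.1-5 um range typical of unmyelinated axons.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param axon_length_um Total axon length.
#' @param shaft_diam_um Inter-bouton shaft diameter.
#' @param n_boutons Number of boutons (including the giant one).
#' @param bouton_meanlog,bouton_sdlog Log-normal parameters of small-bouton
#'   diameters (um).
#' @param bouton_diam_range Clipping range for small-bouton diameters, um.
#' @param giant_diam_um Diameter of the giant bouton (2-5 um).
#' @param min_spacing_um Minimum bouton center spacing.
#' @param margin_um Bouton-free margin at both axon ends.
#' @param node_spacing_um Morphology node spacing.
#' @param noise_sd_nA Current noise SD for synthetic recordings.
#' @param headstage_khz One-pole low-pass corner of the recording noise.
#' @param vsd Named list of VSD render parameters: `f0` (baseline counts),
#'   `sensitivity` (fractional signal per 100 mV), `bleach_tau_ms`
#'   (length 2), `bleach_frac` (length 2 amplitude fractions), `shot_scale`,
#'   `read_noise`, `frame_khz`, `px_um`, `nx`, `ny`.
#' @param n_trials Trial count for VSD datasets.
#' @param jitter_sd_ms Gaussian spike-detection jitter of the electrical
#'   reference (SD, ms) added to the uniform frame-phase jitter.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1, axon_length_um = 400,
                           shaft_diam_um = 0.3, n_boutons = 15,
                           bouton_meanlog = log(1.0), bouton_sdlog = 0.45,
                           bouton_diam_range = c(0.5, 4),
                           giant_diam_um = 3.5, min_spacing_um = 18,
                           margin_um = 40, node_spacing_um = 0.5,
                           noise_sd_nA = 0.005, headstage_khz = 10,
                           vsd = list(), n_trials = 20,
                           jitter_sd_ms = 0.004) {
  vsd_defaults <- list(f0 = 2000, sensitivity = 0.08,
                       bleach_tau_ms = c(50, 500),
                       bleach_frac = c(0.05, 0.15), shot_scale = 0.5,
                       read_noise = 2, frame_khz = 10, px_um = 0.79,
                       nx = 64, ny = 46)
  vsd <- utils::modifyList(vsd_defaults, vsd)
  stopifnot(axon_length_um > 0, shaft_diam_um > 0, n_boutons >= 1,
            giant_diam_um >= 2, giant_diam_um <= 5)
  structure(list(seed = seed, axon_length_um = axon_length_um,
                 shaft_diam_um = shaft_diam_um, n_boutons = n_boutons,
                 bouton_meanlog = bouton_meanlog,
                 bouton_sdlog = bouton_sdlog,
                 bouton_diam_range = bouton_diam_range,
                 giant_diam_um = giant_diam_um,
                 min_spacing_um = min_spacing_um, margin_um = margin_um,
                 node_spacing_um = node_spacing_um,
                 noise_sd_nA = noise_sd_nA, headstage_khz = headstage_khz,
                 vsd = vsd, n_trials = n_trials,
                 jitter_sd_ms = jitter_sd_ms),
            class = "generator_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_bouton_positions <- function(spec) {
  lo <- spec$margin_um
  hi <- spec$axon_length_um - spec$margin_um
  n <- spec$n_boutons
  if (n == 1) return(runif(1, lo, hi))
  # jittered regular grid: guarantees the minimum spacing whenever the
  # span can hold n boutons at all
  base <- seq(lo, hi, length.out = n)
  gap <- base[2] - base[1]
  if (gap < spec$min_spacing_um) {
    abort("axon too short for the requested bouton count and spacing")
  }
  jit <- runif(n, -1, 1) * (gap - spec$min_spacing_um) / 2
  base + jit
}

#' Generate a synthetic varicose axon
#'
#' Builds an unbranched axon whose diameter profile is the shaft diameter
#' plus Gaussian bumps at the bouton positions (bump SD a quarter of the
#' bouton diameter, so varicosities rise and fall over about one bouton
#' diameter), with one giant bouton. Nodes whose diameter exceeds 1.5x the
#' shaft are labelled `"bouton"`.
#'
#' @param spec A [generator_spec()].
#' @return An [morphology()] object.
#' @export
make_axon <- function(spec = generator_spec()) {
  with_seed(spec$seed, {
    pos <- draw_bouton_positions(spec)
    d <- rlnorm(spec$n_boutons, spec$bouton_meanlog, spec$bouton_sdlog)
    d <- pmin(pmax(d, spec$bouton_diam_range[1]), spec$bouton_diam_range[2])
    d[sample.int(spec$n_boutons, 1)] <- spec$giant_diam_um
    x <- seq(0, spec$axon_length_um, by = spec$node_spacing_um)
    prof <- rep(spec$shaft_diam_um, length(x))
    for (b in seq_along(pos)) {
      # steep neck: bump SD a quarter of the bouton diameter, floored so
      # sub-micron boutons still span a few nodes
      w <- max(d[b] / 4, 0.4)
      prof <- prof + (d[b] - spec$shaft_diam_um) *
        exp(-(x - pos[b])^2 / (2 * w^2))
    }
    prof <- pmin(prof, 5)
    label <- ifelse(prof > 1.5 * spec$shaft_diam_um, "bouton", "axon")
    nodes <- tibble::tibble(
      id = seq_along(x),
      parent_id = c(NA_integer_, seq_along(x)[-length(x)]),
      x = x, y = 0, z = 0, radius = prof / 2, label = label)
    morphology(nodes, metadata = list(generator = "make_axon",
                                      seed = spec$seed,
                                      bouton_pos = pos, bouton_diam = d))
  })
}

#' Closed-form two-compartment seal-test transient
#'
#' Analytic pipette current of a voltage step applied through an access
#' resistance to a two-compartment equivalent circuit (local membrane
#' `c_local`/`r_local` coupled through `r_coupling` to a remote compartment
#' `c_remote`/`r_remote`), the circuit behind the local-capacitance probe.
#' The 2x2 linear system is solved by eigen-decomposition, so the trace is
#' an exact biexponential plus offset. Defaults describe a bouton-like
#' structure patched through a high access resistance on a thin axon: the
#' local membrane resistance matches 50 kOhm cm^2 for the local area implied
#' by `c_local_pf` at 1 uF/cm^2, and the remote axon couples through a
#' GOhm-scale axial path as expected for sub-micron calibers.
#'
#' @param t Time grid, ms (step at t = 0).
#' @param dv Step amplitude, mV (default -20: -70 to -90).
#' @param access_mohm Access resistance, MOhm.
#' @param c_local_pf,c_remote_pf Compartment capacitances, pF.
#' @param r_local_mohm,r_remote_mohm Membrane (leak) resistances, MOhm.
#' @param r_coupling_mohm Axial coupling resistance, MOhm.
#' @return A tibble with `time` (ms) and `current` (nA), zero before the
#'   step; attributes `taus_ms` and `amps_na` hold the exact components
#'   (fast first, amplitudes at step onset) and `i_ss` the steady state.
#' @export
two_compartment_transient <- function(t, dv = -20, access_mohm = 150,
                                      c_local_pf = 2, r_local_mohm = 25000,
                                      c_remote_pf = 1.5,
                                      r_remote_mohm = 30000,
                                      r_coupling_mohm = 1500) {
  rs <- access_mohm
  c1 <- c_local_pf * 1e-3; c2 <- c_remote_pf * 1e-3  # nF
  g1 <- 1 / r_local_mohm; g2 <- 1 / r_remote_mohm    # uS
  gx <- 1 / r_coupling_mohm; gs <- 1 / rs
  # states: v1 (local), v2 (remote), relative to holding; pipette at dv
  # c1 v1' = gs(dv - v1) - g1 v1 + gx(v2 - v1)
  # c2 v2' = gx(v1 - v2) - g2 v2
  A <- matrix(c(-(gs + g1 + gx) / c1, gx / c1,
                gx / c2, -(gx + g2) / c2), 2, 2, byrow = TRUE)
  b <- c(gs * dv / c1, 0)
  vss <- solve(A, -b)
  eg <- eigen(A)
  lam <- eg$values; U <- eg$vectors
  coef0 <- solve(U, -vss)                 # v(0) = 0
  # pipette current i(t) = gs*(dv - v1(t)) in nA
  v1 <- function(tt) {
    vss[1] + Re(U[1, 1] * coef0[1] * exp(lam[1] * tt) +
                U[1, 2] * coef0[2] * exp(lam[2] * tt))
  }
  cur <- ifelse(t < 0, 0, gs * (dv - v1(pmax(t, 0))))
  # exact exponential components of i(t): -gs * U[1,j] coef0[j] e^{lam t}
  amps <- -gs * Re(U[1, ] * coef0)
  taus <- -1 / Re(lam)
  ord <- order(taus)
  out <- tibble::tibble(time = t, current = cur)
  structure(out, taus_ms = taus[ord], amps_na = amps[ord],
            i_ss = gs * (dv - vss[1]), dv = dv,
            class = c("tbl_df", "tbl", "data.frame"))
}

#' Synthetic seal-test recording with instrument-like noise
#'
#' Adds white Gaussian current noise shaped by a one-pole headstage
#' low-pass to a clean transient, emulating the recorded trace.
#'
#' @param clean A tibble with `time` and `current` (e.g. from
#'   [two_compartment_transient()]).
#' @param noise_sd Noise SD in nA, measured at the output of the filter.
#' @param headstage_khz One-pole corner frequency, kHz.
#' @param seed Integer seed.
#' @return The input tibble with a `current` column containing noise.
#' @export
add_recording_noise <- function(clean, noise_sd = 0.01, headstage_khz = 10,
                                seed = 1) {
  dt <- clean$time[2] - clean$time[1]
  with_seed(seed, {
    w <- rnorm(nrow(clean))
    a <- exp(-2 * pi * headstage_khz * dt)
    f <- stats::filter(w, a, method = "recursive")
    f <- as.numeric(f) / stats::sd(f) * noise_sd
    out <- clean
    out$current <- clean$current + f
    out
  })
}

#' Render a synthetic VSD dataset from a simulated axon
#'
#' Simulates one propagating AP on the morphology, lays a stretch of the
#' axon along the middle row of a camera image, and renders per-trial
#' fluorescence stacks with the linear dye model
#' `F(t) = F0 * bleach(t) * (1 + s * (V(t) - V_rest)/100 mV)` plus shot and
#' read noise. Trials share the same underlying voltage but differ in the
#' frame-clock phase (uniform within one frame period) and in noise; each
#' trial carries a 250 kHz electrical reference peak time with Gaussian
#' detection jitter.
#'
#' @param spec A [generator_spec()]; `spec$vsd` holds the render
#'   parameters and `spec$n_trials`/`spec$jitter_sd_ms` the trial
#'   structure.
#' @param morph Optional [morphology()]; defaults to `make_axon(spec)`.
#' @param window_um Path window imaged, um (defaults to a camera-width
#'   stretch centered on the axon midpoint).
#' @param duration_ms Rendered duration per trial (default 30).
#' @param densities,mixture,passive Membrane model for the underlying
#'   simulation.
#' @param keep_stacks How many full per-trial stacks to keep (default 2;
#'   segment traces are kept for every trial).
#' @return A list: `stacks` (first `keep_stacks` [vsd_stack()]s),
#'   `segments` (tibble: trial, segment, path_mid, time, f),
#'   `ref` (tibble: trial, peak_time — the jittered electrical reference),
#'   `truth` (list with the noiseless high-rate voltage waveform per
#'   segment and the true AP peak time), and `mask` (the pixel tibble).
#' @export
make_vsd_dataset <- function(spec = generator_spec(), morph = NULL,
                             window_um = NULL, duration_ms = 30,
                             densities = active_densities(),
                             mixture = NULL,
                             passive = passive_params(),
                             keep_stacks = 2) {
  if (is.null(morph)) morph <- make_axon(spec)
  vp <- spec$vsd
  grid <- discretize(morph, 1)
  total <- max(grid$path_pos)
  img_w <- vp$nx * vp$px_um
  if (is.null(window_um)) {
    window_um <- c(total / 2 - img_w / 2, total / 2 + img_w / 2)
  }
  # high-rate simulation of one AP
  cfg <- sim_config(duration = duration_ms, settle_ms = 20, dt = 0.004,
                    record_species = character(0),
                    stimuli = list(stim_current_step(2, 0.15, 1, 1)))
  sim <- simulate_cable(grid, passive, densities, mixture, cfg)
  v_rest <- sim$v[1, 1]
  # pixel map: axon along image row y0, one pixel thick
  y0 <- ceiling(vp$ny / 2)
  cols <- seq_len(vp$nx)
  col_path <- window_um[1] + (cols - 0.5) * vp$px_um
  comp_of_col <- vapply(col_path, function(p)
    which.min(abs(grid$path_pos - p)), integer(1))
  pixels <- tidyr::expand_grid(x = seq_len(vp$nx), y = seq_len(vp$ny))
  pixels$px <- seq_len(nrow(pixels))
  pixels$path_pos <- NA_real_
  on_ax <- pixels$y == y0
  pixels$path_pos[on_ax] <- col_path[pixels$x[on_ax]]
  # baseline brightness: membrane area in the pixel for axon pixels,
  # faint background elsewhere
  f0 <- rep(vp$f0 * 0.05, nrow(pixels))
  ax_area <- grid$area[comp_of_col] / max(grid$area[comp_of_col])
  f0[on_ax] <- vp$f0 * (0.3 + 0.7 * ax_area[pixels$x[on_ax]])
  # per-frame voltage factor for each axon column
  frame_period <- 1 / vp$frame_khz
  n_frames <- floor(duration_ms / frame_period)
  v_at <- function(tq) {
    # sim$time is uniform; linear interpolation per column
    vapply(seq_along(comp_of_col), function(j) {
      stats::approx(sim$time, sim$v[, comp_of_col[j]], tq, rule = 2)$y
    }, numeric(length(tq)))
  }
  true_peak <- sim$time[which.max(sim$v[, comp_of_col[1]])]
  bleach <- function(tq) {
    1 - vp$bleach_frac[1] * (1 - exp(-tq / vp$bleach_tau_ms[1])) -
      vp$bleach_frac[2] * (1 - exp(-tq / vp$bleach_tau_ms[2]))
  }
  with_seed(spec$seed + 1000L, {
    stacks <- list()
    seg_rows <- list()
    refs <- numeric(spec$n_trials)
    for (tr in seq_len(spec$n_trials)) {
      phase <- runif(1, 0, frame_period)
      ft <- phase + (seq_len(n_frames) - 1) * frame_period
      vmat <- v_at(ft)                         # frames x columns
      if (is.null(dim(vmat))) vmat <- matrix(vmat, nrow = length(ft))
      frames <- matrix(rep(f0, each = n_frames), nrow = n_frames)
      bl <- bleach(ft)
      sig <- 1 + vp$sensitivity * (vmat - v_rest) / 100
      ax_cols_px <- pixels$px[on_ax][order(pixels$x[on_ax])]
      frames[, ax_cols_px] <- frames[, ax_cols_px] * sig
      frames <- frames * bl
      frames <- frames +
        vp$shot_scale * sqrt(pmax(frames, 0)) *
          matrix(rnorm(length(frames)), nrow = n_frames) +
        vp$read_noise * matrix(rnorm(length(frames)), nrow = n_frames)
      frames <- pmax(frames, 0)
      st <- vsd_stack(frames, pixels, frame_khz = vp$frame_khz,
                      px_um = vp$px_um, events = true_peak - phase)
      # frame clock starts at `phase`: stack time 0 is the first frame, so
      # events are expressed on the frame clock
      if (tr <= keep_stacks) stacks[[tr]] <- st
      segs <- segment_average(st)
      segs$trial <- tr
      seg_rows[[tr]] <- segs
      refs[tr] <- (true_peak - phase) + rnorm(1, 0, spec$jitter_sd_ms)
    }
    truth_seg <- {
      # noiseless normalized fluorescence at 250 kHz for the middle column
      tq <- seq(0, duration_ms, by = 0.004)
      vs <- stats::approx(sim$time,
                          sim$v[, comp_of_col[ceiling(length(cols) / 2)]],
                          tq, rule = 2)$y
      tibble::tibble(time = tq, v = vs,
                     f = 1 + spec$vsd$sensitivity * (vs - v_rest) / 100)
    }
    list(stacks = stacks,
         segments = dplyr::bind_rows(seg_rows),
         ref = tibble::tibble(trial = seq_len(spec$n_trials),
                              peak_time = refs),
         truth = list(waveform = truth_seg, peak_time = true_peak,
                      v_rest = v_rest, sim = sim,
                      comp_of_col = comp_of_col),
         mask = pixels)
  })
}

#' Synthetic recordings for the probe and instrument pipelines
#'
#' Runs the requested protocol on a morphology through the cable solver
#' (optionally through the pipette/amplifier forward model) and returns
#' paired clean and noisy traces.
#'
#' @param spec A [generator_spec()].
#' @param morph An [morphology()] (defaults to `make_axon(spec)`).
#' @param protocol One of `"seal_test"`, `"single_ap"`, `"ap_train"`,
#'   `"ina_ik"`.
#' @param site_um Recording/stimulation site, um.
#' @param instrument Optional [pipette_amplifier()] applied to current-clamp
#'   protocols.
#' @param ... Passed to the underlying protocol function.
#' @return A list with `clean` and `noisy` waveform tibbles plus
#'   protocol-specific extras.
#' @export
make_recording <- function(spec = generator_spec(), morph = NULL,
                           protocol = c("seal_test", "single_ap",
                                        "ap_train", "ina_ik"),
                           site_um = NULL, instrument = NULL, ...) {
  protocol <- match.arg(protocol)
  if (is.null(morph)) morph <- make_axon(spec)
  grid <- discretize(morph, 1)
  if (is.null(site_um)) site_um <- max(grid$path_pos) / 2
  if (protocol == "seal_test") {
    vc <- voltage_clamp(grid, config = sim_config(duration = 120,
                                                  settle_ms = 5,
                                                  dt = 0.004,
                                                  record_species = "leak"),
                        site_um = site_um, access_mohm = 300, ...)
    clean <- tibble::tibble(time = vc$time, current = vc$i_clamp)
    noisy <- add_recording_noise(clean, spec$noise_sd_nA,
                                 spec$headstage_khz, spec$seed)
    return(list(clean = clean, noisy = noisy, sim = vc))
  }
  if (protocol == "single_ap") {
    cfg <- sim_config(duration = 12, settle_ms = 20, dt = 0.004,
                      record_species = character(0),
                      stimuli = list(stim_current_step(site_um, 0.3, 1, 3)))
    if (!is.null(instrument)) {
      rec <- forward_record(grid, instrument, site_um = site_um,
                            config = cfg, ...)
      clean <- tibble::tibble(time = rec$time, v = rec$v_amp)
    } else {
      sim <- simulate_cable(grid, config = cfg, ...)
      w <- sim_waveform(sim, site_um)
      clean <- tibble::tibble(time = w$time, v = w$v)
    }
    noisy <- clean
    with_seed(spec$seed,
              noisy$v <- noisy$v + rnorm(nrow(noisy), 0, 0.2))
    return(list(clean = clean, noisy = noisy))
  }
  if (protocol == "ap_train") {
    tr <- train_protocol(grid, site_um = site_um, ...)
    det <- sim_waveform(tr, site_um)
    clean <- tibble::tibble(time = det$time, v = det$v)
    noisy <- clean
    with_seed(spec$seed,
              noisy$v <- noisy$v + rnorm(nrow(noisy), 0, 0.2))
    return(list(clean = clean, noisy = noisy, sim = tr))
  }
  # ina_ik: single-compartment outside-out patch protocol
  res <- ina_ik_protocol(...)
  res
}
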