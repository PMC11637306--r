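#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a multi-exponential transient fit
#'
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @return A tibble with one row per exponential component (`term`,
#'   `amplitude_na`, `tau_ms`) plus the shared offset.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = paste0("exp", seq_len(x$n_exp)),
                 amplitude_na = x$amps, tau_ms = x$taus,
                 offset_na = x$offset)
}

#' @rdname tidy.exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_exp = x$n_exp, sse = x$sse,
                 window_start = x$window[1], window_end = x$window[2])
}

#' Tidy a conductance fit
#'
#' @param x A `conductance_fit`.
#' @param ... Unused.
#' @return One row per optimized parameter with the averaged estimate and
#'   the spread across starts.
#' @export
tidy.conductance_fit <- function(x, ...) {
  ps <- x$per_start[, c("g_na", "g_k", "vshift", "rate_scale_na",
                        "rate_scale_k")]
  tibble::tibble(term = names(ps),
                 estimate = unname(x$params[names(ps)]),
                 sd_across_starts = vapply(ps, stats::sd, numeric(1)))
}

#' @rdname tidy.conductance_fit
#' @export
glance.conductance_fit <- function(x, ...) {
  tibble::tibble(n_optimizations = nrow(x$per_start),
                 mean_rms_mv = x$rms_mv,
                 best_rms_mv = min(x$per_start$rms_mv))
}

#' Tidy an experiment report
#'
#' @param x An `axon_experiment`.
#' @param ... Unused.
#' @return The long form of the report summary (`statistic`, `value`).
#' @export
tidy.axon_experiment <- function(x, ...) {
  s <- x$summary
  tibble::tibble(statistic = names(s),
                 value = vapply(s, function(v)
                   if (is.numeric(v)) as.numeric(v) else as.numeric(NA),
                   numeric(1)))
}

#' @rdname tidy.axon_experiment
#' @export
glance.axon_experiment <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(name = x$name, seed = x$seed), x$summary)
}

#' Voltage traces of a simulation as a long tibble
#'
#' @param sim An `axon_sim`.
#' @param sites_um Path positions to extract (default: five evenly spaced
#'   positions).
#' @return A tibble with `path_pos`, `time`, `v`.
#' @export
sim_traces <- function(sim, sites_um = NULL) {
  if (is.null(sites_um)) {
    rng <- range(sim$grid$path_pos[sim$v_idx])
    sites_um <- seq(rng[1] + 0.05 * diff(rng), rng[2] - 0.05 * diff(rng),
                    length.out = 5)
  }
  purrr::map_dfr(sites_um, function(p) {
    idx <- which.min(abs(sim$grid$path_pos[sim$v_idx] - p))
    tibble::tibble(path_pos = sim$grid$path_pos[sim$v_idx][idx],
                   time = sim$time, v = sim$v[, idx])
  })
}

#' Plot voltage traces along the axon
#'
#' @param object An `axon_sim`.
#' @param sites_um Positions to plot (see [sim_traces()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.axon_sim <- function(object, sites_um = NULL, ...) {
  df <- sim_traces(object, sites_um)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$v,
                                   colour = factor(round(.data$path_pos)))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)",
                  colour = "path (um)") +
    ggplot2::theme_minimal()
}

#' Plot a morphology diameter profile
#'
#' @param object An `axon_morphology`.
#' @param ... Unused.
#' @return A ggplot of diameter against path position.
#' @export
autoplot.axon_morphology <- function(object, ...) {
  grid <- discretize(object, 1)
  ggplot2::ggplot(grid, ggplot2::aes(.data$path_pos, .data$diameter)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "path position (um)", y = "diameter (um)") +
    ggplot2::theme_minimal()
}

#' Plot an influx profile along the axon
#'
#' @param object An `influx_profile`.
#' @param ... Unused.
#' @return A ggplot of influx density against path position.
#' @export
autoplot.influx_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$path_pos,
                                       .data$influx_fc_um2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "path position (um)",
                  y = "Ca influx density (fC/um^2)") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' For AP experiments, repolarization area against local capacitance per
#' compartment (boutons highlighted); for the VSD experiment, the
#' per-segment VSD AP area against diameter.
#'
#' @param object An `axon_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.axon_experiment <- function(object, ...) {
  if (!is.null(object$tables$per_comp)) {
    pc <- object$tables$per_comp
    ycol <- intersect(c("repol_area", "ra_dtx"), names(pc))[1]
    if (is.na(ycol)) abort("no area column in the per-compartment table")
    if (!"bouton_id" %in% names(pc)) pc$bouton_id <- NA_integer_
    return(
      ggplot2::ggplot(pc, ggplot2::aes(.data$capacitance_pf,
                                       .data[[ycol]],
                                       colour = !is.na(.data$bouton_id))) +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                             se = FALSE, colour = "black") +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "local capacitance (pF)",
                      y = "repolarization area (mV ms)",
                      colour = "bouton") +
        ggplot2::theme_minimal())
  }
  if (!is.null(object$tables$per_segment)) {
    ps <- object$tables$per_segment
    return(
      ggplot2::ggplot(ps, ggplot2::aes(.data$diameter, .data$vsd_area)) +
        ggplot2::geom_point() +
        ggplot2::labs(x = "segment diameter (um)",
                      y = "VSD AP area (normalized ms)") +
        ggplot2::theme_minimal())
  }
  abort("no plottable table in this report")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write simulation traces to CSV
#'
#' Columnar export: time plus one named column per recorded compartment.
#'
#' @param sim An `axon_sim`.
#' @param path Output CSV path.
#' @param what `"v"` (default) or one of the recorded current species.
#' @return The path, invisibly.
#' @export
write_sim_csv <- function(sim, path, what = "v") {
  m <- switch(what, v = sim$v, i_na = sim$i_na, i_k = sim$i_k,
              i_ca = sim$i_ca, i_leak = sim$i_leak,
              abort("unknown trace kind"))
  idx <- if (what == "v") sim$v_idx else sim$i_idx
  df <- data.frame(time = sim$time, m)
  names(df) <- c("time", sprintf("%s_um%.1f", what,
                                 sim$grid$path_pos[idx]))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
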