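#' Integrate calcium influx per compartment
#'
#' Trapezoid time-integral of the inward calcium current over the analysis
#' window. Influx is reported as positive inward charge: per unit membrane
#' in fC/um^2 and, where bouton labels are available, per bouton in fC.
#'
#' @param sim An `axon_sim` result that recorded `i_ca`.
#' @param window `c(t0, t1)` integration window in ms; defaults to AP onset
#'   at the recording site to onset + 5 ms when `NULL`, or the full trace.
#' @return A tibble of class `influx_profile`: one row per recorded
#'   compartment with `index`, `path_pos`, `diameter`, `area`,
#'   `capacitance_pf`, `influx_fc_um2`, `influx_fc`, `bouton_id` (if
#'   present in the grid).
#' @export
integrate_influx <- function(sim, window = NULL) {
  if (is.null(sim$i_ca) || ncol(sim$i_ca) == 0) {
    abort("simulation did not record i_ca")
  }
  t <- sim$time
  if (is.null(window)) window <- range(t)
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
    abort("influx window outside the simulated time range")
  }
  sel <- t >= window[1] & t <= window[2]
  idx <- sim$i_idx
  area <- sim$grid$area[idx]
  # i_ca is in nA (inward negative); integrate the inward part
  inward <- pmax(-sim$i_ca[sel, , drop = FALSE], 0)
  q_nA_ms <- apply(inward, 2, function(y) trapz(t[sel], y))
  q_fc <- q_nA_ms * 1000          # 1 nA*ms = 1e-12 C = 1000 fC
  out <- tibble::tibble(
    index = idx,
    path_pos = sim$grid$path_pos[idx],
    diameter = sim$grid$diameter[idx],
    area = area,
    capacitance_pf = sim$grid$area[idx] * 0.01,
    influx_fc = q_fc,
    influx_fc_um2 = q_fc / area
  )
  if ("bouton_id" %in% names(sim$grid)) {
    out$bouton_id <- sim$grid$bouton_id[idx]
  }
  structure(out, window = window,
            class = c("influx_profile", class(tibble::tibble())))
}

#' Per-bouton influx totals
#'
#' @param influx An [integrate_influx()] result with `bouton_id`.
#' @return A tibble with one row per bouton: total influx (fC), geometry,
#'   and capacitance.
#' @export
bouton_influx <- function(influx) {
  stopifnot("bouton_id" %in% names(influx))
  influx %>%
    dplyr::filter(!is.na(.data$bouton_id)) %>%
    dplyr::group_by(.data$bouton_id) %>%
    dplyr::summarise(
      path_pos = mean(.data$path_pos),
      diameter = max(.data$diameter),
      capacitance_pf = sum(.data$capacitance_pf),
      influx_fc = sum(.data$influx_fc),
      .groups = "drop")
}

#' Power-law release from calcium influx
#'
#' Relative synaptic release is computed as influx raised to a cooperative
#' power (default 2.5) and normalized to the profile mean.
#'
#' @param influx A numeric vector of non-negative influx values, or a
#'   tibble with an `influx_fc` column (e.g. from [bouton_influx()]).
#' @param power Cooperativity exponent (default 2.5).
#' @return If `influx` is a vector, a numeric vector of mean-normalized
#'   release; otherwise the input tibble with a `release` column added.
#' @export
release_from_influx <- function(influx, power = 2.5) {
  vec <- if (is.data.frame(influx)) influx$influx_fc else influx
  if (any(vec < 0)) abort("influx must be non-negative")
  rel <- vec^power
  m <- mean(rel)
  rel <- if (m > 0) rel / m else rel
  if (is.data.frame(influx)) {
    influx$release <- rel
    influx
  } else {
    rel
  }
}

#' Spread statistics of a release (or influx) profile
#'
#' @param x A numeric vector, or a tibble with a `release` column.
#' @return A one-row tibble with `cv` (population SD over mean) and
#'   `rel_range` (`(max - min)/mean`).
#' @export
variability_summary <- function(x) {
  vec <- if (is.data.frame(x)) x$release else x
  if (length(vec) < 2) abort("need at least two boutons")
  m <- mean(vec)
  pop_sd <- sqrt(mean((vec - m)^2))
  tibble::tibble(cv = pop_sd / m, rel_range = (max(vec) - min(vec)) / m)
}
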