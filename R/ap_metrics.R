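#' AP waveform container
#'
#' A uniformly sampled single-AP waveform: a tibble with `time` (ms) and
#' `v` (mV, or normalized fluorescence for imaging waveforms).
#'
#' @param x A data frame with columns `time` and `v`.
#' @param source One of `"ephys"`, `"sim"`, `"vsd"`.
#' @return A tibble of class `ap_waveform`.
#' @export
as_ap_waveform <- function(x, source = "ephys") {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("time", "v") %in% names(x)), nrow(x) >= 3)
  dts <- diff(x$time)
  if (diff(range(dts)) > 1e-6 * stats::median(dts)) {
    abort("ap_waveform requires uniform sampling")
  }
  structure(x, source = source,
            class = c("ap_waveform", class(tibble::tibble())))
}

wave_dt <- function(wave) wave$time[2] - wave$time[1]

# linearly interpolated crossing time of y through level between i and i+1
cross_time <- function(t, y, i, level) {
  f <- (level - y[i]) / (y[i + 1] - y[i])
  t[i] + f * (t[i + 1] - t[i])
}

#' Detect AP onset by upstroke velocity
#'
#' The onset is the first point before the peak where dV/dt (central
#' differences) crosses `slope_threshold`; time and voltage are refined by
#' linear sub-sample interpolation of the crossing.
#'
#' @param wave An [as_ap_waveform()] object.
#' @param slope_threshold Upstroke velocity threshold, mV/ms (default 100).
#' @return A list with `time` (ms), `voltage` (mV), and `peak_index`.
#' @export
detect_onset <- function(wave, slope_threshold = 100) {
  t <- wave$time; v <- wave$v
  n <- length(v)
  dvdt <- c(NA, (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
  ipk <- which.max(v)
  pre <- which(dvdt[seq_len(ipk)] >= slope_threshold)
  if (length(pre) == 0) {
    abort("no upstroke reaches the slope threshold: not an AP",
          class = "axonwave_not_an_ap")
  }
  i <- pre[1]
  if (i > 1 && is.finite(dvdt[i - 1]) && dvdt[i] > dvdt[i - 1]) {
    f <- (slope_threshold - dvdt[i - 1]) / (dvdt[i] - dvdt[i - 1])
    t_on <- t[i - 1] + f * (t[i] - t[i - 1])
    v_on <- v[i - 1] + f * (v[i] - v[i - 1])
  } else {
    t_on <- t[i]; v_on <- v[i]
  }
  list(time = t_on, voltage = v_on, peak_index = ipk)
}

# index range + fractional end handling for the onset-to-return window
return_to_level <- function(t, v, ipk, level) {
  n <- length(v)
  post <- seq(ipk, n)
  below <- which(v[post] <= level)
  if (length(below) == 0) return(list(idx_end = n, t_end = t[n],
                                      truncated = TRUE))
  j <- post[below[1]]
  if (j == ipk) return(list(idx_end = j, t_end = t[j], truncated = FALSE))
  list(idx_end = j, t_end = cross_time(t, v, j - 1, level),
       truncated = FALSE)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# integral of (v - level) from t_start to t_end with sub-sample ends
integrate_above <- function(t, v, t_start, t_end, level) {
  vv <- v - level
  inside <- which(t > t_start & t < t_end)
  xs <- c(t_start, t[inside], t_end)
  ys <- c(stats::approx(t, vv, t_start)$y, vv[inside],
          stats::approx(t, vv, t_end)$y)
  trapz(xs, ys)
}

#' AP area from onset to return
#'
#' Trapezoid integral of `(v - onset voltage)` from the detected onset to
#' the first post-peak return of the membrane potential to the onset
#' voltage, with sub-sample interpolation of both ends.
#'
#' @param wave An [as_ap_waveform()] object.
#' @param onset Optional result of [detect_onset()]; computed when absent.
#' @param slope_threshold Passed to [detect_onset()].
#' @return Area in mV ms.
#' @export
ap_area <- function(wave, onset = NULL, slope_threshold = 100) {
  if (is.null(onset)) onset <- detect_onset(wave, slope_threshold)
  ret <- return_to_level(wave$time, wave$v, onset$peak_index, onset$voltage)
  integrate_above(wave$time, wave$v, onset$time, ret$t_end, onset$voltage)
}

#' Repolarization-phase AP area
#'
#' Integral of `(v - reference)` from the AP peak to the first return to
#' the reference level. The reference is the onset voltage for electrical
#' waveforms and the pre-peak baseline for imaging waveforms.
#'
#' @inheritParams ap_area
#' @param reference Optional reference level, mV; defaults to the onset
#'   voltage (ephys/sim sources) or the baseline (vsd source).
#' @return Area in mV ms (or normalized-fluorescence ms).
#' @export
repol_area <- function(wave, reference = NULL, slope_threshold = 100) {
  ipk <- which.max(wave$v)
  if (is.null(reference)) {
    if (identical(attr(wave, "source"), "vsd")) {
      reference <- stats::median(wave$v[seq_len(max(1, ipk - 5))])
    } else {
      reference <- detect_onset(wave, slope_threshold)$voltage
    }
  }
  ret <- return_to_level(wave$time, wave$v, ipk, reference)
  integrate_above(wave$time, wave$v, wave$time[ipk], ret$t_end, reference)
}

#' Width of the AP at a fixed voltage level
#'
#' Time between the sub-sample-interpolated up- and down-crossings of
#' `level` flanking the peak.
#'
#' @param wave An [as_ap_waveform()] object.
#' @param level Voltage level, mV (default -20).
#' @return Width in ms.
#' @export
width_at_level <- function(wave, level = -20) {
  t <- wave$time; v <- wave$v
  ipk <- which.max(v)
  if (v[ipk] <= level) {
    abort("AP peak below the requested level: width undefined",
          class = "axonwave_undefined_width")
  }
  pre <- which(v[seq_len(ipk)] < level)
  post <- which(v[seq(ipk, length(v))] < level)
  if (length(pre) == 0 || length(post) == 0) {
    abort("trace does not cross the level on both sides of the peak",
          class = "axonwave_undefined_width")
  }
  i_up <- pre[length(pre)]
  t_up <- cross_time(t, v, i_up, level)
  i_dn <- ipk + post[1] - 2L
  t_dn <- cross_time(t, v, i_dn, level)
  t_dn - t_up
}

#' AP half-width
#'
#' Width at 50% of the onset-to-peak amplitude.
#'
#' @inheritParams ap_area
#' @return Half-width in ms.
#' @export
half_width <- function(wave, onset = NULL, slope_threshold = 100) {
  if (is.null(onset)) onset <- detect_onset(wave, slope_threshold)
  level <- onset$voltage + (max(wave$v) - onset$voltage) / 2
  width_at_level(wave, level)
}

#' Train broadening: per-AP half-width ratios
#'
#' @param train_waves A list of [as_ap_waveform()] objects, one per AP in
#'   order of occurrence.
#' @param slope_threshold Passed to [detect_onset()].
#' @return A tibble with `ap_number`, `half_width_ms`, and `ratio` (to the
#'   first AP).
#' @export
broadening <- function(train_waves, slope_threshold = 100) {
  hw <- vapply(train_waves, half_width, numeric(1),
               slope_threshold = slope_threshold)
  tibble::tibble(ap_number = seq_along(hw), half_width_ms = hw,
                 ratio = hw / hw[1])
}

#' All AP metrics of one waveform
#'
#' @inheritParams ap_area
#' @param level Level for [width_at_level()], mV.
#' @return A one-row tibble: onset time/voltage, peak time/amplitude, full
#'   and repolarization-phase areas, half-width, level width, and maximal
#'   rise and decay rates.
#' @export
ap_metrics <- function(wave, slope_threshold = 100, level = -20) {
  on <- detect_onset(wave, slope_threshold)
  t <- wave$time; v <- wave$v; n <- length(v)
  dvdt <- (v[-1] - v[-n]) / (t[-1] - t[-n])
  ipk <- on$peak_index
  wl <- tryCatch(width_at_level(wave, level),
                 axonwave_undefined_width = function(e) NA_real_)
  tibble::tibble(
    onset_time = on$time,
    onset_voltage = on$voltage,
    peak_time = t[ipk],
    amplitude = v[ipk] - on$voltage,
    area = ap_area(wave, on),
    repol_area = repol_area(wave),
    half_width = half_width(wave, on),
    width_at_level = wl,
    max_rise = max(dvdt),
    max_decay = min(dvdt)
  )
}
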