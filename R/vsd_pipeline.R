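#' Voltage-sensitive-dye image stack
#'
#' Container for a VSD movie: a frames-by-pixels fluorescence matrix plus
#' per-pixel geometry (image coordinates, and for axon pixels the path
#' position along the axon), acquisition metadata, and AP event times.
#'
#' @param frames Numeric matrix, `n_frames x n_pixels`, counts >= 0.
#' @param pixels Tibble with one row per pixel: `px` (column index into
#'   `frames`), `x`, `y` (pixel coordinates), `path_pos` (um along the
#'   axon; `NA` off-axon).
#' @param frame_khz Frame rate, kHz (default 10).
#' @param px_um Pixel size, um (default 0.79).
#' @param events AP peak times, ms (frame clock).
#' @return A list of class `vsd_stack`.
#' @export
vsd_stack <- function(frames, pixels, frame_khz = 10, px_um = 0.79,
                      events = numeric(0)) {
  stopifnot(is.matrix(frames), nrow(pixels) == ncol(frames),
            frame_khz > 0, px_um > 0)
  if (any(frames < 0)) abort("fluorescence counts must be non-negative")
  structure(list(frames = frames, pixels = tibble::as_tibble(pixels),
                 frame_khz = frame_khz, px_um = px_um, events = events,
                 time = (seq_len(nrow(frames)) - 1) / frame_khz),
            class = "vsd_stack")
}

#' @export
print.vsd_stack <- function(x, ...) {
  cat(sprintf("<vsd_stack> %d frames x %d px at %g kHz, %d events\n",
              nrow(x$frames), ncol(x$frames), x$frame_khz,
              length(x$events)))
  invisible(x)
}

# frames belonging to AP event windows (logical over frames)
event_frame_mask <- function(stack, pre_ms = 1, post_ms = 3) {
  inwin <- rep(FALSE, length(stack$time))
  for (ev in stack$events) {
    inwin <- inwin | (stack$time >= ev - pre_ms & stack$time <= ev + post_ms)
  }
  inwin
}

# double (or single) exponential + offset fit of a bleach time course
fit_bleach_curve <- function(t, y, n_exp = 2) {
  lin_solve <- function(taus) {
    X <- cbind(1, vapply(taus, function(tau) exp(-t / tau),
                         numeric(length(t))))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    list(cf = cf, sse = sum((y - X %*% cf)^2), taus = taus)
  }
  span <- max(t) - min(t)
  obj <- function(lt) {
    if (any(lt < log(span / 200)) || any(lt > log(span * 100))) return(1e300)
    s <- lin_solve(exp(lt))
    if (is.null(s)) return(1e300)
    s$sse
  }
  st <- if (n_exp == 2) log(c(span / 10, span)) else log(span / 3)
  o <- if (n_exp == 2) {
    stats::optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 500))
  } else {
    list(par = stats::optimize(obj, interval = log(c(span / 200,
                                                     span * 100)))$minimum)
  }
  best <- lin_solve(exp(o$par))
  if (is.null(best)) return(NULL)
  function(tt) {
    X <- cbind(1, vapply(best$taus, function(tau) exp(-tt / tau),
                         numeric(length(tt))))
    as.numeric(X %*% best$cf)
  }
}

#' Photobleaching correction by binned double-exponential fits
#'
#' Pixels are clustered into `n_bins` intensity bins (octiles by mean
#' intensity for the default 8). For each bin a double exponential plus
#' offset is fitted to the bin-mean time course with AP event windows
#' excluded, and each pixel in the bin is divided by the fitted curve
#' normalized to its initial value, so the corrected baseline is flat while
#' each pixel keeps its own brightness. Bins whose double-exponential fit
#' fails fall back to a mono-exponential and are flagged.
#'
#' @param stack A [vsd_stack()].
#' @param n_bins Number of intensity bins (default 8).
#' @param event_pre_ms,event_post_ms Window around each AP event excluded
#'   from the fit.
#' @return The corrected `vsd_stack`; `attr(, "bleach_fallback")` lists
#'   bins that fell back to a mono-exponential.
#' @export
bleach_correct <- function(stack, n_bins = 8, event_pre_ms = 1,
                           event_post_ms = 3) {
  stopifnot(inherits(stack, "vsd_stack"))
  n_event_frames <- sum(event_frame_mask(stack, event_pre_ms, event_post_ms))
  if (length(stack$time) < 10 * max(n_event_frames, 1)) {
    warn("stack is short relative to the AP windows; bleach fit may leak")
  }
  keep <- !event_frame_mask(stack, event_pre_ms, event_post_ms)
  mean_int <- colMeans(stack$frames)
  bins <- cut(rank(mean_int, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  fallback <- integer(0)
  out <- stack$frames
  for (b in seq_len(n_bins)) {
    px <- which(bins == b)
    if (length(px) == 0) next
    trace <- rowMeans(stack$frames[, px, drop = FALSE])
    fitfun <- fit_bleach_curve(stack$time[keep], trace[keep], n_exp = 2)
    if (is.null(fitfun)) {
      fitfun <- fit_bleach_curve(stack$time[keep], trace[keep], n_exp = 1)
      fallback <- c(fallback, b)
    }
    if (is.null(fitfun)) abort(sprintf("bleach fit failed in bin %d", b),
                               class = "axonwave_fit_error")
    curve <- fitfun(stack$time)
    norm <- curve / curve[1]
    norm[norm <= 0] <- 1
    out[, px] <- stack$frames[, px, drop = FALSE] / norm
  }
  res <- stack
  res$frames <- out
  attr(res, "bleach_fallback") <- fallback
  res
}

#' AP-locked activity (dF/F0) map
#'
#' For each pixel, the mean fluorescence within `peak_window_ms` of each AP
#' peak minus the pre-event baseline, divided by that baseline.
#'
#' @param stack A (bleach-corrected) [vsd_stack()] with events.
#' @param peak_window_ms Half-window around AP peaks, ms (default 0.2).
#' @param baseline_gap_ms Time before the first event excluded from the
#'   baseline, ms.
#' @return The `pixels` tibble with a `dff` column added.
#' @export
activity_map <- function(stack, peak_window_ms = 0.2, baseline_gap_ms = 1) {
  stopifnot(inherits(stack, "vsd_stack"))
  if (length(stack$events) == 0) abort("no AP events in the stack")
  peak_sel <- rep(FALSE, length(stack$time))
  for (ev in stack$events) {
    peak_sel <- peak_sel | abs(stack$time - ev) <= peak_window_ms
  }
  base_sel <- stack$time < min(stack$events) - baseline_gap_ms
  if (sum(base_sel) < 3) abort("no pre-event baseline frames")
  base <- colMeans(stack$frames[base_sel, , drop = FALSE])
  pk <- colMeans(stack$frames[peak_sel, , drop = FALSE])
  out <- stack$pixels
  out$dff <- (pk - base) / base
  out
}

#' Average pixel traces in short axonal segments
#'
#' Partitions the on-axon pixels into contiguous path segments no longer
#' than `max_extent_um` and averages the pixel traces within each segment.
#'
#' @param stack A [vsd_stack()].
#' @param max_extent_um Maximum segment extent along the axon, um
#'   (default 5).
#' @return A tibble with columns `segment`, `path_mid`, `n_px`, `time`,
#'   `f` (one row per segment and frame).
#' @export
segment_average <- function(stack, max_extent_um = 5) {
  px <- dplyr::filter(stack$pixels, !is.na(.data$path_pos))
  if (nrow(px) == 0) abort("no pixels carry a path position (empty mask)")
  span <- range(px$path_pos)
  n_seg <- max(1L, ceiling(diff(span) / max_extent_um - 1e-9))
  edges <- seq(span[1], span[2], length.out = n_seg + 1)
  seg_of <- pmin(findInterval(px$path_pos, edges, rightmost.closed = TRUE),
                 n_seg)
  purrr::map_dfr(seq_len(n_seg), function(s) {
    cols <- px$px[seg_of == s]
    if (length(cols) == 0) return(NULL)
    tibble::tibble(segment = s,
                   path_mid = mean(edges[s + 0:1]),
                   n_px = length(cols),
                   time = stack$time,
                   f = rowMeans(stack$frames[, cols, drop = FALSE]))
  })
}

#' Spike-locked shift-and-mean temporal oversampling
#'
#' Combines frame samples from many trials into one waveform at a higher
#' effective rate: each trial's frame times are shifted by its electrical
#' reference AP peak time, the aligned samples of all trials are pooled and
#' sorted, and consecutive groups of `resample_factor` samples are averaged
#' (both in time and value).
#'
#' @param traces A list of per-trial tibbles with `time` (ms, frame clock)
#'   and `f`.
#' @param ref_peaks Per-trial AP peak times from the high-rate electrical
#'   reference, ms; trials with a missing (NA) reference are dropped with a
#'   message.
#' @param resample_factor Samples per output point (default 8).
#' @return A tibble with `time` (aligned to the AP peak) and `f`;
#'   `attr(, "effective_rate_khz")` is the output point density
#'   (points per covered ms), `attr(, "n_trials")` the trials used.
#' @export
shift_and_mean <- function(traces, ref_peaks, resample_factor = 8) {
  stopifnot(length(traces) == length(ref_peaks), resample_factor >= 1)
  ok <- !is.na(ref_peaks)
  if (any(!ok)) {
    rlang::inform(sprintf("dropping %d trial(s) without a reference peak",
                          sum(!ok)))
  }
  traces <- traces[ok]
  ref_peaks <- ref_peaks[ok]
  if (length(traces) == 0) abort("no trials with reference peaks")
  pooled <- dplyr::bind_rows(purrr::map2(traces, ref_peaks, function(tr, p) {
    tibble::tibble(time = tr$time - p, f = tr$f)
  }))
  pooled <- dplyr::arrange(pooled, .data$time)
  n_out <- floor(nrow(pooled) / resample_factor)
  if (n_out < 2) abort("too few pooled samples for block averaging")
  idx <- rep(seq_len(n_out), each = resample_factor)
  use <- seq_len(n_out * resample_factor)
  out <- tibble::tibble(time = pooled$time[use], f = pooled$f[use],
                        block = idx) %>%
    dplyr::group_by(.data$block) %>%
    dplyr::summarise(time = mean(.data$time), f = mean(.data$f),
                     .groups = "drop") %>%
    dplyr::select("time", "f")
  span <- max(pooled$time[use]) - min(pooled$time[use])
  attr(out, "effective_rate_khz") <- nrow(out) / span
  attr(out, "n_trials") <- length(traces)
  out
}

#' Two-step zero-phase Butterworth low-pass
#'
#' Applies forward-backward (zero-phase) 4-pole Butterworth low-pass
#' filters sequentially at the given cutoffs. A cutoff at or above the
#' Nyquist frequency of the waveform is skipped with a message, matching
#' how an oversampled-but-still-slow signal cannot be filtered at a cutoff
#' its rate does not support.
#'
#' @param waveform A tibble with `time` (ms) and `f` (or `v`).
#' @param cutoffs_khz Cutoff frequencies, kHz (default `c(10, 100)` for
#'   oversampled signals; use `c(2, 20)` for stimulation-evoked APs).
#' @param rate_khz Sampling rate; inferred from `time` when missing.
#' @return The filtered waveform (same columns).
#' @export
lowpass_two_step <- function(waveform, cutoffs_khz = c(10, 100),
                             rate_khz = NULL) {
  col <- if ("f" %in% names(waveform)) "f" else "v"
  y <- waveform[[col]]
  if (is.null(rate_khz)) {
    rate_khz <- 1 / stats::median(diff(waveform$time))
  }
  for (fc in cutoffs_khz) {
    if (fc >= rate_khz / 2) {
      rlang::inform(sprintf(
        "skipping %g kHz low-pass: at or above Nyquist (%g kHz)",
        fc, rate_khz / 2))
      next
    }
    bf <- signal::butter(4, fc / (rate_khz / 2), type = "low")
    y <- signal::filtfilt(bf, y)
  }
  waveform[[col]] <- y
  waveform
}

#' VSD AP area of a peak-normalized waveform
#'
#' The waveform is normalized so the pre-peak baseline maps to 0 and the
#' peak to 1 (VSD amplitudes are not comparable across recordings, so
#' normalization must precede any area metric), then integrated over a
#' fixed window starting a fixed offset after the peak.
#'
#' @param waveform A tibble with `time` (ms) and `f` (or `v`).
#' @param start_offset_ms Offset of the window start after the peak
#'   (0.05 or 0.1; default 0.05).
#' @param window_ms Window length, ms (default 0.6).
#' @param baseline_frac Fraction of the pre-peak trace (from its start)
#'   used for the baseline (default 0.5).
#' @return The normalized area (dimensionless time integral, ms).
#' @export
vsd_ap_area <- function(waveform, start_offset_ms = 0.05, window_ms = 0.6,
                        baseline_frac = 0.5) {
  stopifnot(start_offset_ms >= 0, window_ms > 0)
  col <- if ("f" %in% names(waveform)) "f" else "v"
  t <- waveform$time
  y <- waveform[[col]]
  ipk <- which.max(y)
  if (ipk < 3) abort("no pre-peak baseline available")
  base_n <- max(2, floor(ipk * baseline_frac))
  base <- stats::median(y[seq_len(base_n)])
  if (y[ipk] == base) abort("flat waveform: normalization undefined")
  yn <- (y - base) / (y[ipk] - base)
  t0 <- t[ipk] + start_offset_ms
  t1 <- t0 + window_ms
  if (t1 > max(t) + 1e-9) abort("area window exceeds the trace",
                                class = "axonwave_window_error")
  inside <- which(t > t0 & t < t1)
  xs <- c(t0, t[inside], t1)
  ys <- c(stats::approx(t, yn, t0)$y, yn[inside], stats::approx(t, yn, t1)$y)
  trapz(xs, ys)
}
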