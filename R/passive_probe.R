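#' Subtract the averaged cell-attached trace from a whole-cell transient
#'
#' Removes residual uncompensated instrumental capacitance: the averaged
#' cell-attached seal-test response is subtracted point-wise from the
#' whole-cell response recorded with the same step.
#'
#' @param whole_cell,cell_attached_avg Tibbles with matching `time` grids
#'   and a `current` column (nA).
#' @return A tibble like `whole_cell` with the difference in `current` and
#'   an attribute `subtracted = TRUE`.
#' @export
subtract_cell_attached <- function(whole_cell, cell_attached_avg) {
  if (nrow(whole_cell) != nrow(cell_attached_avg) ||
      max(abs(whole_cell$time - cell_attached_avg$time)) > 1e-9) {
    abort("whole-cell and cell-attached traces must share the time grid")
  }
  out <- whole_cell
  out$current <- whole_cell$current - cell_attached_avg$current
  attr(out, "subtracted") <- TRUE
  out
}

#' Multi-exponential fit of a capacitive transient
#'
#' Least-squares fit of `sum(A_i * exp(-(t - t0)/tau_i)) + offset` to the
#' decay of a capacitive current transient in a window after its peak.
#' Amplitudes are referenced to the step onset `t0` (back-extrapolated along
#' the fitted exponentials), so the fast-component charge `A_fast * tau_fast`
#' estimates the charge delivered to the local membrane. The fit uses
#' separable least squares (amplitudes solved linearly for trial time
#' constants) refined by Levenberg-Marquardt, with log-spaced multi-start
#' initializations plus nested starts from the best lower-order fit, which
#' guarantees `sse(n+1) <= sse(n)`.
#'
#' @param record A tibble with `time` (ms) and `current` (nA). The step
#'   onset is taken as `attr(record, "step_onset")` or time 0.
#' @param n_exp Number of exponentials (1, 2 or 3).
#' @param window `c(start, end)` in ms after the transient peak. The
#'   default `c(0.2, 5)` starts just after the peak (skipping residual
#'   uncompensated artifact) and spans about 5 ms, the window length over
#'   which access-resistance-scale fast components (tau ~ 0.2-1 ms) remain
#'   identifiable; both bounds are configurable.
#' @param n_starts Number of log-spaced tau initializations (>= 5).
#' @return An `exp_fit` object: list with `n_exp`, `amps` (nA, at onset),
#'   `taus` (ms, ascending), `offset`, `sse`, `window`, `fitted` tibble.
#' @export
fit_exponentials <- function(record, n_exp = 2, window = c(0.2, 5),
                             n_starts = 5) {
  stopifnot(n_exp %in% 1:3, length(window) == 2, window[2] > window[1],
            n_starts >= 5)
  t0 <- attr(record, "step_onset")
  if (is.null(t0)) t0 <- 0
  ipk <- which.max(abs(record$current))
  t_pk <- record$time[ipk]
  sel <- record$time >= t_pk + window[1] & record$time <= t_pk + window[2]
  if (sum(sel) < 3 * n_exp + 3) abort("fit window too short for the model")
  tt <- record$time[sel] - t0
  yy <- record$current[sel]

  # time constants a window can resolve: not much faster than the window
  # start (back-extrapolation would explode) nor much slower than ~20x its
  # end (indistinguishable from the offset)
  tau_lo <- max(window[1] / 4, (tt[2] - tt[1]) * 2)
  tau_hi <- 20 * (t_pk + window[2] - t0)

  # separable LS: given taus, amplitudes+offset are linear
  lin_solve <- function(taus) {
    X <- cbind(1, vapply(taus, function(tau) exp(-tt / tau), numeric(length(tt))))
    cf <- tryCatch(qr.coef(qr(X), yy), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    resid <- yy - X %*% cf
    list(offset = cf[1], amps = cf[-1], sse = sum(resid^2), taus = taus)
  }
  refine <- function(start) {
    # optimize log-taus with profiled linear coefficients (Nelder-Mead for
    # n>1, golden for n=1 via optimize)
    obj <- function(lt) {
      if (any(lt < log(tau_lo)) || any(lt > log(tau_hi))) return(1e12)
      s <- lin_solve(exp(lt))
      if (is.null(s)) return(1e12)
      s$sse
    }
    if (n_exp == 1) {
      o <- stats::optimize(function(l) obj(l),
                           interval = log(c(tau_lo, tau_hi)))
      lt <- o$minimum
    } else {
      o <- stats::optim(log(start$taus), obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
      lt <- o$par
    }
    lin_solve(exp(lt))
  }

  tau_grid <- exp(seq(log(tau_lo * 1.2), log(tau_hi / 1.2),
                      length.out = n_starts))
  starts <- lapply(seq_len(n_starts), function(k) {
    taus <- tau_grid[((k + seq_len(n_exp) - 2) %% n_starts) + 1]
    taus <- sort(taus) * seq(1, 1.5, length.out = n_exp)
    list(taus = taus)
  })
  # nested starts: best lower-order fit plus one extra fast/slow component
  if (n_exp > 1) {
    lower <- fit_exponentials(record, n_exp - 1, window, n_starts)
    starts <- c(starts,
                list(list(taus = sort(c(lower$taus,
                                        max(min(lower$taus) / 10, tau_lo * 1.5)))),
                     list(taus = sort(c(lower$taus,
                                        min(max(lower$taus) * 10, tau_hi / 1.5))))))
  }
  fits <- lapply(starts, function(s) tryCatch(refine(s),
                                              error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("exponential fit failed for all starts",
                               class = "axonwave_fit_error")
  best <- fits[[which.min(vapply(fits, function(f) f$sse, numeric(1)))]]
  ord <- order(best$taus)
  fitted <- tibble::tibble(
    time = record$time[sel],
    current = as.numeric(best$offset +
                           vapply(seq_len(n_exp), function(j)
                             best$amps[ord][j] * exp(-tt / best$taus[ord][j]),
                             numeric(length(tt))) %*% rep(1, n_exp)))
  structure(list(n_exp = n_exp, amps = unname(best$amps[ord]),
                 taus = unname(best$taus[ord]), offset = unname(best$offset),
                 sse = best$sse, window = window, step_onset = t0,
                 fitted = fitted),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %d exponentials, sse = %.4g nA^2\n", x$n_exp, x$sse))
  for (j in seq_len(x$n_exp)) {
    cat(sprintf("  A%d = %.4g nA  tau%d = %.4g ms\n", j, x$amps[j], j,
                x$taus[j]))
  }
  invisible(x)
}

#' Choose between mono-, bi-, and tri-exponential transient models
#'
#' The two-compartment (biexponential) model is the default. The
#' mono-exponential model is chosen when it comes within `mono_tol` of the
#' biexponential SSE; the tri-exponential model only when it improves on the
#' biexponential SSE by more than `tri_tol`.
#'
#' @param fits A list of three `exp_fit` objects (orders 1, 2, 3, any
#'   order).
#' @param mono_tol,tri_tol Relative SSE tolerances (default 0.1).
#' @return The chosen number of exponentials (1, 2 or 3).
#' @export
select_model <- function(fits, mono_tol = 0.1, tri_tol = 0.1) {
  ord <- vapply(fits, function(f) f$n_exp, numeric(1))
  stopifnot(setequal(ord, 1:3))
  sse <- vapply(1:3, function(n) fits[[which(ord == n)]]$sse, numeric(1))
  if (sse[1] <= (1 + mono_tol) * sse[2]) return(1L)
  # numerically exact biexponential fits leave nothing for a third component
  if (sse[3] < (1 - tri_tol) * sse[2] && sse[2] > 1e-9 * sse[1]) return(3L)
  2L
}

#' Structure capacitance from the fast fit component
#'
#' The local (structure) capacitance is derived from the fast-component
#' charge, `C = |A_fast * tau_fast / dV|`, with the amplitude
#' back-extrapolated to the step onset (done inside [fit_exponentials()]).
#' Because the local membrane only sees the fraction of the step that
#' survives the access-resistance divider, the raw charge underestimates C
#' by the squared divider ratio; with `series_correction = TRUE` (default)
#' the divider is estimated from the fit itself (peak current vs the
#' slow-plus-offset current back-extrapolated to onset) and divided out —
#' exact for an ideal two-compartment circuit.
#'
#' @param fit An `exp_fit` with at least two components.
#' @param dv Step amplitude, mV (default -20).
#' @param series_correction Apply the access-divider correction.
#' @return Capacitance in pF. A warning condition of class
#'   `axonwave_tau_separation` is signalled when `tau2/tau1 < 3`.
#' @export
structure_capacitance <- function(fit, dv = -20, series_correction = TRUE) {
  stopifnot(inherits(fit, "exp_fit"))
  if (fit$n_exp < 2) abort("structure capacitance needs a >=2-exponential fit")
  if (dv == 0) abort("step amplitude must be nonzero")
  if (fit$taus[2] / fit$taus[1] < 3) {
    warn("fast and slow time constants poorly separated (tau2/tau1 < 3)",
         class = "axonwave_tau_separation")
  }
  c_nf <- abs(fit$amps[1] * fit$taus[1] / dv)    # nA*ms/mV = nF
  if (series_correction) {
    i_tot0 <- sum(fit$amps) + fit$offset         # peak current at onset
    i_slow0 <- sum(fit$amps[-1]) + fit$offset    # without the fast component
    divider <- 1 - i_slow0 / i_tot0
    if (is.finite(divider) && divider > 0.05) c_nf <- c_nf / divider^2
  }
  1000 * c_nf
}

#' Input resistance from a voltage-clamp step
#'
#' `R_in = dV / dI_ss`, with the steady-state current measured over the
#' last 20% of the step and the pre-step baseline subtracted (leak
#' subtraction).
#'
#' @param record A tibble with `time` (ms) and `current` (nA);
#'   `attr(record, "step_onset")`, `attr(record, "step_width")` (ms) and
#'   `attr(record, "dv")` (mV) describe the step (onset defaults to 0).
#' @param dv Step amplitude override, mV.
#' @param step_width Step width override, ms.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(record, dv = NULL, step_width = NULL) {
  t0 <- attr(record, "step_onset"); if (is.null(t0)) t0 <- 0
  if (is.null(dv)) dv <- attr(record, "dv")
  if (is.null(step_width)) step_width <- attr(record, "step_width")
  stopifnot(!is.null(dv), !is.null(step_width))
  base <- record$current[record$time < t0]
  if (length(base) < 2) abort("no pre-step baseline available")
  ss_sel <- record$time >= t0 + 0.8 * step_width &
    record$time <= t0 + step_width
  if (sum(ss_sel) < 2) abort("step too short to reach steady state")
  di <- mean(record$current[ss_sel]) - mean(base)
  dv / di
}

#' Membrane time constant from a current-clamp relaxation
#'
#' Fits a single exponential to the late phase of the voltage relaxation
#' following a small current step; by default the first 20% of the
#' relaxation is discarded so fast (pipette/axial) components do not bias
#' the slow membrane component.
#'
#' @param cc_trace A tibble with `time` (ms) and `v` (mV), covering the
#'   relaxation from step onset (`attr(cc_trace, "step_onset")` or 0).
#' @param late_frac Fraction of the relaxation used, from the end
#'   (default 0.8).
#' @return Time constant in ms.
#' @export
membrane_time_constant <- function(cc_trace, late_frac = 0.8) {
  t0 <- attr(cc_trace, "step_onset"); if (is.null(t0)) t0 <- 0
  sel <- cc_trace$time >= t0
  tt <- cc_trace$time[sel] - t0
  vv <- cc_trace$v[sel]
  use <- tt >= (1 - late_frac) * max(tt)
  if (sum(use) < 5) abort("relaxation too short for a time-constant fit")
  tu <- tt[use]; vu <- vv[use]
  # single exponential plus free offset, amplitude/offset profiled out
  sse_of <- function(ltau) {
    X <- cbind(1, exp(-tu / exp(ltau)))
    cf <- tryCatch(qr.coef(qr(X), vu), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(1e300)
    sum((vu - X %*% cf)^2)
  }
  span <- max(tu) - min(tu)
  o <- stats::optimize(sse_of, interval = log(c(span / 100, span * 20)))
  exp(o$minimum)
}

#' Full passive probe of a seal-test transient
#'
#' Runs the paper-style measurement pipeline on one transient: fits mono-,
#' bi-, and tri-exponential models, selects the model, and derives the
#' structure capacitance and input resistance.
#'
#' @param record A tibble with `time`, `current`, and step attributes (see
#'   [input_resistance()]).
#' @param dv Step amplitude, mV.
#' @param window Fit window after the peak, ms.
#' @param step_width Step width, ms.
#' @return A list of class `passive_estimate`: `fits` (the three fits),
#'   `chosen_n`, `capacitance_pf`, `input_resistance_mohm`, and a `tidy`
#'   one-row tibble summary.
#' @export
passive_probe <- function(record, dv = -20, window = c(0.2, 5),
                          step_width = 100) {
  fits <- lapply(1:3, function(n) fit_exponentials(record, n, window))
  chosen <- select_model(fits)
  cap <- withCallingHandlers(
    structure_capacitance(fits[[2]], dv),
    axonwave_tau_separation = function(w) invokeRestart("muffleWarning"))
  rin <- tryCatch(input_resistance(record, dv = dv,
                                   step_width = step_width),
                  error = function(e) NA_real_)
  out <- list(fits = fits, chosen_n = chosen, capacitance_pf = cap,
              input_resistance_mohm = rin,
              sse = vapply(fits, function(f) f$sse, numeric(1)))
  class(out) <- "passive_estimate"
  out
}

#' @export
print.passive_estimate <- function(x, ...) {
  cat(sprintf(
    "<passive_estimate> model: %d exp; C = %.3g pF; R_in = %.3g MOhm\n",
    x$chosen_n, x$capacitance_pf, x$input_resistance_mohm))
  invisible(x)
}
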