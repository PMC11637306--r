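#' Passive membrane parameters
#'
#' Defaults follow common values for thin unmyelinated axons: specific
#' capacitance 1 uF/cm^2, axial resistivity 150 Ohm cm, specific membrane
#' resistance 50 kOhm cm^2, leak reversal -80 mV.
#'
#' @param cm Specific capacitance, uF/cm^2.
#' @param ra Axial resistivity, Ohm cm.
#' @param rm Specific membrane resistance, kOhm cm^2.
#' @param e_leak Leak reversal potential, mV.
#' @return A list of class `passive_params`.
#' @export
passive_params <- function(cm = 1, ra = 150, rm = 50, e_leak = -80) {
  stopifnot(cm > 0, ra > 0, rm > 0)
  structure(list(cm = cm, ra = ra, rm = rm, e_leak = e_leak),
            class = "passive_params")
}

#' Active conductance densities
#'
#' Hodgkin-Huxley type sodium and backbone potassium densities, plus an
#' optional compensatory (Kv1-like) potassium density which may be scalar or
#' per-compartment. Default densities are 290 mS/cm^2 (Na) and 17 mS/cm^2
#' (backbone K), with reversals +70 and -90 mV. The default voltage shift
#' (+5 mV) and kinetic scale factors (6 for Na activation, 12 for Na
#' inactivation, 8 for K) calibrate the canonical squid rate equations to a
#' brief axonal AP at 35 degrees C (half-width about 0.35 ms, full
#' repolarization within about 1 ms); all are configurable and the
#' instrument-fitting pathway varies them freely.
#'
#' @param g_na,g_k,g_k_comp Conductance densities in mS/cm^2; `g_k_comp`
#'   may be a vector (one value per compartment).
#' @param e_na,e_k Reversal potentials, mV.
#' @param vshift Uniform voltage shift applied to all rate equations, mV.
#' @param vshift_k Additional voltage shift of the backbone K activation
#'   only (default 0; positive values give a high-threshold, Kv3-like
#'   current).
#' @param vshift_kc Additional shift of the compensatory K activation
#'   (default 0: low-threshold, Kv1-like).
#' @param rate_scale_kc Kinetic scale of the compensatory K gate.
#' @param rate_scale_na,rate_scale_h,rate_scale_k Multiplicative kinetic
#'   scale factors for Na activation, Na inactivation, and K activation.
#' @return A list of class `active_densities`.
#' @export
active_densities <- function(g_na = 290, g_k = 17, g_k_comp = 0,
                             e_na = 70, e_k = -90, vshift = 5,
                             rate_scale_na = 6, rate_scale_h = 12,
                             rate_scale_k = 8, vshift_k = 0,
                             vshift_kc = 0, rate_scale_kc = 4) {
  stopifnot(all(g_na >= 0), all(g_k >= 0), all(g_k_comp >= 0),
            rate_scale_na > 0, rate_scale_h > 0, rate_scale_k > 0,
            rate_scale_kc > 0)
  structure(list(g_na = g_na, g_k = g_k, g_k_comp = g_k_comp,
                 e_na = e_na, e_k = e_k, vshift = vshift,
                 rate_scale_na = rate_scale_na,
                 rate_scale_h = rate_scale_h,
                 rate_scale_k = rate_scale_k,
                 vshift_k = vshift_k, vshift_kc = vshift_kc,
                 rate_scale_kc = rate_scale_kc),
            class = "active_densities")
}

#' GHK calcium channel mixture
#'
#' A compound calcium current carried by P/Q-, N-, and R-type subtypes in a
#' fixed permeability ratio (default 6.5 : 2.5 : 1). Each subtype has a
#' single squared activation gate with subtype-specific half-activation and
#' slope; the open-channel flux follows the Goldman-Hodgkin-Katz constant
#' field equation. Gate rates are scaled by `q10^((temp - temp_ref)/10)`.
#'
#' @param p_total Total permeability density summed over subtypes, cm/s.
#' @param ratio Length-3 positive vector of P/Q : N : R permeability ratios.
#' @param vh Half-activation voltages (mV) per subtype.
#' @param slope Activation slopes (mV) per subtype.
#' @param rate Base symmetric rate constants (1/ms) per subtype.
#' @param q10 Temperature coefficient for the gate rates.
#' @param temp Simulation temperature, degrees C.
#' @param temp_ref Reference temperature of the kinetics, degrees C.
#' @param ca_in,ca_out Internal and external Ca2+ concentration, mM.
#' @return A list of class `ca_mixture`.
#' @export
ca_mixture <- function(p_total = 2e-4, ratio = c(6.5, 2.5, 1),
                       vh = c(-5, -12, -25), slope = c(6, 6.5, 7),
                       rate = c(1.2, 1.2, 1.0),
                       q10 = 2.5, temp = 35, temp_ref = 24,
                       ca_in = 1e-4, ca_out = 2) {
  stopifnot(length(ratio) == 3, all(ratio > 0), q10 > 0, p_total >= 0,
            ca_in >= 0, ca_out >= 0)
  structure(list(p_total = p_total, ratio = ratio / sum(ratio),
                 vh = vh, slope = slope, rate = rate, q10 = q10,
                 temp = temp, temp_ref = temp_ref,
                 ca_in = ca_in, ca_out = ca_out),
            class = "ca_mixture")
}

#' Hodgkin-Huxley rate constants
#'
#' Forward and backward rates of the squid-axon rate equations for gate
#' `"m"`, `"h"`, or `"n"`, with a uniform voltage shift and a kinetic scale
#' factor. Removable singularities of the linear/exponential forms are
#' evaluated by their analytic limits.
#'
#' @param v Membrane potential, mV.
#' @param gate One of `"m"`, `"h"`, `"n"`.
#' @param vshift Voltage shift, mV.
#' @param rate_scale Multiplicative kinetic scale.
#' @return A list with elements `alpha` and `beta` (1/ms).
#' @export
hh_rates <- function(v, gate = c("m", "h", "n"), vshift = 0,
                     rate_scale = 1) {
  gate <- match.arg(gate)
  gid <- match(gate, c("m", "h", "n")) - 1L
  stopifnot(is.finite(v))
  cpp_hh_rates(v, gid, vshift, rate_scale)
}

#' Goldman-Hodgkin-Katz current density
#'
#' Constant-field current density for an ion of valence `z` at permeability
#' `p` (cm/s), continuous through v = 0 where the analytic limit
#' `z*F*p*(c_in - c_out)` applies.
#'
#' @param v Membrane potential, mV.
#' @param p Permeability, cm/s.
#' @param z Valence.
#' @param c_in,c_out Concentrations, mM.
#' @param temp_K Absolute temperature, K.
#' @return Current density in mA/cm^2 (inward negative).
#' @export
ghk_current <- function(v, p, z = 2, c_in = 1e-4, c_out = 2,
                        temp_K = 273.15 + 35) {
  stopifnot(c_in >= 0, c_out >= 0, temp_K > 0)
  p * vapply(v, cpp_ghk_flux, numeric(1), z = z, cin = c_in, cout = c_out,
             TK = temp_K)
}

#' Q10 temperature scaling of a kinetic rate
#'
#' @param rate Rate in 1/ms.
#' @param temp Temperature, degrees C.
#' @param temp_ref Reference temperature, degrees C.
#' @param q10 Temperature coefficient.
#' @return `rate * q10^((temp - temp_ref)/10)`.
#' @export
q10_scale <- function(rate, temp, temp_ref, q10 = 2.5) {
  stopifnot(q10 > 0)
  rate * q10^((temp - temp_ref) / 10)
}

#' Instantaneous membrane current decomposition
#'
#' Evaluates the per-species current densities at a single voltage and gate
#' state, using `i_na = g_na m^3 h (v - e_na)`, `i_k = g_k n^4 (v - e_k)`,
#' the analogous compensatory current, the GHK calcium mixture with squared
#' activation gates, and the ohmic leak.
#'
#' @param v Membrane potential, mV.
#' @param gates Named list with elements `m`, `h`, `n`, and optionally `p`
#'   (compensatory K gate) and `ca` (length-3 subtype activations), each in
#'   `[0, 1]`.
#' @param densities An [active_densities()] object.
#' @param mixture A [ca_mixture()] object.
#' @param passive A [passive_params()] object.
#' @return A tibble with columns `i_na`, `i_k`, `i_k_comp`, `i_ca`,
#'   `i_leak`, `i_total` in mA/cm^2.
#' @export
membrane_current <- function(v, gates, densities = active_densities(),
                             mixture = ca_mixture(),
                             passive = passive_params()) {
  g <- gates
  stopifnot(all(unlist(g) >= 0), all(unlist(g) <= 1))
  pgate <- if (is.null(g$p)) 0 else g$p
  cag <- if (is.null(g$ca)) rep(0, 3) else g$ca
  # mS/cm2 * mV = uA/cm2; convert to mA/cm2
  i_na <- densities$g_na * g$m^3 * g$h * (v - densities$e_na) * 1e-3
  i_k <- densities$g_k * g$n^4 * (v - densities$e_k) * 1e-3
  i_kc <- sum(densities$g_k_comp[1]) * pgate^4 * (v - densities$e_k) * 1e-3
  p_sub <- mixture$p_total * mixture$ratio
  i_ca <- sum(ghk_current(v, p_sub * cag^2, z = 2, c_in = mixture$ca_in,
                          c_out = mixture$ca_out,
                          temp_K = 273.15 + mixture$temp))
  i_leak <- (1 / passive$rm) * (v - passive$e_leak) * 1e-3
  tibble::tibble(i_na = i_na, i_k = i_k, i_k_comp = i_kc, i_ca = i_ca,
                 i_leak = i_leak,
                 i_total = i_na + i_k + i_kc + i_ca + i_leak)
}
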