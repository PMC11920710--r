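#' Carreau-Yasuda blood viscosity parameters
#'
#' Defaults are the standard literature constants for human blood:
#' zero-shear viscosity 0.056 Pa s, infinite-shear viscosity 0.0035 Pa s,
#' relaxation time 1.902 s, power-law index 0.22 and Yasuda exponent 1.25.
#'
#' @param mu_inf infinite-shear viscosity, Pa s.
#' @param mu_0 zero-shear viscosity, Pa s; must exceed `mu_inf`.
#' @param lambda_cy relaxation time, s.
#' @param m power-law index (dimensionless); `m < 1` gives shear thinning.
#' @param a Yasuda exponent (dimensionless).
#' @return An object of class `viscosity_params`.
#' @export
viscosity_params <- function(mu_inf = 0.0035, mu_0 = 0.056,
                             lambda_cy = 1.902, m = 0.22, a = 1.25) {
  # mu_0 == mu_inf is allowed: it is the Newtonian limit
  if (!(mu_0 >= mu_inf && mu_inf > 0)) {
    stop("need mu_0 >= mu_inf > 0", call. = FALSE)
  }
  if (lambda_cy <= 0 || a <= 0) stop("lambda_cy and a must be > 0", call. = FALSE)
  structure(list(mu_inf = mu_inf, mu_0 = mu_0, lambda_cy = lambda_cy,
                 m = m, a = a), class = "viscosity_params")
}

#' Carreau-Yasuda shear-thinning viscosity
#'
#' `mu = (mu_0 - mu_inf) * (1 + (lambda * gdot)^a)^((m - 1)/a) + mu_inf`.
#' At zero shear rate this reduces to `mu_0`; for `gdot -> Inf` it tends to
#' `mu_inf`; for `m < 1` it is strictly decreasing in between.
#'
#' @param gamma_dot shear rate(s), 1/s; must be nonnegative.
#' @param vp a [viscosity_params()] object.
#' @return Viscosity in Pa s, same length as `gamma_dot`.
#' @examples
#' carreau_yasuda(0)          # 0.056
#' carreau_yasuda(1e6)        # ~0.0035
#' @export
carreau_yasuda <- function(gamma_dot, vp = viscosity_params()) {
  if (any(gamma_dot < 0)) stop("shear rate must be nonnegative", call. = FALSE)
  (vp$mu_0 - vp$mu_inf) *
    (1 + (vp$lambda_cy * gamma_dot)^vp$a)^((vp$m - 1) / vp$a) + vp$mu_inf
}

#' Murray-law flow split between the two daughter branches
#'
#' Apportions flow to the LAD and LCx proportionally to the cube of their
#' diameters, the standard stand-in for pressure-outlet boundary conditions
#' that let the flow distribute itself between branches.
#'
#' @param d_lad,d_lcx daughter diameters, mm; both positive.
#' @return Named numeric `c(LAD = ..., LCX = ...)` summing to 1.
#' @examples
#' murray_flow_split(2, 1)  # 8/9, 1/9
#' @export
murray_flow_split <- function(d_lad, d_lcx) {
  if (d_lad <= 0 || d_lcx <= 0) {
    stop("daughter diameters must be positive", call. = FALSE)
  }
  s <- d_lad^3 + d_lcx^3
  c(LAD = d_lad^3 / s, LCX = d_lcx^3 / s)
}

#' Pulsatile inlet flow waveform
#'
#' Two-lobe raised-cosine (sin^2) pulse train over one cardiac cycle with a
#' diastolic-dominant second lobe, riding on a small baseline flow, rescaled
#' analytically to cycle mean exactly 1. This emulates the shape of a left
#' coronary inlet velocity wave without digitizing any measured trace.
#'
#' @param period cycle length T, s.
#' @param systole_frac fraction of the cycle occupied by the systolic lobe.
#' @param diastolic_gain amplitude of the diastolic lobe relative to the
#'   systolic one (> 1 makes diastole dominant, as in coronary flow).
#' @param baseline constant baseline flow relative to the systolic amplitude.
#' @return A function `w(t)` (vectorized, period-extended) with attributes
#'   `period` and `mean` (= 1).
#' @examples
#' w <- flow_waveform()
#' integrate(w, 0, attr(w, "period"))$value / attr(w, "period")  # ~1
#' @export
flow_waveform <- function(period = 0.8, systole_frac = 0.375,
                          diastolic_gain = 2, baseline = 0.2) {
  stopifnot(period > 0, systole_frac > 0, systole_frac < 1,
            diastolic_gain >= 0, baseline >= 0)
  t1 <- systole_frac * period
  # mean of sin^2 over its lobe is 1/2
  mean_raw <- baseline + (t1 / 2 + diastolic_gain * (period - t1) / 2) / period
  f <- function(t) {
    tt <- t %% period
    raw <- ifelse(tt < t1,
                  baseline + sin(pi * tt / t1)^2,
                  baseline + diastolic_gain * sin(pi * (tt - t1) / (period - t1))^2)
    raw / mean_raw
  }
  attr(f, "period") <- period
  attr(f, "mean") <- 1
  f
}

#' Inlet flow state for one morphology
#'
#' Mean inlet flow is `v_mean * pi * d_lm^2 / 4` (plug mean velocity over the
#' LM cross-section); branch fractions follow [murray_flow_split()].
#'
#' @param params morphology row with `d_lm`, `d_lad`, `d_lcx` (mm).
#' @param v_mean cycle-mean inlet velocity, mm/s (default 400 = 0.4 m/s).
#' @param waveform a [flow_waveform()]-style function with a `period` attribute.
#' @return Object of class `flow_state`: `q_mean_lm` (mm^3/s), `waveform`,
#'   `period` (s), `q_fractions` (LAD/LCX).
#' @export
flow_state <- function(params, v_mean = 400, waveform = flow_waveform()) {
  stopifnot(params$d_lm > 0, v_mean > 0)
  structure(list(q_mean_lm = v_mean * pi * params$d_lm^2 / 4,
                 waveform = waveform,
                 period = attr(waveform, "period"),
                 q_fractions = murray_flow_split(params$d_lad, params$d_lcx)),
            class = "flow_state")
}
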