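#' Passive (end-diastolic) left-ventricular pressure
#'
#' Third-order passive pressure-volume relation of the LV,
#' `P = a_V * V^3` with `a_V = P_Ved_M / V_Ved_M^3`, the lower limb of the
#' Frank-Starling description.
#'
#' @param V LV cavity volume, ml (vectorized).
#' @param params A [wk_params] object.
#' @return Pressure, mmHg.
#' @examples
#' passive_lv_pressure(114, wk_params(P_Ved_M = 40))
#' @export
passive_lv_pressure <- function(V, params = wk_params()) {
  stopifnot(is.numeric(V))
  if (any(V < 0)) stop("volume V must be >= 0", call. = FALSE)
  wk_derived(params)$a_V * V^3
}

#' Isovolumic maximum ventricular pressure
#'
#' The peak pressure the LV could develop in a persisting isovolumic
#' contraction at end-diastolic volume `V_ed`:
#' `P = P_Vivmax_M - b_V * (V_ed - V_Ved_M)^2`, the upper limb of the
#' Frank-Starling description, maximal at `V_ed = V_Ved_M`.
#'
#' @param V_ed End-diastolic volume, ml (vectorized).
#' @inheritParams passive_lv_pressure
#' @return Pressure, mmHg.
#' @examples
#' isovolumic_max_pressure(200)  # the 275 mmHg peak
#' @export
isovolumic_max_pressure <- function(V_ed, params = wk_params()) {
  stopifnot(is.numeric(V_ed))
  if (any(V_ed < 0)) stop("volume V_ed must be >= 0", call. = FALSE)
  params$P_Vivmax_M - wk_derived(params)$b_V * (V_ed - params$V_Ved_M)^2
}

#' Thick-sphere area factor relating wall stress to cavity pressure
#'
#' For a spherical LV with wall volume `V_m` and cavity volume `V_V`, the law
#' of Laplace gives `P_V = sigma_V * A_V` with
#' `A_V = 2*(h/r) + (h/r)^2` and `h/r = (V_m/V_V + 1)^(1/3) - 1`.
#'
#' @param V_m Wall (muscle) volume, ml.
#' @param V_V Cavity volume, ml (vectorized).
#' @return Dimensionless area factor, strictly decreasing in `V_V`.
#' @examples
#' area_factor(140, 20)  # V_m/V_V = 7 -> h/r = 1 -> A_V = 3
#' @export
area_factor <- function(V_m, V_V) {
  stopifnot(is.numeric(V_m), is.numeric(V_V))
  if (any(V_m <= 0)) stop("wall volume V_m must be > 0", call. = FALSE)
  if (any(V_V <= 0)) stop("cavity volume V_V must be > 0 (thin-cavity limit is singular)",
                          call. = FALSE)
  x <- (V_m / V_V + 1)^(1 / 3) - 1
  2 * x + x^2
}

#' Ventricular twitch activation
#'
#' Dimensionless activation of LV contraction within one beat,
#' `f_Vc = exp(-(k_V1*|t - t_Vmax|)^i_V1 - (k_V2*|t - t_Vmax|)^i_V2)`,
#' peaking at exactly 1 at `t = t_Vmax` and symmetric about it. `t_cycle` is
#' measured from the sinoatrial excitation of the current beat.
#'
#' @param t_cycle Time within the beat, s (vectorized).
#' @inheritParams passive_lv_pressure
#' @return Activation in \[0, 1\].
#' @examples
#' lv_activation(c(0.2, 0.3568, 0.5), wk_params())
#' @export
lv_activation <- function(t_cycle, params = wk_params()) {
  stopifnot(is.numeric(t_cycle))
  dt <- abs(t_cycle - params$t_Vmax)
  u <- (params$k_V1 * dt)^params$i_V1 + (params$k_V2 * dt)^params$i_V2
  ifelse(u > 500, 0, exp(-u))
}

#' Atrial twitch activation
#'
#' `f_Ac = exp(-(k_A*|t - t_Amax|)^i_A)`, the (narrower) atrial analogue of
#' [lv_activation()].
#'
#' @inheritParams lv_activation
#' @return Activation in \[0, 1\].
#' @export
la_activation <- function(t_cycle, params = wk_params()) {
  stopifnot(is.numeric(t_cycle))
  u <- (params$k_A * abs(t_cycle - params$t_Amax))^params$i_A
  ifelse(u > 500, 0, exp(-u))
}

#' Ejection de-rating of ventricular stress
#'
#' As the LV empties during ejection, fibre stretch falls and the developed
#' stress is reduced: `f_Ve = 1 - (1/K_e) * (-ln(V_V/V_Ved))^i_e`, equal to 1
#' at `V_V = V_Ved` and decreasing as `V_V` falls. During filling (transient
#' `V_V > V_Ved`) the ratio is clamped to 1.
#'
#' @param V_V Instantaneous LV volume, ml (vectorized).
#' @param V_Ved End-diastolic volume of the current beat, ml.
#' @inheritParams passive_lv_pressure
#' @return Dimensionless de-rating factor.
#' @examples
#' ejection_derating(36, 114, wk_params())
#' @export
ejection_derating <- function(V_V, V_Ved, params = wk_params()) {
  stopifnot(is.numeric(V_V), is.numeric(V_Ved))
  if (any(V_V <= 0)) stop("volume V_V must be > 0", call. = FALSE)
  if (any(V_Ved <= 0)) stop("volume V_Ved must be > 0", call. = FALSE)
  ratio <- pmin(V_V / V_Ved, 1)
  1 - (-log(ratio))^params$i_e / params$K_e
}

#' Instantaneous left-ventricular pressure
#'
#' The developed LV pressure mixes the passive and isovolumic-maximum
#' pressure curves, gated by the twitch activation, the contractility
#' coefficient and the ejection de-rating, with the active term converted
#' through the law-of-Laplace geometry:
#' `P_V = P_pass(V_V) + (P_ivmax(V_Ved) - P_pass(V_V)) * f_Vc * K_Vc * f_Ve *
#' A_V(V_V) / A_V(V_Ved)`.
#' The active stress is referenced to the end-diastolic geometry and acts on
#' the instantaneous wall area, so the rising area factor of the emptying
#' ventricle sustains the cavity pressure during ejection. At `V_V = V_Ved`
#' the area ratio is 1 and the Frank-Starling anchors hold exactly: full
#' activation yields `P_ivmax(V_Ved)`, zero activation the passive cubic.
#'
#' @param t_cycle Time within the beat, s.
#' @param V_V Instantaneous LV volume, ml.
#' @param V_Ved End-diastolic volume of the current beat, ml.
#' @inheritParams passive_lv_pressure
#' @return Pressure, mmHg. Arguments are vectorized and recycled.
#' @examples
#' lv_pressure(0.3568, 90, 114, wk_params())
#' @export
lv_pressure <- function(t_cycle, V_V, V_Ved, params = wk_params()) {
  P_pass <- passive_lv_pressure(V_V, params)
  P_ivm <- isovolumic_max_pressure(V_Ved, params)
  act <- lv_activation(t_cycle, params) * params$K_Vc *
    ejection_derating(V_V, V_Ved, params) *
    area_factor(params$V_m, V_V) / area_factor(params$V_m, V_Ved)
  P_pass + (P_ivm - P_pass) * act
}

#' Left-ventricular wall stress
#'
#' Wall stress consistent with the law of Laplace for a thick-walled sphere:
#' `sigma_V = P_V / A_V(V_m, V_V)`, so that `P_V = sigma_V * A_V` recovers the
#' cavity pressure of [lv_pressure()]. Reported in pressure-equivalent units
#' (mmHg).
#'
#' @inheritParams lv_pressure
#' @return Stress, mmHg.
#' @export
lv_wall_stress <- function(t_cycle, V_V, V_Ved, params = wk_params()) {
  lv_pressure(t_cycle, V_V, V_Ved, params) / area_factor(params$V_m, V_V)
}

#' Instantaneous left-atrial pressure
#'
#' Passive quintic plus a gated active term:
#' `P_A = a_A * V_A^5 + f_Ac * (P_Ac_max - b_A * (V_A - V_A_M)^2)` with
#' `a_A = P_A_M / V_A_M^5`.
#'
#' @param t_cycle Time within the beat, s.
#' @param V_A Atrial volume, ml.
#' @inheritParams passive_lv_pressure
#' @return Pressure, mmHg.
#' @examples
#' la_pressure(0.12, 100, wk_params())  # 30 + 7.5 at the twitch peak
#' @export
la_pressure <- function(t_cycle, V_A, params = wk_params()) {
  stopifnot(is.numeric(V_A))
  if (any(V_A < 0)) stop("volume V_A must be >= 0", call. = FALSE)
  wk_derived(params)$a_A * V_A^5 +
    la_activation(t_cycle, params) *
      (params$P_Ac_max - params$b_A * (V_A - params$V_A_M)^2)
}
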