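# Electrical-analogue circuit of the left heart and systemic circulation:
# mitral valve -> LV -> aortic valve + inertance L -> aortic-arch node
# (viscoelastic C_a1, R_a1) -> R_a -> aortic node (C_a2, R_a2) -> R_p ->
# venous node (elastic C_v) -> R_v -> left atrium. Closed loop: total volume
# V_A + V_V + q_a1 + q_a2 + q_v is conserved exactly by construction.

# Parameter vector order shared with src/wk_ode.c (must stay in sync).
.wk_par_names <- c(
  "T_cycle", "R_DAV", "R_Da", "R_closed", "R_a1", "R_a2", "R_a", "R_p", "R_v",
  "C_a1", "C_a2", "C_v", "L", "a_V", "b_V", "P_Vivmax_M", "V_Ved_M", "K_Vc",
  "k_V1", "k_V2", "i_V1", "i_V2", "t_Vmax", "K_e", "i_e", "a_A", "b_A",
  "V_A_M", "P_Ac_max", "k_A", "i_A", "t_Amax", "V_m", "mitral_open",
  "aortic_open"
)

.wk_state_names <- c("V_A", "V_V", "q_a1", "q_a2", "q_v", "Q_a", "V_Ved_latch")

.wk_aux_names <- c("P_V", "P_A", "P_arc", "P_a", "P_v", "Q_AV", "Q_ven",
                   "f_Vc", "sigma_V")

# Flatten a wk_params object (+ cycle period and valve states) into the
# positional vector consumed by the compiled right-hand side.
wk_par_vector <- function(params, period, mitral_open, aortic_open) {
  d <- wk_derived(params)
  v <- c(period, params$R_DAV, params$R_Da, params$R_closed, params$R_a1,
         params$R_a2, params$R_a, params$R_p, params$R_v, params$C_a1,
         params$C_a2, params$C_v, params$L, d$a_V, d$b_V, params$P_Vivmax_M,
         params$V_Ved_M, params$K_Vc, params$k_V1, params$k_V2, params$i_V1,
         params$i_V2, params$t_Vmax, params$K_e, params$i_e, d$a_A,
         params$b_A, params$V_A_M, params$P_Ac_max, params$k_A, params$i_A,
         params$t_Amax, params$V_m,
         as.numeric(mitral_open), as.numeric(aortic_open))
  stats::setNames(v, .wk_par_names)
}

# Direct call into the compiled right-hand side (used by the test suite to
# cross-check wk_derivatives against the integrator's kernel).
wk_rhs_c <- function(t, state, params, period = 60 / 72,
                     mitral_open = TRUE, aortic_open = FALSE) {
  pvec <- wk_par_vector(params, period, mitral_open, aortic_open)
  out <- .C("wk_rhs_test", t = as.double(t),
            y = as.double(state[.wk_state_names]),
            pars = as.double(pvec), ydot = double(7), aux = double(9),
            PACKAGE = "wkheart")
  list(stats::setNames(out$ydot, .wk_state_names),
       stats::setNames(out$aux, .wk_aux_names))
}

#' Two-state (diode) valve resistance
#'
#' Cardiac valves are modelled as pressure-controlled diodes: the open-state
#' resistance applies while the forward pressure drop is positive, and a large
#' closed-state resistance (`R_closed`, default 1e4 mmHg·s/ml) otherwise. A
#' zero drop is treated as closed.
#'
#' @param forward_pressure_drop Pressure drop in the forward flow direction,
#'   mmHg (vectorized): `P_A - P_V` for the mitral valve, `P_V - P_arc` for
#'   the aortic valve.
#' @param open_R Open-state resistance, mmHg·s/ml.
#' @param R_closed Closed-state resistance, mmHg·s/ml.
#' @return Resistance, mmHg·s/ml.
#' @examples
#' valve_resistance(5, 0.012)    # open mitral valve
#' valve_resistance(-5, 0.025)   # closed aortic valve
#' @export
valve_resistance <- function(forward_pressure_drop, open_R, R_closed = 1e4) {
  ifelse(forward_pressure_drop > 0, open_R, R_closed)
}

#' Algebraic node pressures of the arterial and venous compliances
#'
#' The two arterial compliances are viscoelastic (capacitor with a series
#' resistor), so their node pressures satisfy
#' `P_arc = q_a1/C_a1 + R_a1 * dq_a1/dt` and
#' `P_a = q_a2/C_a2 + R_a2 * dq_a2/dt`, where the charge derivatives are the
#' local flow balances which themselves depend on the node pressures. The
#' resulting 2x2 linear system is solved exactly; the venous compliance is
#' purely elastic, `P_v = q_v / C_v`.
#'
#' @param state Named numeric vector (or 1-row data frame) with at least
#'   `q_a1`, `q_a2`, `q_v`, `Q_a` (ml, ml, ml, ml/s).
#' @param params A [wk_params] object.
#' @return Named list with `P_arc`, `P_a`, `P_v` (mmHg).
#' @examples
#' node_pressures(c(q_a1 = 8, q_a2 = 130, q_v = 350, Q_a = 0), wk_params())
#' @export
node_pressures <- function(state, params = wk_params()) {
  s <- as.list(state)
  P_v <- s$q_v / params$C_v
  a11 <- 1 + params$R_a1 / params$R_a
  a12 <- -params$R_a1 / params$R_a
  a21 <- -params$R_a2 / params$R_a
  a22 <- 1 + params$R_a2 / params$R_a + params$R_a2 / params$R_p
  b1 <- s$q_a1 / params$C_a1 + params$R_a1 * s$Q_a
  b2 <- s$q_a2 / params$C_a2 + (params$R_a2 / params$R_p) * P_v
  det <- a11 * a22 - a12 * a21
  if (!is.finite(det) || abs(det) < .Machine$double.eps) {
    stop("singular viscoelastic node system; check R_a1, R_a2, R_a, R_p",
         call. = FALSE)
  }
  list(P_arc = (b1 * a22 - a12 * b2) / det,
       P_a = (a11 * b2 - a21 * b1) / det,
       P_v = P_v)
}

#' Reference right-hand side of the circulation ODEs
#'
#' Pure-R implementation of the coupled state derivatives, used as the
#' readable reference for the compiled right-hand side that drives
#' [wk_simulate()] (the two are cross-checked in the test suite). The state
#' holds 6 dynamic quantities (`V_A`, `V_V`, `q_a1`, `q_a2`, `q_v`, `Q_a`)
#' plus the per-beat latched end-diastolic volume `V_Ved_latch`, and the two
#' viscoelastic node pressures are resolved algebraically at every call.
#'
#' @param t Absolute time, s (the beat phase is `t` modulo the period).
#' @param state Named numeric vector with entries `V_A`, `V_V`, `q_a1`,
#'   `q_a2`, `q_v`, `Q_a`, `V_Ved_latch`.
#' @param params A [wk_params] object.
#' @param period Stimulation period, s (0.8333 s at 72 beats/min).
#' @param mitral_open,aortic_open Logical valve states of the current segment.
#' @return List: derivative vector, then a named numeric vector of auxiliary
#'   outputs (`P_V`, `P_A`, `P_arc`, `P_a`, `P_v`, `Q_AV`, `Q_ven`, `f_Vc`,
#'   `sigma_V`), matching the `deSolve` convention.
#' @export
wk_derivatives <- function(t, state, params = wk_params(), period = 60 / 72,
                           mitral_open = TRUE, aortic_open = FALSE) {
  s <- as.list(state)
  tc <- t %% period
  P_V <- lv_pressure(tc, s$V_V, s$V_Ved_latch, params)
  P_A <- la_pressure(tc, s$V_A, params)
  np <- node_pressures(state, params)

  R_mit <- if (mitral_open) params$R_DAV else params$R_closed
  R_aov <- if (aortic_open) params$R_Da else params$R_closed
  Q_AV <- (P_A - P_V) / R_mit
  Q_1 <- (np$P_arc - np$P_a) / params$R_a
  Q_p <- (np$P_a - np$P_v) / params$R_p
  Q_ven <- (np$P_v - P_A) / params$R_v

  dy <- c(
    V_A = Q_ven - Q_AV,
    V_V = Q_AV - s$Q_a,
    q_a1 = s$Q_a - Q_1,
    q_a2 = Q_1 - Q_p,
    q_v = Q_p - Q_ven,
    Q_a = (P_V - np$P_arc - R_aov * s$Q_a) / params$L,
    V_Ved_latch = 0
  )
  if (!all(is.finite(dy))) {
    bad <- names(dy)[!is.finite(dy)]
    stop("non-finite derivative in branch(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aux <- c(P_V = P_V, P_A = P_A, P_arc = np$P_arc, P_a = np$P_a, P_v = np$P_v,
           Q_AV = Q_AV, Q_ven = Q_ven,
           f_Vc = lv_activation(tc, params),
           sigma_V = P_V / area_factor(params$V_m, s$V_V))
  list(dy, aux)
}
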