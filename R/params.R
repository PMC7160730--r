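#' Model parameters of the left heart and systemic circulation
#'
#' Builds the full parameter set of the lumped (Windkessel) model: two-state
#' valve resistances, arterial/venous resistances and compliances, blood
#' inertance, and the constitutive constants of the left ventricle (LV) and
#' left atrium (LA). Defaults are the published control parameterization of
#' the model; the three quantities that are not fixed by the circuit table
#' (`P_Ved_M`, `V_m`, `total_blood_volume`) carry the package's calibrated
#' control values (see the methods vignette).
#'
#' @param ... Named parameter overrides. Unknown names are an error.
#'
#' @details
#' Circuit elements (electrical analogue):
#' \describe{
#'   \item{R_DAV, R_Da}{open mitral / aortic valve resistances, mmHg·s/ml}
#'   \item{R_closed}{closed-valve resistance, mmHg·s/ml (default 1e4)}
#'   \item{R_a1, R_a2}{series resistances of the two viscoelastic arterial
#'     compliances, mmHg·s/ml}
#'   \item{R_a, R_p, R_v}{aortic, peripheral and venous flow resistances,
#'     mmHg·s/ml}
#'   \item{C_a1, C_a2, C_v}{aortic-arch, aortic and venous compliances, ml/mmHg}
#'   \item{L}{blood inertance, mmHg·s^2/ml}
#' }
#' Ventricle (Frank–Starling + twitch activation + ejection de-rating):
#' \describe{
#'   \item{P_Vivmax_M, V_Ved_M}{peak isovolumic-maximum pressure (mmHg) and the
#'     end-diastolic volume (ml) at which it is reached}
#'   \item{P_Ved_M}{end-diastolic pressure at `V_Ved_M` (mmHg); sets the passive
#'     cubic `a_V = P_Ved_M / V_Ved_M^3`}
#'   \item{K_Vc}{dimensionless contractility coefficient (1 = control)}
#'   \item{k_V1, k_V2, i_V1, i_V2}{twitch rate constants (1/s) and exponents}
#'   \item{t_Vmax}{time from sinoatrial excitation to maximal LV contraction, s}
#'   \item{K_e, i_e}{ejection de-rating constants}
#'   \item{V_m}{LV wall (muscle) volume, ml; used for wall-stress reporting}
#' }
#' Atrium:
#' \describe{
#'   \item{V_A_M, P_A_M}{passive quintic anchor: `a_A = P_A_M / V_A_M^5`}
#'   \item{b_A, P_Ac_max}{active-term shape (mmHg/ml^2) and peak (mmHg)}
#'   \item{k_A, i_A, t_Amax}{atrial twitch rate (1/s), exponent, and peak time (s)}
#' }
#' `total_blood_volume` (ml) is the conserved volume of the closed loop.
#'
#' @return An object of class `wk_params`: a named list of numeric scalars.
#' @examples
#' p <- wk_params(K_Vc = 0.982, t_Vmax = 0.3885)
#' p$K_Vc
#' @export
wk_params <- function(...) {
  p <- wk_default_params()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  p <- structure(p, class = "wk_params")
  validate_wk_params(p)
  p
}

#' Default (control) parameter values
#'
#' @return Named list of all model parameters at their control values.
#' @keywords internal
wk_default_params <- function() {
  list(
    # valves
    R_DAV = 0.012, R_Da = 0.025, R_closed = 1e4,
    # vessels
    R_a1 = 0.05, R_a2 = 0.026, R_a = 0.0001, R_p = 1, R_v = 0.01,
    C_a1 = 0.08, C_a2 = 1.3, C_v = 70, L = 0.0003,
    # ventricle
    P_Vivmax_M = 275, V_Ved_M = 200, P_Ved_M = 35,
    K_Vc = 1, k_V1 = 5.68722, k_V2 = 5.2270,
    i_V1 = 2.0224, i_V2 = 9.11538, t_Vmax = 0.3568,
    K_e = 1.355, i_e = 0.35, V_m = 320,
    # atrium
    V_A_M = 100, P_A_M = 30, b_A = 0.00075, P_Ac_max = 7.5,
    k_A = 24, i_A = 7, t_Amax = 0.12,
    # closed-loop volume
    total_blood_volume = 760
  )
}

validate_wk_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("parameter(s) not finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  positive <- c("R_DAV", "R_Da", "R_closed", "R_a1", "R_a2", "R_a", "R_p",
                "R_v", "C_a1", "C_a2", "C_v", "L", "P_Vivmax_M", "V_Ved_M",
                "P_Ved_M", "k_V1", "k_V2", "i_V1", "i_V2", "t_Vmax", "K_e",
                "i_e", "V_m", "V_A_M", "P_A_M", "b_A", "k_A", "i_A", "t_Amax",
                "total_blood_volume")
  for (nm in positive) {
    if (p[[nm]] <= 0) {
      stop("parameter ", nm, " must be > 0 (got ", p[[nm]], ")", call. = FALSE)
    }
  }
  if (p$K_Vc < 0) stop("parameter K_Vc must be >= 0", call. = FALSE)
  if (p$P_Ac_max < 0) stop("parameter P_Ac_max must be >= 0", call. = FALSE)
  if (p$P_Vivmax_M <= p$P_Ved_M) {
    stop("P_Vivmax_M must exceed P_Ved_M", call. = FALSE)
  }
  invisible(p)
}

#' Derived constitutive coefficients
#'
#' The polynomial coefficients of the chamber pressure-volume laws are fixed by
#' their anchor points: `a_V = P_Ved_M / V_Ved_M^3`,
#' `b_V = P_Vivmax_M / V_Ved_M^2`, `a_A = P_A_M / V_A_M^5`.
#'
#' @param params A [wk_params] object.
#' @return Named list with `a_V` (mmHg/ml^3), `b_V` (mmHg/ml^2),
#'   `a_A` (mmHg/ml^5).
#' @examples
#' wk_derived(wk_params())$b_V  # 275 / 200^2
#' @export
wk_derived <- function(params) {
  list(
    a_V = params$P_Ved_M / params$V_Ved_M^3,
    b_V = params$P_Vivmax_M / params$V_Ved_M^2,
    a_A = params$P_A_M / params$V_A_M^5
  )
}

#' @export
print.wk_params <- function(x, ...) {
  cat("<wk_params> lumped left-heart model parameters\n")
  d <- wk_derived(x)
  df <- data.frame(value = unlist(x, use.names = TRUE))
  print(df)
  cat(sprintf("derived: a_V = %.6g mmHg/ml^3, b_V = %.6g mmHg/ml^2, a_A = %.6g mmHg/ml^5\n",
              d$a_V, d$b_V, d$a_A))
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x A [wk_params] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.wk_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unname(unlist(x)))
}
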