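# ggplot2 views of simulated traces and scenario comparisons.

#' Plot a simulated cardiac cycle
#'
#' @param object A `wk_sim` object.
#' @param type `"pressures"` (LV, atrial and aortic pressure versus time),
#'   `"pv_loop"` (LV pressure-volume diagram; loop area = stroke work) or
#'   `"volumes"` (chamber volumes versus time).
#' @param beats Beat numbers to show (default: the last two complete beats).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wk_sim <- function(object, type = c("pressures", "pv_loop", "volumes"),
                            beats = NULL, ...) {
  type <- match.arg(type)
  n_beats <- max(object$trace$beat)
  beats <- beats %||% seq(max(1, n_beats - 2), n_beats - 1)
  tr <- dplyr::filter(object$trace, .data$beat %in% beats)

  if (type == "pressures") {
    long <- tidyr::pivot_longer(tr[, c("t", "P_V", "P_A", "P_a")],
                                cols = -"t", names_to = "signal",
                                values_to = "pressure")
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$pressure,
                                       colour = .data$signal,
                                       linetype = .data$signal)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "pressure (mmHg)",
                    colour = NULL, linetype = NULL) +
      ggplot2::theme_minimal()
  } else if (type == "pv_loop") {
    ggplot2::ggplot(tr, ggplot2::aes(.data$V_V, .data$P_V,
                                     group = .data$beat)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = expression(V[V] ~ "(ml)"),
                    y = expression(P[V] ~ "(mmHg)")) +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(tr[, c("t", "V_V", "V_A")], cols = -"t",
                                names_to = "chamber", values_to = "volume")
    ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$volume,
                                       colour = .data$chamber)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "volume (ml)", colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Plot a control-versus-scenario comparison
#'
#' Overlays the steady cycles of the two arms, either as pressure traces or
#' as PV loops.
#'
#' @param object A `wk_comparison` object.
#' @param type `"pressures"` or `"pv_loop"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wk_comparison <- function(object, type = c("pressures", "pv_loop"),
                                   ...) {
  type <- match.arg(type)
  last_beat <- function(sim) {
    b <- max(sim$trace$beat) - 1L
    dplyr::filter(sim$trace, .data$beat == b)
  }
  tr <- dplyr::bind_rows(
    control = last_beat(object$control_sim),
    scenario = last_beat(object$scenario_sim),
    .id = "arm"
  )
  tr$t <- tr$t - min(tr$t)
  if (type == "pressures") {
    long <- tidyr::pivot_longer(tr[, c("arm", "t", "P_V", "P_A", "P_a")],
                                cols = c("P_V", "P_A", "P_a"),
                                names_to = "signal", values_to = "pressure")
    ggplot2::ggplot(long, ggplot2::aes(.data$t %% (max(.data$t) + 1e-9),
                                       .data$pressure,
                                       colour = .data$arm,
                                       linetype = .data$signal)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time in beat (s)", y = "pressure (mmHg)",
                    colour = NULL, linetype = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tr, ggplot2::aes(.data$V_V, .data$P_V, colour = .data$arm)) +
      ggplot2::geom_path() +
      ggplot2::labs(x = expression(V[V] ~ "(ml)"),
                    y = expression(P[V] ~ "(mmHg)"), colour = NULL) +
      ggplot2::theme_minimal()
  }
}
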