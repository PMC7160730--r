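# Per-beat hemodynamic indexes extracted from simulated traces: beat
# segmentation from valve events, (dP/dt)max over the isovolumic window,
# PV-loop stroke work and power, arterial pressure extrema.

# 1 mmHg * 1 ml in joules; the single place this conversion lives.
MMHG_ML_TO_J <- 1.33322e-4

wk_trace_events <- function(x) {
  if (inherits(x, "wk_sim")) {
    return(list(trace = x$trace, events = x$events, period = x$period,
                heart_rate = x$heart_rate))
  }
  if (is.data.frame(x) && all(c("t", "mitral_open", "aortic_open") %in% names(x))) {
    tr <- x
    ev <- lapply(c(mitral = "mitral_open", aortic = "aortic_open"), function(col) {
      s <- tr[[col]]
      i <- which(diff(s) != 0) + 1L
      tibble::tibble(t = tr$t[i],
                     action = ifelse(s[i], "open", "close"),
                     V_V = if ("V_V" %in% names(tr)) tr$V_V[i] else NA_real_)
    })
    events <- dplyr::bind_rows(ev, .id = "valve")[, c("t", "valve", "action", "V_V")]
    events <- events[order(events$t), ]
    return(list(trace = tr, events = events, period = NULL, heart_rate = NULL))
  }
  stop("x must be a wk_sim object or a trace data frame with t, mitral_open, aortic_open",
       call. = FALSE)
}

#' Segment one beat into its valve phases
#'
#' Phase boundaries are taken from the valve events of the simulation (or,
#' for a bare trace, from `mitral_open`/`aortic_open` transitions): mitral
#' closure, aortic opening, aortic closure, mitral opening. The isovolumic
#' contraction duration is IVCD = t(aortic open) - t(mitral close) and the
#' ejection phase duration is EPD = t(aortic close) - t(aortic open). Should
#' the mitral valve flutter during diastasis, the closure immediately
#' preceding aortic opening is used.
#'
#' @param x A `wk_sim` object or a trace tibble with valve-state columns.
#' @param beat Beat number (1-based; beats start at each stimulation time).
#' @param period Stimulation period, s; taken from `x` when it is a `wk_sim`.
#' @return One-row tibble: `beat`, `t_mitral_close`, `t_aortic_open`,
#'   `t_aortic_close`, `t_mitral_open`, `IVCD` and `EPD` (ms), and
#'   `degenerate` (TRUE when the aortic valve never opens in the beat, e.g.
#'   at zero contractility).
#' @export
segment_beat <- function(x, beat, period = NULL) {
  te <- wk_trace_events(x)
  period <- period %||% te$period
  if (is.null(period)) stop("period must be supplied for a bare trace", call. = FALSE)
  t0 <- (beat - 1) * period
  t1 <- beat * period
  if (t0 < min(te$trace$t) - 1e-9 || t1 > max(te$trace$t) + 1e-9) {
    stop("beat ", beat, " is not fully contained in the trace", call. = FALSE)
  }
  ev <- te$events
  deg <- function() tibble::tibble(
    beat = beat, t_mitral_close = NA_real_, t_aortic_open = NA_real_,
    t_aortic_close = NA_real_, t_mitral_open = NA_real_,
    IVCD = NA_real_, EPD = NA_real_, degenerate = TRUE)

  ao <- ev$t[ev$valve == "aortic" & ev$action == "open" & ev$t >= t0 & ev$t < t1]
  if (!length(ao)) return(deg())
  t_ao <- ao[1]
  mc <- ev$t[ev$valve == "mitral" & ev$action == "close" & ev$t <= t_ao]
  if (!length(mc)) return(deg())
  t_mc <- mc[length(mc)]
  ac <- ev$t[ev$valve == "aortic" & ev$action == "close" & ev$t > t_ao]
  if (!length(ac)) return(deg())
  t_ac <- ac[1]
  mo <- ev$t[ev$valve == "mitral" & ev$action == "open" & ev$t > t_ac]
  t_mo <- if (length(mo)) mo[1] else NA_real_

  tibble::tibble(
    beat = beat, t_mitral_close = t_mc, t_aortic_open = t_ao,
    t_aortic_close = t_ac, t_mitral_open = t_mo,
    IVCD = 1000 * (t_ao - t_mc), EPD = 1000 * (t_ac - t_ao),
    degenerate = FALSE)
}

#' Peak rate of LV pressure rise
#'
#' Maximum of the centered finite-difference derivative of `P_V` over the
#' isovolumic contraction window of a beat, refined by local quadratic
#' interpolation through the three differences around the discrete maximum.
#' For an external pressure trace (a data frame with columns `t` in s and `P`
#' in mmHg, no valve states) the maximum is taken over the whole series.
#'
#' @param x A `wk_sim` object, a valve-annotated trace tibble, or a
#'   two-column external pressure trace (`t`, `P`).
#' @param beat Beat number (ignored for an external trace).
#' @param period Stimulation period, s, for bare traces.
#' @return (dP/dt)max, mmHg/s.
#' @export
dpdt_max <- function(x, beat = NULL, period = NULL) {
  if (is.data.frame(x) && all(c("t", "P") %in% names(x)) &&
      !("mitral_open" %in% names(x))) {
    return(dpdt_max_window(x$t, x$P))
  }
  te <- wk_trace_events(x)
  seg <- segment_beat(x, beat, period)
  if (seg$degenerate) {
    stop("beat ", beat, " is degenerate (no ejection); no IVC window", call. = FALSE)
  }
  tr <- te$trace
  i <- tr$t >= seg$t_mitral_close - 1e-12 & tr$t <= seg$t_aortic_open + 1e-12
  dpdt_max_window(tr$t[i], tr$P_V[i])
}

dpdt_max_window <- function(t, P) {
  keep <- !duplicated(t)
  t <- t[keep]; P <- P[keep]
  n <- length(t)
  if (n < 3) stop("IVC window shorter than 3 samples", call. = FALSE)
  i <- 2:(n - 1)
  d <- (P[i + 1] - P[i - 1]) / (t[i + 1] - t[i - 1])
  k <- which.max(d)
  if (k == 1 || k == length(d)) return(d[k])
  # quadratic through the three neighbouring difference estimates
  tt <- t[i][(k - 1):(k + 1)]
  dd <- d[(k - 1):(k + 1)]
  co <- stats::coef(stats::lm(dd ~ tt + I(tt^2)))
  if (!is.finite(co[3]) || co[3] >= 0) return(d[k])
  t_star <- -co[2] / (2 * co[3])
  if (t_star < tt[1] || t_star > tt[3]) return(d[k])
  unname(co[1] + co[2] * t_star + co[3] * t_star^2)
}

#' Stroke work and mechanical power from the PV loop
#'
#' Stroke work is the closed area of the beat's pressure-volume loop,
#' computed with the shoelace formula over the `(V_V, P_V)` samples of the
#' beat (1 mmHg·ml = 1.33322e-4 J); LV power is stroke work times heart rate.
#' The traversal direction does not affect the reported magnitude. If the
#' loop is visibly open (a non-steady beat) a warning is emitted and the area
#' includes the implicit closing segment.
#'
#' @param x A `wk_sim` object or valve-annotated trace tibble.
#' @param beat Beat number.
#' @param heart_rate Beats/min; taken from `x` when it is a `wk_sim`.
#' @param period Stimulation period, s, for bare traces.
#' @return One-row tibble: `stroke_work` (J) and `W_LV` (W).
#' @export
pv_loop_power <- function(x, beat, heart_rate = NULL, period = NULL) {
  te <- wk_trace_events(x)
  heart_rate <- heart_rate %||% te$heart_rate
  period <- period %||% te$period
  if (is.null(heart_rate)) stop("heart_rate must be supplied", call. = FALSE)
  if (is.null(period)) period <- 60 / heart_rate
  tr <- te$trace
  i <- tr$t >= (beat - 1) * period - 1e-12 & tr$t <= beat * period + 1e-12
  V <- tr$V_V[i]; P <- tr$P_V[i]
  area <- pv_loop_area(V, P)
  gap <- abs(V[1] - V[length(V)])
  if (gap > 0.02 * max(diff(range(V)), 1e-12)) {
    warning("PV loop of beat ", beat, " is open (volume gap ",
            signif(gap, 3), " ml); area computed with the closing segment",
            call. = FALSE)
  }
  sw <- area * MMHG_ML_TO_J
  tibble::tibble(stroke_work = sw, W_LV = sw * heart_rate / 60)
}

# Shoelace area of the (V, P) polygon, orientation-independent.
pv_loop_area <- function(V, P) {
  n <- length(V)
  j <- c(2:n, 1)
  abs(sum(V * P[j] - V[j] * P)) / 2
}

#' Systolic and diastolic aortic pressure of a beat
#'
#' @param x A `wk_sim` object or valve-annotated trace tibble.
#' @param beat Beat number.
#' @param period Stimulation period, s, for bare traces.
#' @return One-row tibble: `P_a_s`, `P_a_d` (max and min of `P_a` over the
#'   beat), mmHg.
#' @export
arterial_extrema <- function(x, beat, period = NULL) {
  te <- wk_trace_events(x)
  period <- period %||% te$period
  if (is.null(period)) stop("period must be supplied for a bare trace", call. = FALSE)
  tr <- te$trace
  i <- tr$t >= (beat - 1) * period - 1e-12 & tr$t <= beat * period + 1e-12
  tibble::tibble(P_a_s = max(tr$P_a[i]), P_a_d = min(tr$P_a[i]))
}

#' Per-beat hemodynamic indexes
#'
#' Extracts, for every complete beat of a simulation, the indexes used to
#' characterize LV performance: isovolumic contraction and ejection phase
#' durations, (dP/dt)max, end-diastolic and end-systolic volumes (at mitral
#' and aortic closure respectively), stroke volume, ejection fraction,
#' cardiac output, systolic/diastolic aortic pressure, stroke work and LV
#' power. The volume identities `SV = V_Ved - V_Ves`,
#' `EF = 100 * SV / V_Ved` and `CO = SV * HR` hold exactly by construction.
#'
#' @param x A `wk_sim` object.
#' @param beats Integer vector of beat numbers (default: all complete beats).
#' @return A tibble with one row per beat; degenerate beats (no ejection)
#'   carry `degenerate = TRUE` and NA indexes.
#' @export
beat_metrics <- function(x, beats = NULL) {
  stopifnot(inherits(x, "wk_sim"))
  n_beats <- floor(x$duration / x$period + 1e-9)
  beats <- beats %||% seq_len(n_beats)
  ev <- x$events
  purrr::map_dfr(beats, function(b) {
    seg <- segment_beat(x, b)
    ext <- arterial_extrema(x, b)
    if (seg$degenerate) {
      return(tibble::tibble(
        beat = b, IVCD = NA_real_, EPD = NA_real_, dPdt_max = NA_real_,
        V_Ved = NA_real_, V_Ves = NA_real_, SV = NA_real_, EF = NA_real_,
        CO = NA_real_, P_a_s = ext$P_a_s, P_a_d = ext$P_a_d,
        stroke_work = NA_real_, W_LV = NA_real_, degenerate = TRUE))
    }
    v_ed <- ev$V_V[ev$valve == "mitral" & ev$action == "close" &
                     abs(ev$t - seg$t_mitral_close) < 1e-9][1]
    v_es <- ev$V_V[ev$valve == "aortic" & ev$action == "close" &
                     abs(ev$t - seg$t_aortic_close) < 1e-9][1]
    sv <- v_ed - v_es
    # transitional beats are naturally open loops; the open-loop warning is
    # reserved for direct pv_loop_power() calls
    pw <- suppressWarnings(pv_loop_power(x, b))
    dpdt <- tryCatch(dpdt_max(x, b), error = function(e) NA_real_)
    tibble::tibble(
      beat = b, IVCD = seg$IVCD, EPD = seg$EPD,
      dPdt_max = dpdt,
      V_Ved = v_ed, V_Ves = v_es, SV = sv, EF = 100 * sv / v_ed,
      CO = sv * x$heart_rate,
      P_a_s = ext$P_a_s, P_a_d = ext$P_a_d,
      stroke_work = pw$stroke_work, W_LV = pw$W_LV,
      degenerate = FALSE)
  })
}

#' Read an external pressure trace
#'
#' Reads a two-column CSV (time in s, pressure in mmHg), e.g. a digitized
#' clinical LV pressure trace, for comparison against simulated traces.
#' Metric extraction for such traces is limited to [dpdt_max()].
#'
#' @param path CSV file path; the first two columns are used.
#' @return A tibble with columns `t` and `P`.
#' @export
read_pressure_trace <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected a two-column time/pressure CSV", call. = FALSE)
  out <- tibble::tibble(t = as.numeric(df[[1]]), P = as.numeric(df[[2]]))
  if (any(!is.finite(out$t)) || any(!is.finite(out$P))) {
    stop("non-numeric values in pressure trace ", path, call. = FALSE)
  }
  if (any(diff(out$t) <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  out
}
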