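# Hemodynamic index extraction: beat segmentation, (dP/dt)max, PV-loop work,
# arterial extrema, identities.

# A synthetic one-beat trace tracing a rectangular PV loop (40-120 ml,
# 80-120 mmHg), valve-annotated so the trace-level code paths work.
rect_trace <- function(n_edge = 50) {
  V <- c(seq(120, 40, length.out = n_edge),  # ejection at top pressure
         rep(40, n_edge),
         seq(40, 120, length.out = n_edge),  # filling at bottom pressure
         rep(120, n_edge))
  P <- c(rep(120, n_edge), seq(120, 80, length.out = n_edge),
         rep(80, n_edge), seq(80, 120, length.out = n_edge))
  n <- length(V)
  tibble::tibble(t = seq(0, 60 / 72, length.out = n), V_V = V, P_V = P,
                 P_a = 100, mitral_open = FALSE, aortic_open = FALSE)
}

test_that("a linear pressure ramp has its exact slope as (dP/dt)max", {
  tr <- tibble::tibble(t = seq(0, 0.05, by = 1e-3), P = 1600 * seq(0, 0.05, by = 1e-3))
  expect_equal(dpdt_max(tr), 1600, tolerance = 1e-9)
  expect_error(dpdt_max(tibble::tibble(t = c(0, 1e-3), P = c(0, 1))),
               "3 samples")
})

test_that("rectangular PV loop area converts exactly to joules and watts", {
  pw <- pv_loop_power(rect_trace(), beat = 1, heart_rate = 72)
  expect_equal(pw$stroke_work, 3200 * 1.33322e-4, tolerance = 1e-6)
  expect_equal(pw$stroke_work, 0.4266, tolerance = 1e-3)
  expect_equal(pw$W_LV, pw$stroke_work * 1.2, tolerance = 1e-12)
  # traversal direction must not change the reported magnitude
  rev_tr <- rect_trace()[rev(seq_len(nrow(rect_trace()))), ]
  rev_tr$t <- sort(rev_tr$t)
  pw2 <- pv_loop_power(rev_tr, beat = 1, heart_rate = 72)
  expect_equal(pw2$stroke_work, pw$stroke_work, tolerance = 1e-9)
})

test_that("arterial extrema report max and min over the beat", {
  tr <- rect_trace()
  tr$P_a <- 100 + 20 * sin(2 * pi * tr$t / max(tr$t))
  ex <- arterial_extrema(tr, 1, period = 60 / 72)
  expect_equal(ex$P_a_s, max(tr$P_a))
  expect_equal(ex$P_a_d, min(tr$P_a))
  tr$P_a <- 90
  ex <- arterial_extrema(tr, 1, period = 60 / 72)
  expect_equal(ex$P_a_s, ex$P_a_d)
})

test_that("beat segmentation reproduces valve event times and durations", {
  sim <- control_sim()
  seg <- segment_beat(sim, 70)
  expect_false(seg$degenerate)
  expect_equal(seg$IVCD, 1000 * (seg$t_aortic_open - seg$t_mitral_close))
  expect_equal(seg$EPD, 1000 * (seg$t_aortic_close - seg$t_aortic_open))
  expect_true(seg$t_mitral_close < seg$t_aortic_open &&
              seg$t_aortic_open < seg$t_aortic_close &&
              seg$t_aortic_close < seg$t_mitral_open)
  # trace-derived segmentation (valve-state transitions) agrees to within the
  # sampling interval
  seg_tr <- segment_beat(sim$trace, 70, period = sim$period)
  expect_equal(seg_tr$IVCD, seg$IVCD, tolerance = 2 * 1000 * sim$output_dt / seg$IVCD)
})

test_that("a zero-contractility beat is flagged degenerate", {
  p <- wk_params(K_Vc = 0, P_Ac_max = 0, b_A = 1e-12)
  sim <- cached("decay20", wk_simulate(p, duration = 20))
  seg <- segment_beat(sim, 10)
  expect_true(seg$degenerate)
  expect_error(dpdt_max(sim, 10), "degenerate")
  m <- beat_metrics(sim, beats = 10L)
  expect_true(m$degenerate)
  expect_true(is.na(m$EF))
})

test_that("volume identities hold exactly on every steady beat", {
  m <- control_metrics()
  m <- m[m$beat > 5, ]
  expect_equal(m$SV, m$V_Ved - m$V_Ves, tolerance = 1e-12)
  expect_equal(m$EF, 100 * m$SV / m$V_Ved, tolerance = 1e-12)
  expect_equal(m$CO, m$SV * 72, tolerance = 1e-12)
  expect_true(all(m$P_a_s > m$P_a_d))
  expect_true(all(m$IVCD > 0 & m$EPD > 0))
})

test_that("loop-area power equals the time-integral of P dV within 0.5%", {
  sim <- control_sim()
  tr <- sim$trace[sim$trace$beat == 70, ]
  pw <- pv_loop_power(sim, 70)
  # trapezoid of -P_V * dV_V over the closed cycle
  work_int <- -sum((tr$P_V[-1] + tr$P_V[-nrow(tr)]) / 2 * diff(tr$V_V)) *
    1.33322e-4
  expect_equal(pw$stroke_work, abs(work_int), tolerance = 5e-3)
})

test_that("metrics are stable under 2x time-grid refinement", {
  coarse <- cached("refine_coarse", wk_simulate(duration = 15))
  fine <- cached("refine_fine", wk_simulate(duration = 15, output_dt = 5e-4))
  mc <- beat_metrics(coarse, beats = 14L)
  mf <- beat_metrics(fine, beats = 14L)
  for (col in c("dPdt_max", "P_a_s", "P_a_d", "stroke_work")) {
    expect_lt(abs(mf[[col]] - mc[[col]]) / mc[[col]], 1e-3)
  }
})

test_that("external pressure traces round-trip through CSV and yield dP/dt", {
  tf <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 0.2, by = 1e-3)
  P <- 80 * (1 - cos(pi * t / 0.2)) / 2
  utils::write.csv(data.frame(time_s = t, pressure_mmHg = P), tf,
                   row.names = FALSE)
  tr <- read_pressure_trace(tf)
  expect_equal(nrow(tr), length(t))
  # max slope of the raised cosine: 80 * pi / (2 * 0.2)
  expect_equal(dpdt_max(tr), 80 * pi / 0.4, tolerance = 1e-3)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,P\n0,1\n0,2", bad)
  expect_error(read_pressure_trace(bad), "increasing")
})
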