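# Constitutive laws of the left ventricle and atrium.

test_that("passive LV pressure is the anchored cubic", {
  p <- wk_params(P_Ved_M = 40, V_Ved_M = 200)
  expect_equal(passive_lv_pressure(0, p), 0)
  expect_equal(passive_lv_pressure(200, p), 40)         # anchor point
  expect_equal(passive_lv_pressure(114, p), 40 * (114 / 200)^3, tolerance = 1e-12)
  V <- seq(1, 250, by = 7)
  expect_true(all(diff(passive_lv_pressure(V, p)) > 0))  # monotone
  expect_error(passive_lv_pressure(-1, p), "V must be")
})

test_that("isovolumic maximum pressure peaks at V_Ved_M", {
  p <- wk_params()
  expect_equal(isovolumic_max_pressure(200, p), 275)
  expect_equal(isovolumic_max_pressure(0, p), 0)         # 275 - b_V * 200^2
  expect_equal(isovolumic_max_pressure(114, p), 275 - 0.006875 * 86^2,
               tolerance = 1e-12)
  V <- seq(0, 400, by = 10)
  expect_true(all(isovolumic_max_pressure(V, p) <= 275 + 1e-12))
})

test_that("area factor matches the thick-sphere geometry", {
  # V_m/V_V = 7 gives h/r = 1, A_V = 3 exactly
  expect_equal(area_factor(140, 20), 3, tolerance = 1e-12)
  # geometric round trip: build volumes from random (r, h), recover 2h/r + (h/r)^2
  set.seed(42)
  for (i in 1:25) {
    r <- runif(1, 0.5, 5); h <- runif(1, 0.1, 3)
    V_V <- 4 / 3 * pi * r^3
    V_m <- 4 / 3 * pi * ((r + h)^3 - r^3)
    expect_equal(area_factor(V_m, V_V), 2 * (h / r) + (h / r)^2,
                 tolerance = 1e-10)
  }
  # root of the cubic in h/r reproduces V_m/V_V
  set.seed(7)
  for (i in 1:25) {
    V_m <- runif(1, 50, 400); V_V <- runif(1, 10, 250)
    x <- (V_m / V_V + 1)^(1 / 3) - 1
    expect_equal(3 * x + 3 * x^2 + x^3, V_m / V_V, tolerance = 1e-10)
  }
  # membrane limit and strict monotone decrease in V_V
  expect_lt(area_factor(1e-6, 100), 1e-6)
  V <- seq(20, 200, by = 5)
  expect_true(all(diff(area_factor(150, V)) < 0))
  expect_error(area_factor(150, 0), "singular")
})

test_that("LV twitch activation peaks at 1, is symmetric, and is compact", {
  p <- wk_params()
  expect_equal(lv_activation(p$t_Vmax, p), 1)
  d <- seq(0.01, 0.4, by = 0.01)
  expect_equal(lv_activation(p$t_Vmax + d, p), lv_activation(p$t_Vmax - d, p))
  # direct evaluation at delta = 0.15 s with the published constants
  oracle <- exp(-(5.68722 * 0.15)^2.0224 - (5.2270 * 0.15)^9.11538)
  expect_equal(lv_activation(p$t_Vmax + 0.15, p), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.434, tolerance = 1e-3)
  # near-complete relaxation well inside one 0.8333 s cycle
  far <- abs(seq(0, 0.8333, by = 1e-3) - p$t_Vmax) > 0.35
  expect_true(all(lv_activation(seq(0, 0.8333, by = 1e-3), p)[far] < 0.01))
})

test_that("ejection de-rating is 1 at end-diastole and falls with volume", {
  p <- wk_params()
  expect_equal(ejection_derating(114, 114, p), 1)
  expect_equal(ejection_derating(150, 114, p), 1)   # filling clamp
  oracle <- 1 - (-log(36 / 114))^0.35 / 1.355
  expect_equal(ejection_derating(36, 114, p), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.2244, tolerance = 1e-3)
  expect_lt(ejection_derating(0.3 * 114, 114, p),
            ejection_derating(0.6 * 114, 114, p))
})

test_that("LV pressure recovers its limiting curves and is affine in K_Vc", {
  p <- wk_params()
  # zero activation (t far from t_Vmax) -> passive cubic
  expect_equal(lv_pressure(0, 90, 114, p), passive_lv_pressure(90, p),
               tolerance = 1e-9)
  # full activation at V = V_Ved -> isovolumic maximum (area ratio = 1)
  expect_equal(lv_pressure(p$t_Vmax, 114, 114, p),
               isovolumic_max_pressure(114, p), tolerance = 1e-9)
  # affine in the contractility coefficient
  pv <- function(k) lv_pressure(0.25, 90, 114, wk_params(K_Vc = k))
  expect_equal(pv(0.5), pv(0) + 0.5 * (pv(1) - pv(0)), tolerance = 1e-10)
  expect_equal(pv(0.982) - pv(0), 0.982 * (pv(1) - pv(0)), tolerance = 1e-10)
  # continuity in t and isovolumic bounds at V = V_Ved
  t <- seq(0, 0.8333, by = 1e-3)
  P <- lv_pressure(t, 114, 114, p)
  expect_true(all(abs(diff(P)) < 25))   # no jumps at 1 ms resolution
  expect_true(all(P >= passive_lv_pressure(114, p) - 1e-9))
  expect_true(all(P <= isovolumic_max_pressure(114, p) + 1e-9))
})

test_that("wall stress times the area factor recovers cavity pressure", {
  p <- wk_params()
  for (V in c(40, 80, 114)) {
    expect_equal(lv_wall_stress(0.3, V, 114, p) * area_factor(p$V_m, V),
                 lv_pressure(0.3, V, 114, p), tolerance = 1e-12)
  }
})

test_that("atrial pressure combines the quintic and the gated active term", {
  p <- wk_params()
  expect_equal(la_pressure(0.5, 100, p), 30, tolerance = 1e-9)  # f_Ac ~ 0
  expect_equal(la_pressure(p$t_Amax, 100, p), 37.5)             # peak twitch
  expect_equal(la_pressure(0.5, 0, p), 0, tolerance = 1e-9)
  # active term vanishes ~50 ms after the atrial peak
  expect_lt(la_activation(p$t_Amax + 0.06, p), 0.01)
})

test_that("constitutive outputs are deterministic pure functions", {
  p <- wk_params()
  args <- list(0.21, 97.3, 112.8)
  expect_identical(do.call(lv_pressure, c(args, list(p))),
                   do.call(lv_pressure, c(args, list(p))))
  expect_identical(la_pressure(0.13, 88.2, p), la_pressure(0.13, 88.2, p))
})
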