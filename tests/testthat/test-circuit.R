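# Circuit assembly: diode valves, viscoelastic node algebra, closed-loop
# right-hand side.

random_state <- function() {
  c(V_A = runif(1, 20, 120), V_V = runif(1, 30, 180),
    q_a1 = runif(1, 2, 12), q_a2 = runif(1, 60, 180),
    q_v = runif(1, 300, 600), Q_a = runif(1, -50, 600),
    V_Ved_latch = runif(1, 90, 150))
}

test_that("valve resistance is a pressure-controlled diode", {
  expect_equal(valve_resistance(5, 0.012), 0.012)
  expect_equal(valve_resistance(-5, 0.025), 1e4)
  expect_equal(valve_resistance(0, 0.012), 1e4)   # tie broken toward closed
  expect_equal(valve_resistance(c(1, -1), 0.025, 2e4), c(0.025, 2e4))
})

test_that("node pressures solve the viscoelastic algebra", {
  p <- wk_params()
  # equal-pressure, zero-flow state: resistive terms vanish
  st <- c(q_a1 = p$C_a1 * 5, q_a2 = p$C_a2 * 5, q_v = 350, Q_a = 0)
  np <- node_pressures(st, p)
  expect_equal(np$P_v, 5)
  expect_equal(np$P_arc, 5, tolerance = 1e-12)
  expect_equal(np$P_a, 5, tolerance = 1e-12)
  # steady DC chain at flow Q: P_arc = P_v + Q(R_a + R_p), P_a = P_v + Q R_p
  Q <- 94; P_v <- 5
  st <- c(q_a1 = p$C_a1 * (P_v + Q * (p$R_a + p$R_p)),
          q_a2 = p$C_a2 * (P_v + Q * p$R_p),
          q_v = P_v * p$C_v, Q_a = Q)
  np <- node_pressures(st, p)
  expect_equal(np$P_arc, P_v + Q * (p$R_a + p$R_p), tolerance = 1e-10)
  expect_equal(np$P_a, P_v + Q * p$R_p, tolerance = 1e-10)
})

test_that("the closed loop conserves volume exactly (Kirchhoff)", {
  p <- wk_params()
  set.seed(11)
  for (i in 1:20) {
    st <- random_state()
    for (valves in list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE))) {
      dy <- wk_derivatives(runif(1, 0, 0.8), st, p,
                           mitral_open = valves[1], aortic_open = valves[2])[[1]]
      vol_idx <- c("V_A", "V_V", "q_a1", "q_a2", "q_v")
      expect_lt(abs(sum(dy[vol_idx])), 1e-9 * max(abs(dy[vol_idx])))
    }
  }
})

test_that("compiled and reference right-hand sides agree", {
  p <- wk_params()
  set.seed(23)
  for (i in 1:15) {
    st <- random_state()
    t <- runif(1, 0, 60)
    mo <- runif(1) > 0.5; ao <- runif(1) > 0.5
    r_ref <- wk_derivatives(t, st, p, mitral_open = mo, aortic_open = ao)
    r_c <- wkheart:::wk_rhs_c(t, st, p, mitral_open = mo, aortic_open = ao)
    expect_equal(r_c[[1]], r_ref[[1]], tolerance = 1e-10)
    expect_equal(r_c[[2]], r_ref[[2]], tolerance = 1e-10)
  }
})

test_that("aortic flow obeys the inertance law and stalls for large L", {
  p <- wk_params()
  st <- random_state()
  r <- wk_derivatives(0.3, st, p, mitral_open = FALSE, aortic_open = TRUE)
  np <- node_pressures(st, p)
  expect_equal(r[[1]][["Q_a"]],
               (r[[2]][["P_V"]] - np$P_arc - p$R_Da * st[["Q_a"]]) / p$L,
               tolerance = 1e-9)
  pL <- wk_params(L = 0.3)  # 1000x inertance
  rL <- wk_derivatives(0.3, st, pL, mitral_open = FALSE, aortic_open = TRUE)
  expect_equal(rL[[1]][["Q_a"]] * 1000, r[[1]][["Q_a"]], tolerance = 1e-9)
})

test_that("with both valves closed and equal pressures all flows are leaks", {
  p <- wk_params()
  # construct a state where P_V = P_A = P_arc = P_a = P_v = P*
  Pstar <- 8
  d <- wk_derived(p)
  st <- c(V_A = (Pstar / d$a_A)^(1 / 5), V_V = (Pstar / d$a_V)^(1 / 3),
          q_a1 = p$C_a1 * Pstar, q_a2 = p$C_a2 * Pstar, q_v = p$C_v * Pstar,
          Q_a = 0, V_Ved_latch = (Pstar / d$a_V)^(1 / 3))
  p0 <- wk_params(K_Vc = 0, P_Ac_max = 0)
  r <- wk_derivatives(0.5, st, p0, mitral_open = FALSE, aortic_open = FALSE)
  expect_true(all(abs(r[[1]][c("V_A", "V_V", "q_a1", "q_a2", "q_v")]) < 1e-6))
})

test_that("zero contractility decays to the no-flow equilibrium", {
  # b_A ~ 0 removes the volume-dependent part of the gated atrial term too
  p <- wk_params(K_Vc = 0, P_Ac_max = 0, b_A = 1e-12)
  sim <- cached("decay20", wk_simulate(p, duration = 20))
  last <- sim$trace[sim$trace$t > 19.5, ]
  # independent oracle: distribute total volume at a common pressure P*
  d <- wk_derived(p)
  f <- function(P) {
    (P / d$a_V)^(1 / 3) + (P / d$a_A)^(1 / 5) +
      P * (p$C_a1 + p$C_a2 + p$C_v) - p$total_blood_volume
  }
  Pstar <- stats::uniroot(f, c(0.1, 30), tol = 1e-10)$root
  expect_equal(mean(last$P_v), Pstar, tolerance = 0.02)
  expect_lt(max(abs(last$Q_a)), 0.5)
  expect_lt(max(abs(last$Q_AV)), 2)
  expect_lt(diff(range(last$P_V)), 0.5)
})
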