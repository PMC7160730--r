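# Shared fixtures: simulations are expensive enough to be worth memoizing
# across test files (test_dir runs all files in one session).

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# Steady control run at package defaults (60 s, 72 beats/min).
control_sim <- function() {
  cached("control60", wk_simulate(duration = 60))
}

control_metrics <- function() {
  cached("control60_metrics", beat_metrics(control_sim()))
}

# Steady run with the reduced-TCV activation parameterization.
tcv_sim <- function() {
  cached("tcv60",
         wk_simulate(wk_params(t_Vmax = 0.3885, K_Vc = 0.982), duration = 60))
}

# Short run for structural checks.
short_sim <- function() {
  cached("short10", wk_simulate(duration = 10))
}

# Published control and 50%-TCV steady-cycle reference values.
ref_control <- c(P_a_s = 125, P_a_d = 80, dPdt_max = 1783, V_Ved = 114,
                    V_Ves = 36, IVCD = 60, EPD = 211, EF = 69, CO = 5653,
                    W_LV = 1.51)
ref_tcv <- c(P_a_s = 122, P_a_d = 79, dPdt_max = 1751, V_Ved = 114,
                V_Ves = 37, IVCD = 71, EPD = 213, EF = 67, CO = 5538,
                W_LV = 1.45)
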