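# Configuration file handling: one flat YAML namespace whose keys are the
# model symbol names (R_p, C_v, t_Vmax, K_Vc, ...) plus the simulation
# settings and an optional scenario list.

.wk_sim_keys <- c("heart_rate", "duration", "abs_tol", "rel_tol", "output_dt")

.wk_sim_defaults <- list(heart_rate = 72, duration = 60, abs_tol = 1e-5,
                         rel_tol = 1e-7, output_dt = 1e-3)

#' Load a model configuration
#'
#' Reads a flat YAML configuration. Every key is optional: an empty file
#' yields the full default parameterization. Model parameter keys mirror the
#' symbol names of [wk_params()]; simulation keys are `heart_rate`,
#' `duration`, `abs_tol`, `rel_tol`, `output_dt`; an optional `scenarios`
#' block maps scenario names to either `{t_Vmax, K_Vc}` overrides or
#' `{target_IVCD, target_dPdt_max}` calibration targets. Unknown keys are
#' rejected, naming the offender.
#'
#' @param path Path to a YAML file.
#' @param echo If TRUE, write the effective parameter values to the console
#'   (via `message()`), making a run reproducible from its log alone.
#' @return A list with elements `params` ([wk_params]), `simulation` (named
#'   list of the five simulation settings) and `scenarios` (possibly empty
#'   list of [wk_scenario] objects).
#' @export
read_wk_config <- function(path, echo = FALSE) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping", call. = FALSE)

  known <- c(names(wk_default_params()), .wk_sim_keys, "scenarios")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  par_over <- raw[intersect(names(raw), names(wk_default_params()))]
  params <- do.call(wk_params, par_over)

  simulation <- .wk_sim_defaults
  for (k in intersect(names(raw), .wk_sim_keys)) simulation[[k]] <- as.numeric(raw[[k]])
  if (simulation$duration <= 0 || simulation$heart_rate <= 0 ||
      simulation$abs_tol <= 0 || simulation$rel_tol <= 0 ||
      simulation$output_dt <= 0) {
    stop("simulation settings must be positive", call. = FALSE)
  }

  scenarios <- list()
  for (nm in names(raw$scenarios)) {
    s <- raw$scenarios[[nm]]
    ok <- setdiff(names(s), c("target_IVCD", "target_dPdt_max", "t_Vmax", "K_Vc"))
    if (length(ok)) {
      stop("unknown key(s) in scenario '", nm, "': ", paste(ok, collapse = ", "),
           call. = FALSE)
    }
    scenarios[[nm]] <- wk_scenario(nm, target_IVCD = s$target_IVCD,
                                   target_dPdt_max = s$target_dPdt_max,
                                   t_Vmax = s$t_Vmax, K_Vc = s$K_Vc)
  }

  if (echo) {
    kv <- c(unlist(unclass(params)), unlist(simulation))
    message("effective configuration:\n",
            paste0("  ", names(kv), " = ", format(kv, digits = 10), collapse = "\n"))
  }
  list(params = params, simulation = simulation, scenarios = scenarios)
}

#' Write a model configuration
#'
#' Serializes a configuration (as returned by [read_wk_config()], or a bare
#' [wk_params] object) back to flat YAML; `read_wk_config()` on the result is
#' an identity.
#'
#' @param config A configuration list or a [wk_params] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_wk_config <- function(config, path) {
  if (inherits(config, "wk_params")) {
    config <- list(params = config, simulation = .wk_sim_defaults,
                   scenarios = list())
  }
  flat <- c(unclass(config$params), config$simulation)
  if (length(config$scenarios)) {
    flat$scenarios <- lapply(config$scenarios, function(s) {
      out <- s[c("target_IVCD", "target_dPdt_max", "t_Vmax", "K_Vc")]
      out[!vapply(out, is.null, logical(1))]
    })
  }
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Write a simulated trace to CSV
#'
#' One row per sample with columns `t`, `P_V`, `P_A`, `P_arc`, `P_a`, `P_v`,
#' `V_V`, `V_A`, `Q_a`, `mitral_open`, `aortic_open`.
#'
#' @param sim A `wk_sim` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "wk_sim"))
  cols <- c("t", "P_V", "P_A", "P_arc", "P_a", "P_v", "V_V", "V_A", "Q_a",
            "mitral_open", "aortic_open")
  utils::write.csv(as.data.frame(sim$trace[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' Write per-beat metrics to JSON
#'
#' @param sim A `wk_sim` object.
#' @param path Output JSON path; the report is keyed by beat number.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(sim, path) {
  stopifnot(inherits(sim, "wk_sim"))
  m <- beat_metrics(sim)
  keyed <- stats::setNames(
    lapply(seq_len(nrow(m)), function(i) as.list(m[i, setdiff(names(m), "beat")])),
    paste0("beat_", m$beat)
  )
  jsonlite::write_json(keyed, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
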