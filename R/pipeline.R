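# Pipeline driver: validated config, stage orchestration, results table, log.

pipeline_schema <- list(
  seed = NULL,
  stages = NULL,
  acquisition = c("delta_ms", "Delta_ms", "tau_ms", "TL_ms", "nucleus"),
  buffer = c("Na_buffer_mM"),
  predicted_Ncation = NULL,
  fitting = c("weighting", "bootstrap"),
  calibrate = c("file", "D_reference_1e5_cm2_s"),
  decay = c("file"),
  quantify = c("file", "r_buffer"),
  exchange = c("file", "D_f_1e5_cm2_s", "a"),
  competition = c("file", "Na_total_mM", "T_capacity_mM",
                  "D_f_1e5_cm2_s", "D_b_1e5_cm2_s"),
  release = c("D_PD_1e5_cm2_s", "D_D_1e5_cm2_s", "D_f_1e5_cm2_s",
              "se_D_PD_1e5_cm2_s", "se_D_D_1e5_cm2_s", "se_D_f_1e5_cm2_s",
              "n_c", "p_complex", "P_total_mM", "DNA_total_mM", "Kd_mM"),
  lineshape = c("file", "init_centers_hz", "r2_file", "R_f", "a")
)

#' Validate a pipeline configuration
#'
#' The configuration is a named list (typically parsed from a YAML file)
#' with one section per pipeline stage plus shared sections for acquisition
#' timing, buffer composition and fitting options. Every key is checked
#' against the known schema before any computation; unknown keys are an
#' error, which catches typos that would otherwise silently disable an
#' option.
#'
#' @param config named list
#' @return the validated config, invisibly classed `pipeline_config`
#' @export
pipeline_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(config)) {
    allowed <- pipeline_schema[[section]]
    if (is.null(allowed)) next
    if (!is.list(config[[section]])) {
      stop("config section '", section, "' must be a mapping", call. = FALSE)
    }
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad) > 0L) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Read and validate a YAML pipeline configuration file
#'
#' @param path YAML file path
#' @return a validated `pipeline_config`
#' @export
read_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_acquisition <- function(config) {
  acq <- config$acquisition
  if (is.null(acq)) stop("config section 'acquisition' is required for decay stages",
                         call. = FALSE)
  pulse_params(delta = acq$delta_ms * 1e-3,
               Delta = acq$Delta_ms * 1e-3,
               tau = if (is.null(acq$tau_ms)) 0.2e-3 else acq$tau_ms * 1e-3,
               TL = if (is.null(acq$TL_ms)) 0 else acq$TL_ms * 1e-3,
               nucleus = if (is.null(acq$nucleus)) "23Na" else acq$nucleus)
}

result_row <- function(parameter, estimate, se, units, method, n) {
  if (is.null(se) || length(se) == 0L || is.na(se)) se <- NA_real_
  data.frame(parameter = parameter, estimate = estimate, se = se,
             units = units, method = method, n = n,
             stringsAsFactors = FALSE)
}

#' Run the analysis pipeline from a validated configuration
#'
#' Executes the requested stages in dependency order (decay, calibrate,
#' quantify, exchange, competition, release, lineshape), writes a results
#' table (`results.csv`) and a plain-text log (`log.txt`) to `out_dir`, and
#' returns the report. Any stage failure aborts with the stage name;
#' results of stages completed before the failure are preserved in the
#' output directory.
#'
#' Assumption flags recorded in the log: a fixed quantification intercept
#' (when used), the counterion-condensation assumption that the atmosphere
#' capacity n_c equals the single-cation ion count a, and equal total
#' cation concentration in compared release samples.
#'
#' @param config a [pipeline_config()] (or plain list, validated on entry)
#' @param out_dir output directory, created if needed
#' @return list of per-stage results, invisibly; also written to disk
#' @export
run_pipeline <- function(config, out_dir = tempfile("iondiff_run_")) {
  config <- pipeline_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  results_path <- file.path(out_dir, "results.csv")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  flush_log <- function() writeLines(log_lines, log_path)

  stages <- config$stages
  if (is.null(stages)) {
    stages <- intersect(c("decay", "calibrate", "quantify", "exchange",
                          "competition", "release", "lineshape"),
                        names(config))
  }
  order_all <- c("decay", "calibrate", "quantify", "exchange",
                 "competition", "release", "lineshape")
  stages <- order_all[order_all %in% stages]
  Na_buffer <- if (!is.null(config$buffer$Na_buffer_mM)) {
    conc_to_si(config$buffer$Na_buffer_mM)
  } else 0.020
  boot <- if (!is.null(config$fitting$bootstrap)) config$fitting$bootstrap else 0
  seed <- if (!is.null(config$seed)) config$seed else 1L
  note("pipeline start: stages = %s, seed = %d", paste(stages, collapse = ","), seed)

  report <- list()
  rows <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      note("stage '%s' FAILED: %s", name, conditionMessage(e))
      flush_log()
      if (length(rows) > 0L) write_table(do.call(rbind, rows), results_path)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  for (stage in stages) {
    if (stage == "decay") {
      run_stage("decay", function() {
        params <- config_acquisition(config)
        series <- read_decay_table(config$decay$file, params)
        fit <- fit_diffusion(series)
        report$decay <<- fit
        rows$decay <<- result_row("D_app", diffusion_from_si(fit$D),
                                  diffusion_from_si(fit$se_D),
                                  "1e-5 cm^2/s", "nls BPP-LED", fit$n_points)
        note("decay: D_app = %.3f (SE %.3f) x 1e-5 cm^2/s, n = %d",
             diffusion_from_si(fit$D), diffusion_from_si(fit$se_D), fit$n_points)
      })
    } else if (stage == "calibrate") {
      run_stage("calibrate", function() {
        params <- config_acquisition(config)
        series <- read_decay_table(config$calibrate$file, params)
        cal <- calibrate_gradient(series,
                                  diffusion_to_si(config$calibrate$D_reference_1e5_cm2_s))
        report$calibrate <<- cal
        rows$calibrate <<- result_row("gradient_scale", cal$scale, NA,
                                      "", "sqrt(D_fit/D_ref)", cal$fit$n_points)
        note("calibrate: gradient scale factor s = %.5f", cal$scale)
      })
    } else if (stage == "quantify") {
      run_stage("quantify", function() {
        tab <- read_quant_table(config$quantify$file)
        Na_tot <- na_total(tab$r_sample, config$quantify$r_buffer, Na_buffer)
        fit <- fit_ion_excess(tab$C_M, Na_tot, Na_buffer = Na_buffer)
        report$quantify <<- fit
        rows$quantify <<- result_row("a", fit$a, fit$se_a, "ions per macromolecule",
                                     "ols", fit$n_points)
        note("quantify: a (ion excess for single-cation solutions) = %.2f (SE %.2f)",
             fit$a, fit$se_a)
        if (!is.null(config$predicted_Ncation)) {
          pct <- percent_vs_prediction(fit$a, config$predicted_Ncation)
          report$quantify_pct <<- pct
          note("quantify: %.1f%% vs predicted_Ncation = %.1f",
               pct, config$predicted_Ncation)
        }
      })
    } else if (stage == "exchange") {
      run_stage("exchange", function() {
        tab <- read_titration_table(config$exchange$file, "C_M_mM")
        D_f <- diffusion_to_si(config$exchange$D_f_1e5_cm2_s)
        a <- config$exchange$a
        fit <- fit_Db(tab$x, tab$D_app, D_f, a, Na_buffer,
                      bootstrap = boot, seed = seed)
        ent <- entropy_of_release(fit$estimate, D_f)
        report$exchange <<- list(fit = fit, entropy = ent)
        rows$exchange <<- rbind(
          result_row("D_b", diffusion_from_si(fit$estimate),
                     diffusion_from_si(fit$se), "1e-5 cm^2/s",
                     "nls 1-parameter", length(tab$x)),
          result_row("dS_release", ent$dS_per_ion_eu, NA, "eu per ion",
                     "-R ln(D_b/D_f)", length(tab$x)))
        note("exchange: D_b = %.3f (SE %.3f) x 1e-5 cm^2/s; D_b/D_f = %.2f; dS = %.2f eu/ion",
             diffusion_from_si(fit$estimate), diffusion_from_si(fit$se),
             ent$ratio, ent$dS_per_ion_eu)
        note("assumption: D_f and a fixed at measured values (not fitted)")
      })
    } else if (stage == "competition") {
      run_stage("competition", function() {
        cc <- config$competition
        tab <- read_titration_table(cc$file, "KCl_mM")
        fit <- fit_Q(tab$x, tab$D_app,
                     Na_total = conc_to_si(cc$Na_total_mM),
                     T_capacity = conc_to_si(cc$T_capacity_mM),
                     D_f = diffusion_to_si(cc$D_f_1e5_cm2_s),
                     D_b = diffusion_to_si(cc$D_b_1e5_cm2_s),
                     bootstrap = boot, seed = seed)
        report$competition <<- fit
        rows$competition <<- result_row("Q", fit$estimate, fit$se, "",
                                        "nls 1-parameter", length(tab$x))
        note("competition: Q = %.3f (SE %.3f)", fit$estimate, fit$se)
        note("assumption: atmosphere occupancy fixed at n_c x [DNA] for all KCl (n_c set equal to a)")
      })
    } else if (stage == "release") {
      run_stage("release", function() {
        rc <- config$release
        p_complex <- rc$p_complex
        if (is.null(p_complex)) {
          p_complex <- complex_fraction(conc_to_si(rc$P_total_mM),
                                        conc_to_si(rc$DNA_total_mM),
                                        if (is.null(rc$Kd_mM)) NULL else conc_to_si(rc$Kd_mM))
        }
        rel <- released_ions(rc$D_PD_1e5_cm2_s, rc$D_D_1e5_cm2_s,
                             rc$D_f_1e5_cm2_s, rc$n_c, p_complex,
                             se_D_PD = rc$se_D_PD_1e5_cm2_s %||% 0,
                             se_D_D = rc$se_D_D_1e5_cm2_s %||% 0,
                             se_D_f = rc$se_D_f_1e5_cm2_s %||% 0)
        report$release <<- rel
        rows$release <<- result_row("n_R", rel$n_R, rel$se, "ions",
                                    "release equation", 1L)
        note("release: n_R = %.1f (SE %.1f), p_complex = %.3f", rel$n_R, rel$se, p_complex)
        note("assumption: equal total cation concentration in the two compared samples")
      })
    } else if (stage == "lineshape") {
      run_stage("lineshape", function() {
        lc <- config$lineshape
        if (!is.null(lc$file)) {
          spec <- read_spectrum(lc$file)
          ls_fit <- fit_lorentzians(spec, lc$init_centers_hz)
          report$lineshape <<- ls_fit
          for (k in seq_len(nrow(ls_fit$components))) {
            rows[[paste0("lineshape_", k)]] <<- result_row(
              sprintf("R2_line%d", k), ls_fit$components$R2[k],
              ls_fit$components$se_R2[k], "s^-1", "Lorentzian line shape",
              nrow(spec))
            note("lineshape: line %d at %.1f Hz, R2 = %.1f s^-1", k,
                 ls_fit$components$center[k], ls_fit$components$R2[k])
          }
        }
        if (!is.null(lc$r2_file)) {
          tab <- read_table(lc$r2_file, c("C_M_mM", "R2_app"), optional = "se_R2")
          fit <- fit_Rb(conc_to_si(tab$C_M_mM), tab$R2_app, lc$R_f, lc$a,
                        Na_buffer, bootstrap = boot, seed = seed)
          report$Rb <<- fit
          rows$Rb <<- result_row("R_b", fit$estimate, fit$se, "s^-1",
                                 "nls 1-parameter", nrow(tab))
          note("lineshape: R_b = %.1f (SE %.1f) s^-1", fit$estimate, fit$se)
        }
      })
    }
  }
  if (length(rows) > 0L) write_table(do.call(rbind, rows), results_path)
  note("pipeline complete")
  flush_log()
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
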