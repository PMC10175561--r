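#' Pipeline configuration
#'
#' Schema-validated configuration for [run_pipeline()]. Unknown keys are
#' rejected. The ramp stage either simulates a cohort per construct (when
#' `constructs` is given) or reads traces from `traces_csv`; the dose, melt
#' and panel stages are optional and run when their blocks are present.
#'
#' @param seed Master seed; every random draw in a run derives from it
#'   (per-trace seeds are registered in the report).
#' @param constructs Named list; each element a list with `t_half_C` and
#'   optionally `dH` (kJ/mol), `n_traces`, `noise_sd`, `i_max`, `leak_ref`,
#'   `q10_leak`.
#' @param traces_csv Optional CSV of recorded traces (see [read_traces()]);
#'   used when `constructs` is `NULL`.
#' @param protocol List of [ramp_protocol()] arguments.
#' @param detection List of [detection_config()] arguments.
#' @param probe_C Probe temperature for capsaicin-standardized currents.
#' @param tm_method [estimate_tm()] method.
#' @param dose Optional list of [simulate_dose_response()] arguments (or
#'   `csv` pointing at a dose table).
#' @param melt Optional list: `tm_C`, `dH_unfold`, `n_replicates`,
#'   `noise_sd` (or `csv` pointing at a plate).
#' @param panel Optional list of [simulate_mutant_panel()] arguments (or
#'   `tsv` pointing at a panel).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, constructs = NULL, traces_csv = NULL,
                            protocol = list(), detection = list(),
                            probe_C = 40, tm_method = "boltzmann_fit",
                            dose = NULL, melt = NULL, panel = NULL) {
  cfg <- list(seed = seed, constructs = constructs, traces_csv = traces_csv,
              protocol = protocol, detection = detection, probe_C = probe_C,
              tm_method = tm_method, dose = dose, melt = melt, panel = panel)
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed))
    .stopf("seed must be a single integer")
  if (probe_C <= 0) .stopf("probe_C must be positive")
  # instantiating the sub-configs validates their fields (unknown keys too)
  do.call(ramp_protocol, protocol)
  do.call(detection_config, detection)
  known_construct <- c("t_half_C", "dH", "n_traces", "noise_sd", "i_max",
                       "leak_ref", "q10_leak")
  for (nm in names(constructs)) {
    unknown <- setdiff(names(constructs[[nm]]), known_construct)
    if (length(unknown))
      .stopf("construct '%s': unknown key(s) %s", nm,
             paste(unknown, collapse = ", "))
    if (is.null(constructs[[nm]]$t_half_C))
      .stopf("construct '%s': t_half_C is required", nm)
  }
  if (is.null(constructs) && is.null(traces_csv))
    .stopf("either constructs (simulate) or traces_csv (analyze) is required")
  structure(cfg, class = "pipeline_config")
}

# Reproducible hash of the canonical-JSON form of the configuration.
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

.construct_traces <- function(name, con, protocol, base_seed, offset) {
  n_traces <- con$n_traces %||% 6
  noise_sd <- con$noise_sd %||% 0.03
  params <- gating_params_thalf(
    t_half_C = con$t_half_C, dH = con$dH %||% 300,
    i_max = con$i_max %||% 4000, leak_ref = con$leak_ref %||% 50,
    q10_leak = con$q10_leak %||% 1.3, noise_sd = noise_sd)
  lapply(seq_len(n_traces), function(i) {
    sd_i <- (base_seed + offset + i) %% .Machine$integer.max
    simulate_heat_ramp(params, protocol,
                       trace_id = sprintf("%s_%02d", name, i), seed = sd_i)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulation (optional) -> ramp analysis -> dose/melt analyses ->
#' panel statistics and assembles a run report: per-trace results, cohort
#' summaries (mean +/- SE per construct), software version, config hash and
#' seed registry. Per-input failures are captured as skipped rows with a
#' reason; the run continues. Fully deterministic given the configuration
#' (identical config implies a byte-identical JSON report).
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `ramp_results.tsv` and, when present, stage outputs.
#' @return An object of class `run_report` (a list).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  protocol <- do.call(ramp_protocol, cfg$protocol)
  det <- do.call(detection_config, cfg$detection)
  warnings <- character(0)
  seed_registry <- list(master = cfg$seed)

  # --- assemble traces -------------------------------------------------
  if (!is.null(cfg$constructs)) {
    traces <- list(); construct_of <- character(0)
    for (i in seq_along(cfg$constructs)) {
      nm <- names(cfg$constructs)[i]
      trs <- .construct_traces(nm, cfg$constructs[[nm]], protocol,
                               cfg$seed, offset = i * 1000L)
      seed_registry[[nm]] <- cfg$seed + i * 1000L + seq_along(trs)
      traces <- c(traces, trs)
      construct_of <- c(construct_of, rep(nm, length(trs)))
    }
  } else {
    traces <- read_traces(cfg$traces_csv)
    construct_of <- sub("_[^_]*$", "", vapply(traces, `[[`, "", "trace_id"))
  }

  # --- per-trace ramp analysis -----------------------------------------
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    res <- tryCatch(analyze_trace(tr, det, probe_C = cfg$probe_C),
                    error = function(e) e)
    rows[[i]] <- if (inherits(res, "error")) {
      warnings <- c(warnings, sprintf("%s: %s", tr$trace_id, conditionMessage(res)))
      data.frame(trace_id = tr$trace_id, construct = construct_of[i],
                 status = "skipped", threshold_C = NA_real_, q10 = NA_real_,
                 t_half_act_C = NA_real_, i_at_probe_norm = NA_real_,
                 flags = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(trace_id = tr$trace_id, construct = construct_of[i],
                 status = "analyzed", threshold_C = res$threshold_C,
                 q10 = res$q10, t_half_act_C = res$t_half_act_C,
                 i_at_probe_norm = res$i_at_probe_norm,
                 flags = paste(res$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }
  }
  ramp <- do.call(rbind, rows)

  summarize <- function(v) c(n = sum(is.finite(v)), mean = mean(v, na.rm = TRUE),
                             sem = sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v))))
  cohort <- do.call(rbind, lapply(split(ramp, ramp$construct), function(d) {
    s_thr <- summarize(d$threshold_C); s_q <- summarize(d$q10)
    s_h <- summarize(d$t_half_act_C); s_i <- summarize(d$i_at_probe_norm)
    data.frame(construct = d$construct[1], n = as.integer(s_thr["n"]),
               mean_threshold_C = s_thr["mean"], sem_threshold_C = s_thr["sem"],
               mean_q10 = s_q["mean"], sem_q10 = s_q["sem"],
               mean_t_half_act_C = s_h["mean"], sem_t_half_act_C = s_h["sem"],
               mean_i_at_probe = s_i["mean"], sem_i_at_probe = s_i["sem"],
               stringsAsFactors = FALSE)
  }))
  rownames(cohort) <- NULL

  # --- optional stages --------------------------------------------------
  dose_fit <- NULL
  if (!is.null(cfg$dose)) {
    tab <- if (!is.null(cfg$dose$csv)) read_dose(cfg$dose$csv) else {
      seed_registry$dose <- cfg$seed + 77000L
      simulate_dose_response(
        ec50 = cfg$dose$ec50, hill_n = cfg$dose$hill_n,
        r_max = cfg$dose$r_max, doses = cfg$dose$doses,
        n_replicates = cfg$dose$n_replicates %||% 4,
        noise_sd = cfg$dose$noise_sd %||% 0.05,
        seed = cfg$seed + 77000L,
        stimulus_kind = cfg$dose$stimulus_kind %||% "capsaicin")
    }
    dose_fit <- tryCatch(unclass(fit_hill(tab)), error = function(e) {
      warnings <<- c(warnings, paste("dose:", conditionMessage(e))); NULL })
  }

  melt_res <- NULL
  if (!is.null(cfg$melt)) {
    plate <- if (!is.null(cfg$melt$csv)) read_melt(cfg$melt$csv) else {
      seed_registry$melt <- cfg$seed + 88000L
      do.call(rbind, lapply(seq_len(cfg$melt$n_replicates %||% 8), function(i)
        simulate_melt_curve(
          tm_C = cfg$melt$tm_C, dH_unfold = cfg$melt$dH_unfold %||% 300,
          noise_sd = cfg$melt$noise_sd %||% 0,
          seed = cfg$seed + 88000L + i,
          sample_id = sprintf("melt_%02d", i))))
    }
    melt_res <- tryCatch(analyze_melt_plate(plate, method = cfg$tm_method),
                         error = function(e) {
                           warnings <<- c(warnings, paste("melt:", conditionMessage(e))); NULL })
  }

  corr <- NULL
  if (!is.null(cfg$panel)) {
    pan <- if (!is.null(cfg$panel$tsv)) read_panel(cfg$panel$tsv) else {
      seed_registry$panel <- cfg$seed + 99000L
      simulate_mutant_panel(
        n_mutants = cfg$panel$n_mutants %||% 16,
        t0_C = cfg$panel$t0_C %||% 34,
        slope_C_per_kcal = cfg$panel$slope_C_per_kcal %||% -1.5,
        ddg_range = cfg$panel$ddg_range %||% c(-2, 4),
        noise_sd = cfg$panel$noise_sd %||% 1,
        seed = cfg$seed + 99000L)
    }
    corr <- tryCatch(unclass(correlate_ddg_threshold(pan)), error = function(e) {
      warnings <<- c(warnings, paste("panel:", conditionMessage(e))); NULL })
  }

  report <- structure(list(
    package = "thermogate",
    version = as.character(packageVersion("thermogate")),
    config_hash = config_hash(cfg),
    seed_registry = seed_registry,
    ramp_results = ramp,
    cohort_summary = cohort,
    dose_fit = dose_fit,
    melt = melt_res,
    correlation = corr,
    warnings = warnings), class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    write.table(ramp, file.path(out_dir, "ramp_results.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("thermogate run report (v%s, config %s)\n", x$version,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  traces: %d analyzed, %d skipped\n",
              sum(x$ramp_results$status == "analyzed"),
              sum(x$ramp_results$status == "skipped")))
  print(x$cohort_summary, digits = 4)
  if (!is.null(x$correlation))
    cat(sprintf("  panel correlation: r = %.4f (p = %.3g, n = %d)\n",
                x$correlation$r, x$correlation$p, x$correlation$n))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
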