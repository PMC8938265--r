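# Command-line pipeline: config handling, stage orchestration and report
# writers producing a primary-endpoint table (estimate, CI, p, per-level win
# percentages, component event summaries) in delimited and JSON form.

#' Pipeline configuration
#'
#' Exactly one input source must be given: either `input_files` (paths to
#' the three delimited tables) or `generator` (a [trial_config()] or a list
#' of its fields).
#'
#' @param input_files `NULL`, or list/vector with `subjects` and optionally
#'   `events`, `visits` paths.
#' @param generator `NULL`, or a [trial_config()] / list of `trial_config`
#'   arguments.
#' @param mode `"multiple_imputation"` (default) or `"complete_case"`.
#' @param kccq_margin KCCQ win margin in points (default 5).
#' @param horizon_days Follow-up horizon (default 90).
#' @param imputation List of [imputation_config()] arguments (`m`, `seed`,
#'   `model_covariates`).
#' @param alpha Two-sided significance level (default 0.05).
#' @param out_dir Output directory for reports (default `"."`).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_files = NULL, generator = NULL,
                            mode = c("multiple_imputation", "complete_case"),
                            kccq_margin = 5, horizon_days = 90,
                            imputation = list(), alpha = 0.05,
                            out_dir = ".", log_level = c("info", "quiet")) {
  if (is.null(input_files) == is.null(generator)) {
    stop("exactly one input source required: input_files XOR generator",
         call. = FALSE)
  }
  if (!is.null(generator) && !inherits(generator, "trial_config")) {
    generator <- do.call(trial_config, generator)
  }
  structure(list(input_files = input_files, generator = generator,
                 mode = match.arg(mode), kccq_margin = kccq_margin,
                 horizon_days = horizon_days, imputation = imputation,
                 alpha = alpha, out_dir = out_dir,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' Recognized top-level keys: `input_files`, `generator`, `mode`,
#' `kccq_margin`, `horizon_days`, `imputation` (keys `m`, `seed`,
#' `model_covariates`), `alpha`, `out_dir`, `log_level`.
#'
#' @param path JSON file path.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

pipeline_log <- function(cfg, ...) {
  if (cfg$log_level != "quiet") message("[hierwin] ", ...)
  invisible(NULL)
}

load_or_generate <- function(cfg) {
  if (!is.null(cfg$generator)) {
    pipeline_log(cfg, "generating synthetic trial (seed ",
                 cfg$generator$seed, ")")
    generate_trial(cfg$generator)
  } else {
    f <- as.list(cfg$input_files)
    pipeline_log(cfg, "reading trial from ", f$subjects)
    read_trial(f$subjects, f$events, f$visits,
               horizon_days = cfg$horizon_days)
  }
}

component_summaries <- function(data) {
  s <- data$subjects
  ev <- data$events
  out <- list()
  for (a in ARM_LEVELS) {
    sa <- s[s$arm == a, , drop = FALSE]
    n <- nrow(sa)
    deaths <- sum(!is.na(sa$death_day))
    with_hfe <- sum(sa$subject_id %in% ev$subject_id)
    ch <- sa$kccq_day90 - sa$kccq_baseline
    out[[a]] <- list(
      n = n, deaths_n = deaths,
      deaths_pct = if (n) 100 * deaths / n else NA_real_,
      patients_with_hfe_n = with_hfe,
      patients_with_hfe_pct = if (n) 100 * with_hfe / n else NA_real_,
      total_hfes = sum(ev$subject_id %in% sa$subject_id),
      kccq_change_mean = mean(ch, na.rm = TRUE),
      kccq_day90_missing_n = sum(is.na(sa$kccq_day90)))
  }
  out
}

result_as_list <- function(res) {
  list(estimate = res$estimate, se_log = res$se_log,
       ci_lower = res$ci_lower, ci_upper = res$ci_upper,
       p_two_sided = res$p_two_sided,
       pct_wins_treated = as.list(res$pct_wins_treated),
       pct_wins_control = as.list(res$pct_wins_control),
       pct_wins_treated_total = sum(res$pct_wins_treated),
       pct_wins_control_total = sum(res$pct_wins_control),
       pct_ties = res$pct_ties,
       weights = as.list(res$weights), method = res$method,
       problems = res$problems)
}

report_table <- function(res, comps) {
  fmt <- function(x) format(round(x, 4), trim = TRUE, scientific = FALSE)
  rows <- rbind(
    c("win_ratio", fmt(res$estimate), "", ""),
    c("ci_lower", fmt(res$ci_lower), "", ""),
    c("ci_upper", fmt(res$ci_upper), "", ""),
    c("p_two_sided", signif(res$p_two_sided, 4), "", ""),
    c("pct_wins_total", fmt(sum(res$pct_wins_treated)),
      fmt(sum(res$pct_wins_control)), ""),
    do.call(rbind, lapply(HIER_LEVELS, function(l) {
      c(paste0("pct_wins_", l), fmt(res$pct_wins_treated[[l]]),
        fmt(res$pct_wins_control[[l]]), "")
    })),
    c("pct_ties", fmt(res$pct_ties), fmt(res$pct_ties), ""),
    c("deaths_n_pct",
      sprintf("%d (%.1f)", comps$treated$deaths_n, comps$treated$deaths_pct),
      sprintf("%d (%.1f)", comps$control$deaths_n, comps$control$deaths_pct),
      ""),
    c("patients_with_hfe_n_pct",
      sprintf("%d (%.1f)", comps$treated$patients_with_hfe_n,
              comps$treated$patients_with_hfe_pct),
      sprintf("%d (%.1f)", comps$control$patients_with_hfe_n,
              comps$control$patients_with_hfe_pct), ""),
    c("total_hfes", comps$treated$total_hfes, comps$control$total_hfes, ""),
    c("kccq_change_mean", fmt(comps$treated$kccq_change_mean),
      fmt(comps$control$kccq_change_mean), ""))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- c("metric", "treated", "control", "note")
  df
}

#' Run the primary-endpoint analysis pipeline
#'
#' Executes read/generate, optional multiple imputation, pairwise counting,
#' weighting, estimation, U-statistic inference (and Rubin pooling under
#' multiple imputation), and writes `report.csv`, `report.json` and
#' `hierwin.log` to the configured output directory.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `result` (the `win_ratio_result`), `components`
#'   (per-arm event summaries), `data`, and `paths` of the written files.
#' @export
run_primary_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  data <- load_or_generate(cfg)
  res <- if (cfg$mode == "multiple_imputation" &&
             anyNA(data$subjects$kccq_day90)) {
    icfg <- do.call(imputation_config, cfg$imputation)
    pipeline_log(cfg, "imputing (m = ", icfg$m, ", seed ", icfg$seed, ")")
    analyze_mi(data, comparison_rules(kccq_margin = cfg$kccq_margin),
               icfg, alpha = cfg$alpha)
  } else {
    rules <- comparison_rules(kccq_margin = cfg$kccq_margin,
                              kccq_missing = "complete_case")
    suppressWarnings(ustat_inference(data, rules, alpha = cfg$alpha))
  }
  comps <- component_summaries(data)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(csv = file.path(cfg$out_dir, "report.csv"),
             json = file.path(cfg$out_dir, "report.json"),
             log = file.path(cfg$out_dir, "hierwin.log"))
  utils::write.csv(report_table(res, comps), paths[["csv"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(primary = result_as_list(res), components = comps,
         config = cfg_provenance(cfg)),
    paths[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null", na = "null")
  writeLines(c(paste0("hierwin primary analysis @ ",
                      format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               paste0("mode: ", cfg$mode),
               paste0("config: ", as.character(jsonlite::toJSON(
                 cfg_provenance(cfg), auto_unbox = TRUE, digits = NA)))),
             paths[["log"]])
  pipeline_log(cfg, "win ratio ", round(res$estimate, 3), ", p = ",
               signif(res$p_two_sided, 3))
  list(result = res, components = comps, data = data, paths = paths)
}

cfg_provenance <- function(cfg) {
  g <- cfg$generator
  list(mode = cfg$mode, kccq_margin = cfg$kccq_margin,
       horizon_days = cfg$horizon_days, alpha = cfg$alpha,
       imputation = cfg$imputation,
       input_files = cfg$input_files,
       generator = if (!is.null(g)) unclass(g) else NULL)
}

#' Run the secondary-endpoint analyses
#'
#' Computes the per-patient endpoint table and per-arm unadjusted summaries
#' (mean diuretic response at days 15/30 with exclusion counts, DAOH days
#' and percent, NT-proBNP log-AUC through day 30, KCCQ responder
#' proportion), writing `secondary_patients.csv` and `secondary_summary.csv`
#' and appending a `secondary` block to `report.json` if present.
#'
#' @param cfg A [pipeline_config()].
#' @param data Optional pre-loaded `trial_dataset` (else read/generated from
#'   the config).
#' @return List with `patients` (per-patient table), `summary` (per-arm
#'   table) and `paths`.
#' @export
run_secondary_analyses <- function(cfg, data = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(data)) data <- load_or_generate(cfg)
  tab <- secondary_endpoint_table(data)

  summarize_arm <- function(a) {
    ta <- tab[tab$arm == a, , drop = FALSE]
    data.frame(
      arm = a, n = nrow(ta),
      diuretic_response_d15 = mean(ta$diuretic_response_d15, na.rm = TRUE),
      diuretic_response_d15_excluded = sum(is.na(ta$diuretic_response_d15)),
      diuretic_response_d30 = mean(ta$diuretic_response_d30, na.rm = TRUE),
      diuretic_response_d30_excluded = sum(is.na(ta$diuretic_response_d30)),
      daoh_days_mean = mean(ta$daoh_days),
      daoh_percent_mean = mean(ta$daoh_percent),
      ntprobnp_log_auc_d30 = mean(ta$ntprobnp_log_auc_d30, na.rm = TRUE),
      kccq_responder_pct = 100 * mean(ta$kccq_responder, na.rm = TRUE),
      kccq_change_mean = mean(ta$kccq_change, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, lapply(ARM_LEVELS, summarize_arm))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = file.path(cfg$out_dir, "secondary_patients.csv"),
             summary = file.path(cfg$out_dir, "secondary_summary.csv"))
  utils::write.csv(tab, paths[["patients"]], row.names = FALSE, na = "")
  utils::write.csv(summ, paths[["summary"]], row.names = FALSE, na = "")

  json_path <- file.path(cfg$out_dir, "report.json")
  if (file.exists(json_path)) {
    rep <- jsonlite::read_json(json_path)
    rep$secondary <- lapply(split(summ, summ$arm), as.list)
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  }
  list(patients = tab, summary = summ, paths = paths)
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write the three synthetic CSVs), `analyze`
#' (primary analysis), `report` (primary + secondary), `power`
#' (power/type-I-error simulation).  Common flags: `--config <json>`,
#' `--seed`, `--out-dir`, `--mode`, `--replicates`, `--alpha`,
#' `--log-level`.  Flags override config-file values.
#'
#' @param args Character vector of arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hierwin <generate|analyze|report|power> [options]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  if (!cmd %in% c("generate", "analyze", "report", "power")) {
    message("unknown subcommand '", cmd, "'\n", usage)
    return(invisible(1L))
  }
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir"),
    optparse::make_option("--mode", type = "character", default = NULL),
    optparse::make_option("--replicates", type = "integer", default = 500),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--log-level", type = "character",
                          default = "info", dest = "log_level"))
  po <- optparse::parse_args(optparse::OptionParser(option_list = opts),
                             args = args[-1])

  cfg <- if (!is.null(po$config)) load_pipeline_config(po$config) else
    pipeline_config(generator = trial_config())
  cfg$out_dir <- po$out_dir
  cfg$log_level <- if (po$log_level %in% c("quiet", "info")) po$log_level else
    "info"
  if (!is.null(po$mode)) cfg$mode <- po$mode
  if (!is.null(po$seed)) {
    if (!is.null(cfg$generator)) cfg$generator$seed <- po$seed
    cfg$imputation$seed <- po$seed
  }

  status <- 0L
  tryCatch({
    if (cmd == "generate") {
      if (is.null(cfg$generator)) {
        stop("generate requires a generator config", call. = FALSE)
      }
      dat <- generate_trial(cfg$generator)
      paths <- write_trial(dat, cfg$out_dir)
      pipeline_log(cfg, "wrote ", paste(paths, collapse = ", "))
    } else if (cmd == "analyze") {
      run_primary_analysis(cfg)
    } else if (cmd == "report") {
      pr <- run_primary_analysis(cfg)
      run_secondary_analyses(cfg, data = pr$data)
    } else if (cmd == "power") {
      if (is.null(cfg$generator)) {
        stop("power requires a generator config", call. = FALSE)
      }
      ps <- power_simulation(cfg$generator, n_replicates = po$replicates,
                             alpha = po$alpha)
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        ps[c("power", "se", "n_replicates", "alpha")],
        file.path(cfg$out_dir, "power.json"), auto_unbox = TRUE,
        digits = NA)
      pipeline_log(cfg, "rejection fraction ", ps$power, " +/- ", ps$se)
    }
  }, error = function(e) {
    message("hierwin ", cmd, " failed: ", conditionMessage(e))
    status <<- 1L
  })
  invisible(status)
}
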