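MONITORING_CORE <- c("date", "Ca_mg_L", "Mg_mg_L", "TSS_mg_L",
                     "TCu_mg_L", "DCu_mg_L")

#' Validate a monitoring table against the expected schema
#'
#' Checks for the `date` column plus the water-chemistry columns the
#' pipeline derives from, and itemizes every missing column in the error.
#'
#' @param monitoring A data frame.
#' @param required Required column names.
#' @return The table, invisibly, if valid.
#' @export
validate_monitoring <- function(monitoring, required = MONITORING_CORE) {
  miss <- setdiff(required, names(monitoring))
  stop_if(length(miss) > 0,
          paste0("monitoring table is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  invisible(monitoring)
}

#' Read a plain key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values that parse
#' as numbers become numeric. Command-line flags are expected to override
#' file values (the CLI wrapper applies file first, then flags).
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    stop_if(length(kv) < 2, sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full acute-toxicity analysis pipeline
#'
#' Chains every stage into one seeded, reproducible run:
#' survival trial (given or simulated) -> probit fit and LC50 with CI at
#' each observation time -> exponential LC50-time decay fit -> hardness
#' normalization of the final-time LC50 against the sampling-date water
#' chemistry -> derived partitioning columns and the seasonal dry/wet
#' summary with dm flags on the monitoring series (given or simulated).
#'
#' @param seed Integer seed governing all randomness.
#' @param trial A `toxicity_trial`, a trial CSV path, or `NULL` to simulate
#'   from `design` and `truth`.
#' @param monitoring A monitoring tibble, CSV path, or `NULL` to simulate a
#'   series moment-matched to [demo_seasonal_summary()].
#' @param chemistry Single-row monitoring tibble giving the bioassay
#'   water's chemistry for normalization; default
#'   [demo_sampling_chemistry()].
#' @param design,truth Generator settings for synthetic mode
#'   ([trial_design()], [probit_truth()]).
#' @param times Observation times (h) at which to estimate LC50s.
#' @param p Mortality fraction for the lethal-concentration estimates.
#' @param ci_method `"delta"` or `"fieller"`.
#' @param B Bootstrap replicates for seasonal dm statistics.
#' @param ref_hardness,hardness_exponent US EPA normalization settings.
#' @param out_dir If non-`NULL`, write `report.json`, `lc50_table.csv`,
#'   `seasonal_summary.csv`, `seasonal_dm.csv`, `derived_monitoring.csv`,
#'   and a human-readable `report.txt` there.
#' @return The report, an object of class `cuptox_report` (a list).
#' @export
#' @examples
#' rep <- run_pipeline(seed = 1, B = 200)
#' rep$decay
run_pipeline <- function(seed = 1,
                         trial = NULL,
                         monitoring = NULL,
                         chemistry = demo_sampling_chemistry(),
                         design = trial_design(),
                         truth = probit_truth(),
                         times = c(24, 48, 72, 96),
                         p = 0.5,
                         ci_method = c("delta", "fieller"),
                         B = 2000,
                         ref_hardness = 50,
                         hardness_exponent = 0.9422,
                         out_dir = NULL) {
  seed <- check_seed(seed)
  ci_method <- match.arg(ci_method)

  if (is.null(trial)) {
    trial <- simulate_trial(design, truth, seed = seed)
    trial_source <- "synthetic"
  } else if (is.character(trial)) {
    trial_source <- trial
    trial <- read_trial_csv(trial)
  } else {
    trial <- as_toxicity_trial(trial)
    trial_source <- "supplied"
  }

  if (is.null(monitoring)) {
    monitoring <- simulate_seasonal_series(
      specs_from_summary(demo_seasonal_summary()), seed = seed + 1L)
    monitoring_source <- "synthetic"
  } else if (is.character(monitoring)) {
    monitoring_source <- monitoring
    monitoring <- read_monitoring_csv(monitoring)
  } else {
    monitoring_source <- "supplied"
  }
  validate_monitoring(monitoring)
  validate_monitoring(chemistry)

  lc50_tab <- estimate_lc50_series(trial, times = times, p = p,
                                   method = ci_method)
  decay <- fit_time_decay(lc50_tab)

  hard <- hardness(chemistry$Ca_mg_L[1], chemistry$Mg_mg_L[1])
  final_lc50 <- lc50_tab$point[which.max(lc50_tab$time_h)]
  norm <- list(
    hardness_mgCaCO3_L = hard,
    ca_mg_molar_ratio = ca_mg_molar_ratio(chemistry$Ca_mg_L[1],
                                          chemistry$Mg_mg_L[1]),
    lc50_final_h = final_lc50,
    lc50_normalized = normalize_lc50_hardness(final_lc50, hard,
                                              ref_hardness = ref_hardness,
                                              exponent = hardness_exponent),
    ref_hardness = ref_hardness,
    exponent = hardness_exponent)

  derived <- derive_water_chemistry(monitoring)
  seasonal <- seasonal_table(monitoring, B = B, seed = seed + 2L)

  report <- structure(list(
    config = list(seed = seed, times = times, p = p, ci_method = ci_method,
                  B = B, ref_hardness = ref_hardness,
                  hardness_exponent = hardness_exponent,
                  trial_source = trial_source,
                  monitoring_source = monitoring_source),
    lc50_table = lc50_tab,
    decay = list(a = decay$a, k = decay$k, r_squared = decay$r_squared,
                 n_points = decay$n_points),
    normalization = norm,
    seasonal_summary = seasonal$summary,
    seasonal_dm = seasonal$dm,
    derived_monitoring = derived), class = "cuptox_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report A `cuptox_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cuptox_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  j <- unclass(report)
  j$derived_monitoring$date <- as.character(j$derived_monitoring$date)
  j$lc50_table <- as.data.frame(j$lc50_table)
  jsonlite::write_json(j, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  utils::write.csv(report$lc50_table, file.path(out_dir, "lc50_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$seasonal_summary,
                   file.path(out_dir, "seasonal_summary.csv"), row.names = FALSE)
  if (!is.null(report$seasonal_dm)) {
    utils::write.csv(report$seasonal_dm, file.path(out_dir, "seasonal_dm.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$derived_monitoring,
                   file.path(out_dir, "derived_monitoring.csv"),
                   row.names = FALSE)
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

format_report <- function(report) {
  cfg <- report$config
  lt <- report$lc50_table
  dm <- report$seasonal_dm
  c(
    "Acute copper toxicity pipeline report",
    sprintf("seed: %d | CI method: %s | B: %d", cfg$seed, cfg$ci_method, cfg$B),
    "",
    "Lethal concentrations (mg/L):",
    sprintf("  %3g h: LC%.0f = %.3f (%.3f-%.3f)",
            lt$time_h, 100 * lt$p, lt$point, lt$ci_low, lt$ci_high),
    "",
    sprintf("LC50 decay: LC50(t) = %.4f * exp(-%.4f t), R^2 = %.4f",
            report$decay$a, report$decay$k, report$decay$r_squared),
    "",
    sprintf("Test-water hardness: %.1f mg CaCO3/L (Ca:Mg molar ratio %.2f)",
            report$normalization$hardness_mgCaCO3_L,
            report$normalization$ca_mg_molar_ratio),
    sprintf("Final-time LC50 normalized to %g mg CaCO3/L: %.3f mg/L",
            report$normalization$ref_hardness,
            report$normalization$lc50_normalized),
    "",
    "Seasonal dm statistics (|dm| > 2 flags a seasonal difference):",
    if (!is.null(dm)) {
      sprintf("  %-15s dm = %7.2f %s", dm$variable, dm$dm,
              ifelse(dm$significant, "*", " "))
    } else "  (no variables comparable across seasons)")
}

#' @export
print.cuptox_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
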