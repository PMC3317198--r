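#' Define an acute-toxicity trial design
#'
#' Describes the layout of a static acute bioassay: the dissolved-metal
#' concentration series, the number of fish per aquarium, and the scheduled
#' survival observation times. The default concentration grid and tank size
#' are those of a 96-h copper bioassay on *Cnesterodon decemmaculatus* in
#' hard river water (seven doses of 0.05-1.42 mg Cu/L, ten fish per tank,
#' daily observations to 96 h).
#'
#' @param concentrations Strictly positive, strictly increasing dissolved
#'   metal concentrations (mg/L).
#' @param n_per_tank Fish per aquarium (>= 1).
#' @param observation_times Strictly increasing exposure times (hours, > 0)
#'   at which cumulative mortality is recorded.
#' @param control_included Include a zero-dose control tank?
#' @return An object of class `trial_design`.
#' @seealso [simulate_trial()]
#' @export
#' @examples
#' trial_design()
trial_design <- function(concentrations = c(0.05, 0.19, 0.39, 0.61, 0.73, 1.01, 1.42),
                         n_per_tank = 10L,
                         observation_times = c(24, 48, 72, 96),
                         control_included = TRUE) {
  stop_if(!is.numeric(concentrations) || length(concentrations) < 1L,
          "`concentrations` must be a non-empty numeric vector")
  stop_if(any(concentrations <= 0),
          "`concentrations` must be strictly positive")
  stop_if(any(diff(concentrations) <= 0),
          "`concentrations` must be strictly increasing")
  check_number(n_per_tank, "n_per_tank", lower = 1)
  stop_if(!is.numeric(observation_times) || length(observation_times) < 1L ||
            any(observation_times <= 0) || any(diff(observation_times) <= 0),
          "`observation_times` must be strictly increasing and positive")
  structure(
    list(concentrations = as.numeric(concentrations),
         n_per_tank = as.integer(n_per_tank),
         observation_times = as.numeric(observation_times),
         control_included = isTRUE(control_included)),
    class = "trial_design")
}

#' Define the true dose-response used to generate mortality
#'
#' The generating model is a probit dose-response on log dose whose median
#' lethal concentration decays exponentially with exposure time:
#' \deqn{P(\mathrm{death\ by\ } t \mid c) =
#'   \Phi\{\beta (\log_b c - \log_b \mathrm{LC50}(t))\},\qquad
#'   \mathrm{LC50}(t) = \mathrm{LC50}(t_0)\, e^{-k (t - t_0)}.}
#' `slope` is the probit slope \eqn{\beta} per log-dose unit (base
#' `log_base`); `decay_rate` is the per-hour rate \eqn{k}. Defaults place
#' LC50 = 0.655 mg/L at the 96-h reference time with k = 0.0061/h, the
#' regime of an acute Cu bioassay in hard river water, and a slope of 4 per
#' log10 unit, typical of acute Cu-fish assays.
#'
#' @param lc50_at_ref_time True LC50 (mg/L) at `ref_time`.
#' @param slope Probit slope per log-dose unit; `Inf` gives a step response.
#' @param decay_rate Exponential decay rate of LC50 per hour (>= 0).
#' @param ref_time Reference exposure time (h) at which `lc50_at_ref_time`
#'   applies.
#' @param log_base Base of the dose metameter (10, the bioassay convention,
#'   or `exp(1)`).
#' @param background_mortality Probability a control fish dies by the end of
#'   the test (default 0; enables Abbott-correction testing).
#' @return An object of class `probit_truth`.
#' @export
probit_truth <- function(lc50_at_ref_time = 0.655, slope = 4,
                         decay_rate = 0.0061, ref_time = 96,
                         log_base = 10, background_mortality = 0) {
  check_number(lc50_at_ref_time, "lc50_at_ref_time", lower = 0, strict_lower = TRUE)
  stop_if(!is.numeric(slope) || length(slope) != 1L || is.na(slope) || slope <= 0,
          "`slope` must be > 0 (Inf allowed)")
  check_number(decay_rate, "decay_rate", lower = 0)
  check_number(ref_time, "ref_time", lower = 0, strict_lower = TRUE)
  check_number(log_base, "log_base", lower = 1, strict_lower = TRUE)
  check_number(background_mortality, "background_mortality", lower = 0, upper = 1)
  structure(
    list(lc50_at_ref_time = lc50_at_ref_time, slope = slope,
         decay_rate = decay_rate, ref_time = ref_time, log_base = log_base,
         background_mortality = background_mortality),
    class = "probit_truth")
}

#' True LC50 at a given exposure time
#'
#' @param truth A [probit_truth()] object.
#' @param time_h Exposure times (hours).
#' @return LC50 values (mg/L), `lc50_at_ref_time * exp(-decay_rate * (t - ref_time))`.
#' @export
true_lc50 <- function(truth, time_h) {
  stopifnot(inherits(truth, "probit_truth"))
  truth$lc50_at_ref_time * exp(-truth$decay_rate * (time_h - truth$ref_time))
}

# death probability by time t at concentration c under `truth`
death_prob <- function(truth, conc, time_h, t_max) {
  lc <- true_lc50(truth, time_h)
  if (is.infinite(truth$slope)) {
    p <- ifelse(conc == lc, 0.5, as.numeric(conc > lc))
  } else {
    p <- stats::pnorm(truth$slope *
                        (log(conc, truth$log_base) - log(lc, truth$log_base)))
  }
  # background mortality accrues smoothly over the test and acts
  # independently of the dose mechanism
  bg <- 1 - (1 - truth$background_mortality)^(time_h / t_max)
  1 - (1 - p) * (1 - bg)
}

#' Simulate one acute-toxicity trial
#'
#' Mortality is generated per fish from a latent uniform threshold: fish
#' *i* in a tank is dead by time *t* iff \eqn{u_i \le P(t)}, where
#' \eqn{P(t)} is the probit death probability of [probit_truth()]. Because
#' \eqn{P(t)} is non-decreasing in *t* (LC50 decays), cumulative counts are
#' monotone along each tank's path, while each time's count is marginally
#' Binomial(n, P(t)). Control-tank mortality is 0 unless
#' `background_mortality` is set.
#'
#' @param design A [trial_design()].
#' @param truth A [probit_truth()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A `toxicity_trial` tibble with columns `concentration_mg_L`, `n`,
#'   and one `deaths_<t>h` column of cumulative deaths per observation time
#'   (control tank first when present, at concentration 0).
#' @export
#' @examples
#' simulate_trial(trial_design(), probit_truth(), seed = 1)
simulate_trial <- function(design, truth, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "probit_truth"))
  seed <- check_seed(seed)
  times <- design$observation_times
  t_max <- max(times)
  concs <- design$concentrations
  if (design$control_included) concs <- c(0, concs)
  n <- design$n_per_tank
  deaths <- withr::with_seed(seed, {
    vapply(concs, function(conc) {
      u <- stats::runif(n)
      vapply(times, function(tt) {
        p <- if (conc == 0) {
          1 - (1 - truth$background_mortality)^(tt / t_max)
        } else {
          death_prob(truth, conc, tt, t_max)
        }
        sum(u <= p)
      }, numeric(1))
    }, numeric(length(times)))
  })
  deaths <- matrix(deaths, nrow = length(times))
  tab <- tibble::tibble(concentration_mg_L = concs, n = as.integer(n))
  for (i in seq_along(times)) {
    tab[[sprintf("deaths_%gh", times[i])]] <- as.integer(deaths[i, ])
  }
  as_toxicity_trial(tab)
}

#' Describe one season of one monitoring variable
#'
#' A `season_spec` states that variable `variable` is sampled `n` times in
#' season `season` from a lognormal distribution with the given log-scale
#' location and scale. Seasonal monitoring variables are modelled as
#' independent lognormals because only marginal seasonal summaries are
#' available to calibrate against.
#'
#' @param variable Variable (column) name.
#' @param season `"dry"` (May-October) or `"wet"` (November-April).
#' @param meanlog,sdlog Location and scale of the lognormal on the log scale
#'   (`sdlog` > 0).
#' @param n Number of samples in the season (>= 2).
#' @return An object of class `season_spec`.
#' @seealso [season_spec_from_moments()] to match a printed mean/sd.
#' @export
season_spec <- function(variable, season, meanlog, sdlog, n) {
  stop_if(!is.character(variable) || length(variable) != 1L,
          "`variable` must be a single string")
  stop_if(!season %in% c("dry", "wet"),
          sprintf("unknown season label '%s' (must be 'dry' or 'wet')", season))
  check_number(meanlog, "meanlog")
  check_number(sdlog, "sdlog", lower = 0, strict_lower = TRUE)
  check_number(n, "n", lower = 2)
  structure(list(variable = variable, season = season, meanlog = meanlog,
                 sdlog = sdlog, n = as.integer(n)),
            class = "season_spec")
}

#' Lognormal season spec matched to an arithmetic mean and sd
#'
#' Moment-matches a lognormal to the target arithmetic mean `m` and standard
#' deviation `s`: `meanlog = log(m^2 / sqrt(m^2 + s^2))`,
#' `sdlog = sqrt(log(1 + s^2/m^2))`.
#'
#' @inheritParams season_spec
#' @param mean,sd Target arithmetic mean (> 0) and standard deviation (> 0).
#' @return A [season_spec()].
#' @export
season_spec_from_moments <- function(variable, season, mean, sd, n) {
  check_number(mean, "mean", lower = 0, strict_lower = TRUE)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  cv2 <- (sd / mean)^2
  season_spec(variable, season,
              meanlog = log(mean / sqrt(1 + cv2)),
              sdlog = sqrt(log(1 + cv2)),
              n = n)
}

#' Simulate a two-season water-quality monitoring table
#'
#' Draws each variable/season series independently from its lognormal
#' [season_spec()] and attaches calendar dates consistent with
#' [classify_season()]: dry-season records get months May-October, wet-season
#' records November-April, spread across `years`. Within a season, variables
#' with fewer samples than the season's longest series are padded with `NA`
#' (monitoring campaigns do not measure every analyte on every visit).
#'
#' @param specs A list of [season_spec()] objects (>= 1 per season used).
#' @param seed Integer seed; same seed, byte-identical table.
#' @param years Calendar years over which records are dated.
#' @return A tibble with `date`, `season`, and one column per variable,
#'   ordered by date.
#' @export
#' @examples
#' sp <- list(
#'   season_spec_from_moments("Na_mg_L", "dry", 126, 43, 14),
#'   season_spec_from_moments("Na_mg_L", "wet", 49, 31, 13))
#' simulate_seasonal_series(sp, seed = 1)
simulate_seasonal_series <- function(specs, seed, years = 2003:2010) {
  if (inherits(specs, "season_spec")) specs <- list(specs)
  stop_if(length(specs) < 1L || !all(vapply(specs, inherits, logical(1), "season_spec")),
          "`specs` must be a list of season_spec objects")
  seed <- check_seed(seed)
  seasons <- vapply(specs, `[[`, character(1), "season")
  months_of <- list(dry = 5:10, wet = c(11:12, 1:4))
  withr::with_seed(seed, {
    out <- lapply(unique(seasons), function(se) {
      sub <- specs[seasons == se]
      n_rows <- max(vapply(sub, `[[`, integer(1), "n"))
      mo <- sample(months_of[[se]], n_rows, replace = TRUE)
      dt <- as.Date(sprintf("%d-%02d-%02d",
                            sample(years, n_rows, replace = TRUE),
                            mo,
                            sample(28L, n_rows, replace = TRUE)))
      tab <- tibble::tibble(date = sort(dt), season = se)
      for (sp in sub) {
        v <- rep(NA_real_, n_rows)
        v[seq_len(sp$n)] <- stats::rlnorm(sp$n, sp$meanlog, sp$sdlog)
        tab[[sp$variable]] <- v
      }
      tab
    })
    # a variable may be sampled in only one season (pad the other with NA)
    all_cols <- unique(unlist(lapply(out, names)))
    out <- lapply(out, function(tab) {
      for (cc in setdiff(all_cols, names(tab))) tab[[cc]] <- NA_real_
      tab[all_cols]
    })
    do.call(rbind, out)
  })
}

#' Season specs emulating a two-season monitoring summary table
#'
#' Builds one moment-matched [season_spec()] per (variable, season) row of a
#' seasonal summary table such as [demo_seasonal_summary()], using each row's
#' printed n, mean, and sd. Rows with missing or non-positive mean/sd (e.g. a
#' variable not measured in one season) are skipped.
#'
#' @param summary_tbl Data frame with columns `variable`, `season`, `n`,
#'   `mean`, `std`.
#' @return A list of [season_spec()] objects.
#' @export
specs_from_summary <- function(summary_tbl) {
  need <- c("variable", "season", "n", "mean", "std")
  miss <- setdiff(need, names(summary_tbl))
  stop_if(length(miss) > 0,
          paste("summary table lacks columns:", paste(miss, collapse = ", ")))
  specs <- list()
  for (i in seq_len(nrow(summary_tbl))) {
    r <- summary_tbl[i, ]
    if (any(is.na(c(r$mean, r$std, r$n))) || r$mean <= 0 || r$std <= 0 || r$n < 2)
      next
    specs[[length(specs) + 1L]] <-
      season_spec_from_moments(r$variable, r$season, r$mean, r$std, r$n)
  }
  specs
}

#' Write a monitoring table to CSV
#'
#' @param monitoring Tibble from [simulate_seasonal_series()] or of the same
#'   schema.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(monitoring, path) {
  utils::write.csv(monitoring, path, row.names = FALSE)
  invisible(path)
}

#' Read a monitoring table from CSV
#'
#' @param path CSV with a `date` column (ISO-8601) and numeric variables.
#' @return A tibble with `date` parsed to `Date`.
#' @export
read_monitoring_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stop_if(!"date" %in% names(tab), "monitoring CSV must have a `date` column")
  tab$date <- as.Date(tab$date)
  stop_if(anyNA(tab$date), "unparseable dates in monitoring CSV")
  tab
}
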