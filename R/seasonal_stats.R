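#' Classify dates into the dry or wet season
#'
#' Dryland-river convention for this basin: May-October is the dry (low
#' discharge) season, November-April the wet season. Classification is by
#' calendar month of the record's date.
#'
#' @param date `Date` vector, or strings parseable by `as.Date()`.
#' @return Character vector, `"dry"` or `"wet"`.
#' @export
#' @examples
#' classify_season(as.Date(c("2009-05-01", "2009-04-30")))  # dry, wet
classify_season <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  stop_if(length(d) == 0 || anyNA(d), "unparseable date(s)")
  ifelse(as.integer(format(d, "%m")) %in% 5:10, "dry", "wet")
}

#' Bootstrap standard error of the mean
#'
#' Draws `B` resamples with replacement, each of the observed size n, and
#' returns the standard deviation of the B resample means. A constant
#' series gives exactly 0; as B grows the value approaches
#' s/sqrt(n) * sqrt((n-1)/n).
#'
#' @param values Numeric series (n >= 2 after dropping NA).
#' @param B Number of bootstrap replicates (>= 1), default 2000.
#' @param seed Integer seed; same seed and B give the identical SE.
#' @return The bootstrap standard error (single number).
#' @export
#' @examples
#' bootstrap_se(rnorm(50), B = 2000, seed = 1)
bootstrap_se <- function(values, B = 2000, seed = 1) {
  values <- values[!is.na(values)]
  n <- length(values)
  stop_if(n < 2L, "need at least 2 observations")
  check_number(B, "B", lower = 1)
  seed <- check_seed(seed)
  if (stats::sd(values) == 0) return(0)
  withr::with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    stats::sd(colMeans(matrix(values[idx], nrow = n, ncol = B)))
  })
}

dm_classify <- function(dm) !is.na(dm) & abs(dm) > 2

#' dm statistic from summary quantities
#'
#' Closed-form variant for published summary tables:
#' dm = (mean_x - mean_y) / sqrt(se_x^2 + se_y^2). `|dm| > 2` is taken as
#' evidence the two means differ.
#'
#' @param mean_x,mean_y Group means. Vectorized.
#' @param se_x,se_y Standard errors of the means (>= 0, not both 0 unless
#'   the means are equal; equal means with zero SEs give dm = 0, unequal
#'   means give signed `Inf`).
#' @return dm values.
#' @export
#' @examples
#' dm_from_summary(7.87, 0.0535, 7.70, 0.0749)  # ~1.85, not significant
dm_from_summary <- function(mean_x, se_x, mean_y, se_y) {
  stop_if(any(se_x < 0, na.rm = TRUE) || any(se_y < 0, na.rm = TRUE),
          "standard errors must be non-negative")
  denom <- sqrt(se_x^2 + se_y^2)
  num <- mean_x - mean_y
  ifelse(denom == 0, ifelse(num == 0, 0, sign(num) * Inf), num / denom)
}

#' dm difference-of-means statistic with bootstrap standard errors
#'
#' dm = (mean(x) - mean(y)) / sqrt(ESx^2 + ESy^2), where ESx and ESy are
#' bootstrap standard errors of each group mean ([bootstrap_se()]).
#' `|dm| > 2` flags the means as different. Each series' resampling
#' sub-seed is derived from the user seed and the series' own content, so
#' `dm(x, y)` equals `-dm(y, x)` exactly under the same seed.
#'
#' @param x,y Numeric series (length >= 2 each after dropping NA);
#'   conventionally x = dry season, y = wet season.
#' @param B Bootstrap replicates, default 2000.
#' @param seed Integer seed.
#' @return A `dm_result` tibble row: `mean_x`, `mean_y`, `se_x`, `se_y`,
#'   `dm`, `significant`, `n_x`, `n_y`, `B`, `seed`.
#' @export
#' @examples
#' dm_statistic(rnorm(14, 126, 43), rnorm(13, 49, 31), B = 500, seed = 1)
dm_statistic <- function(x, y, B = 2000, seed = 1) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stop_if(length(x) < 2L || length(y) < 2L,
          "both series need at least 2 observations")
  seed <- check_seed(seed)
  se_x <- bootstrap_se(x, B = B, seed = series_seed(seed, x))
  se_y <- bootstrap_se(y, B = B, seed = series_seed(seed, y))
  dm <- dm_from_summary(mean(x), se_x, mean(y), se_y)
  # both series constant and equal: no evidence of difference by definition
  if (is.nan(dm)) dm <- 0
  structure(
    tibble::tibble(mean_x = mean(x), mean_y = mean(y), se_x = se_x, se_y = se_y,
                   dm = dm, significant = dm_classify(dm),
                   n_x = length(x), n_y = length(y),
                   B = as.integer(B), seed = seed),
    class = c("dm_result", class(tibble::tibble())))
}

#' Seasonal summary table with dm comparison per variable
#'
#' Splits a monitoring table into dry/wet season groups (classifying from
#' `date` unless a `season` column is present), summarises every numeric
#' variable per season (n, mean, median, max, min, std, NA dropped per
#' variable), and computes the bootstrap dm statistic dry vs wet for each
#' variable observed at least twice in both seasons. Variables present in
#' only one season keep their summaries but get no dm row.
#'
#' @param monitoring Monitoring tibble with a `date` (or `season`) column
#'   and numeric variables.
#' @param B Bootstrap replicates for the dm SEs.
#' @param seed Integer seed.
#' @param standardize Divide each pooled series by its pooled SD before
#'   computing dm (off by default; it changes dm only through bootstrap
#'   granularity since the factor cancels in the ratio's expectation).
#' @return A list of class `seasonal_table`: `summary` (tibble: variable,
#'   season, n, mean, median, max, min, std) and `dm` (tibble with one
#'   [dm_statistic()] row per comparable variable, plus `variable`).
#' @export
seasonal_table <- function(monitoring, B = 2000, seed = 1, standardize = FALSE) {
  m <- tibble::as_tibble(monitoring)
  if (!"season" %in% names(m)) {
    stop_if(!"date" %in% names(m), "need a `date` or `season` column")
    m$season <- classify_season(m$date)
  }
  stop_if(!all(m$season %in% c("dry", "wet")),
          "unknown season label(s); must be 'dry' or 'wet'")
  vars <- names(m)[vapply(m, is.numeric, logical(1))]
  vars <- setdiff(vars, c("season"))
  stop_if(length(vars) == 0, "no numeric variables to summarise")

  summaries <- list(); dms <- list()
  for (v in vars) {
    for (se in intersect(c("dry", "wet"), unique(m$season))) {
      vals <- m[[v]][m$season == se]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) next
      summaries[[length(summaries) + 1L]] <- tibble::tibble(
        variable = v, season = se, n = length(vals), mean = mean(vals),
        median = stats::median(vals), max = max(vals), min = min(vals),
        std = stats::sd(vals))
    }
    xd <- m[[v]][m$season == "dry"]; xd <- xd[!is.na(xd)]
    xw <- m[[v]][m$season == "wet"]; xw <- xw[!is.na(xw)]
    if (length(xd) >= 2 && length(xw) >= 2) {
      if (standardize) {
        s_pool <- stats::sd(c(xd, xw))
        if (s_pool > 0) { xd <- xd / s_pool; xw <- xw / s_pool }
      }
      r <- dm_statistic(xd, xw, B = B, seed = seed)
      dms[[length(dms) + 1L]] <- tibble::tibble(variable = v, r)
    }
  }
  structure(list(summary = do.call(rbind, summaries),
                 dm = if (length(dms)) do.call(rbind, dms) else NULL),
            class = "seasonal_table")
}

#' @export
print.seasonal_table <- function(x, ...) {
  cat("<seasonal_table>\n$summary\n"); print(x$summary)
  cat("\n$dm\n"); print(x$dm)
  invisible(x)
}

#' Monthly hydrograph summary
#'
#' Aggregates a discharge series by calendar month across years: mean, 10th
#' and 90th percentile (linear interpolation between order statistics,
#' `stats::quantile()` type 7). Months with no observations are omitted
#' with a warning.
#'
#' @param date Dates of the observations.
#' @param discharge Discharge values (same length).
#' @return A tibble: `month` (1-12), `n`, `mean`, `p10`, `p90`.
#' @export
#' @examples
#' d <- seq(as.Date("2005-01-01"), as.Date("2008-12-31"), by = "week")
#' hydrograph_summary(d, 200 + 150 * sinpi(2 * as.numeric(format(d, "%j")) / 365))
hydrograph_summary <- function(date, discharge) {
  d <- as.Date(date)
  stop_if(anyNA(d), "unparseable date(s)")
  stop_if(length(d) != length(discharge), "`date` and `discharge` lengths differ")
  keep <- !is.na(discharge)
  d <- d[keep]; discharge <- discharge[keep]
  mo <- as.integer(format(d, "%m"))
  present <- sort(unique(mo))
  if (length(present) < 12L) {
    warning(sprintf("no observations for month(s): %s",
                    paste(setdiff(1:12, present), collapse = ", ")),
            call. = FALSE)
  }
  rows <- lapply(present, function(mm) {
    q <- discharge[mo == mm]
    tibble::tibble(month = mm, n = length(q), mean = mean(q),
                   p10 = unname(stats::quantile(q, 0.10, type = 7)),
                   p90 = unname(stats::quantile(q, 0.90, type = 7)))
  })
  do.call(rbind, rows)
}
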