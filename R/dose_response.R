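#' Coerce a data frame to a toxicity trial table
#'
#' A toxicity trial table has one row per tank with columns
#' `concentration_mg_L`, `n`, and cumulative death counts `deaths_<t>h` for
#' each observation time. A row at concentration 0 is the control tank.
#' Validation enforces `0 <= deaths <= n`, cumulative deaths non-decreasing
#' across times within each tank, and unique concentrations.
#'
#' @param x Data frame with the columns above.
#' @return A `toxicity_trial` tibble.
#' @export
as_toxicity_trial <- function(x) {
  x <- tibble::as_tibble(x)
  stop_if(!all(c("concentration_mg_L", "n") %in% names(x)),
          "trial table needs `concentration_mg_L` and `n` columns")
  dcols <- grep("^deaths_[0-9.]+h$", names(x), value = TRUE)
  stop_if(length(dcols) < 1L, "trial table needs at least one `deaths_<t>h` column")
  times <- as.numeric(sub("^deaths_([0-9.]+)h$", "\\1", dcols))
  ord <- order(times)
  times <- times[ord]; dcols <- dcols[ord]
  stop_if(anyDuplicated(x$concentration_mg_L) > 0, "concentrations must be unique")
  stop_if(any(x$concentration_mg_L < 0), "concentrations must be >= 0")
  stop_if(any(x$n < 1), "`n` must be >= 1")
  d <- as.matrix(x[dcols])
  stop_if(any(d < 0) || any(d > x$n), "deaths must satisfy 0 <= deaths <= n")
  if (length(dcols) > 1L) {
    stop_if(any(t(apply(d, 1L, diff)) < 0),
            "cumulative deaths must be non-decreasing across times within a tank")
  }
  attr(x, "observation_times") <- times
  class(x) <- c("toxicity_trial", class(x))
  x
}

#' @export
print.toxicity_trial <- function(x, ...) {
  cat(sprintf("<toxicity_trial: %d tanks, observed at %s h>\n",
              nrow(x), paste(attr(x, "observation_times"), collapse = ", ")))
  NextMethod()
}

#' Observation times of a trial table
#' @param trial A `toxicity_trial`.
#' @return Numeric vector of hours.
#' @export
observation_times <- function(trial) {
  stopifnot(inherits(trial, "toxicity_trial"))
  attr(trial, "observation_times")
}

#' Read / write trial tables
#'
#' @param path CSV file with the [as_toxicity_trial()] schema.
#' @return `read_trial_csv()` a `toxicity_trial`; `write_trial_csv()` the
#'   path, invisibly.
#' @export
read_trial_csv <- function(path) {
  as_toxicity_trial(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_csv
#' @param trial A `toxicity_trial`.
#' @export
write_trial_csv <- function(trial, path) {
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}

deaths_at <- function(trial, time_h) {
  col <- sprintf("deaths_%gh", time_h)
  stop_if(!col %in% names(trial),
          sprintf("no observation at %g h (have: %s)", time_h,
                  paste(observation_times(trial), collapse = ", ")))
  as.numeric(trial[[col]])
}

# binomial probit log-likelihood on the chosen log-dose scale
probit_loglik <- function(alpha, beta, logdose, d, n) {
  p <- stats::pnorm(alpha + beta * logdose)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(d * log(p) + (n - d) * log(1 - p))
}

# bounded grid search fallback maximizer (refined zoom)
probit_grid_fit <- function(logdose, d, n, a_range = c(-30, 30),
                            b_range = c(-30, 30), levels = 6L, grid_n = 41L) {
  best <- c(mean(a_range), mean(b_range))
  for (lev in seq_len(levels)) {
    as <- seq(a_range[1], a_range[2], length.out = grid_n)
    bs <- seq(b_range[1], b_range[2], length.out = grid_n)
    ll <- outer(as, bs, Vectorize(function(a, b) probit_loglik(a, b, logdose, d, n)))
    ij <- arrayInd(which.max(ll), dim(ll))
    best <- c(as[ij[1]], bs[ij[2]])
    da <- diff(a_range) / (grid_n - 1); db <- diff(b_range) / (grid_n - 1)
    a_range <- best[1] + c(-2, 2) * da
    b_range <- best[2] + c(-2, 2) * db
  }
  best
}

#' Fit a probit dose-response at one observation time
#'
#' Maximum-likelihood fit of \eqn{P(\mathrm{death}) = \Phi(\alpha + \beta
#' \log_b(\mathrm{dose}))} to the cumulative mortality counts at `time_h`,
#' by iteratively reweighted (Fisher-scoring) estimation with convergence
#' tolerance 1e-8 and at most 100 iterations, falling back to a bounded
#' grid-refinement search when scoring does not converge. Doses with 0% or
#' 100% mortality are retained in the likelihood. A completely separated
#' dose grid (every tank all-dead or all-alive) is returned as a flagged,
#' non-converged fit with a separation diagnostic rather than an error.
#'
#' The control tank (concentration 0) is excluded from the likelihood and
#' must have zero mortality; apply [abbott_correct()] first otherwise.
#'
#' @param trial A `toxicity_trial`.
#' @param time_h Observation time (h) to fit.
#' @param log_base Dose metameter base: 10 (default, the bioassay
#'   convention) or `exp(1)`.
#' @return A `probit_fit` with elements `alpha`, `beta`, `vcov`, `loglik`,
#'   `converged`, `separation`, `n_doses`, `log_base`, `time_h`.
#' @export
#' @examples
#' tr <- simulate_trial(trial_design(), probit_truth(), seed = 1)
#' fit_probit(tr, 96)
fit_probit <- function(trial, time_h, log_base = 10) {
  stopifnot(inherits(trial, "toxicity_trial"))
  check_number(log_base, "log_base", lower = 1, strict_lower = TRUE)
  d_all <- deaths_at(trial, time_h)
  dose <- trial$concentration_mg_L
  n_all <- as.numeric(trial$n)
  ctrl <- dose == 0
  if (any(ctrl) && any(d_all[ctrl] > 0)) {
    stop("control mortality is non-zero; apply abbott_correct() before fitting",
         call. = FALSE)
  }
  d <- d_all[!ctrl]; n <- n_all[!ctrl]; dose <- dose[!ctrl]
  stop_if(length(dose) < 2L, "need at least 2 non-control doses")
  stop_if(all(d == 0) || all(d == n),
          "fewer than 2 informative doses: no partial mortality information")
  ld <- log(dose, log_base)

  separated <- all(d == 0 | d == n)
  fit <- suppressWarnings(
    stats::glm(cbind(d, n - d) ~ ld, family = stats::binomial(link = "probit"),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  alpha <- unname(stats::coef(fit)[1])
  beta <- unname(stats::coef(fit)[2])
  converged <- isTRUE(fit$converged) && !separated && abs(beta) < 50
  V <- tryCatch(unname(stats::vcov(fit)), error = function(e) matrix(NA_real_, 2, 2))

  if (!isTRUE(fit$converged) && !separated) {
    # scoring failed on an informative grid: bounded grid-refinement search
    gb <- probit_grid_fit(ld, d, n)
    alpha <- gb[1]; beta <- gb[2]
    converged <- FALSE
  }

  structure(
    list(alpha = alpha, beta = beta, vcov = V,
         loglik = probit_loglik(alpha, beta, ld, d, n),
         converged = converged, separation = separated,
         n_doses = length(dose), log_base = log_base, time_h = time_h),
    class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf(
    "<probit_fit @ %g h> alpha = %.4f, beta = %.4f per log%s(dose), logLik = %.3f\n",
    x$time_h, x$alpha, x$beta,
    if (isTRUE(all.equal(x$log_base, exp(1)))) "e" else format(x$log_base),
    x$loglik))
  if (x$separation) cat("  ! complete separation: slope diverges, estimates flagged\n")
  else if (!x$converged) cat("  ! did not converge (grid-search fallback estimates)\n")
  invisible(x)
}

#' Lethal concentration for a mortality fraction p
#'
#' Inverts a converged probit fit: the LCp point estimate is
#' \eqn{b^{(\Phi^{-1}(p) - \alpha)/\beta}} with `b` the fit's log base.
#' The 95% (or `level`) confidence interval is computed on the log-dose
#' scale either by the delta method (default) or by Fieller's theorem, and
#' back-transformed, so endpoints are always positive and ordered.
#'
#' @param fit A converged `probit_fit`.
#' @param p Mortality fraction in (0, 1); 0.5 gives the LC50.
#' @param method `"delta"` or `"fieller"`.
#' @param level Confidence level.
#' @return An `lc_estimate` tibble row: `time_h`, `p`, `point`, `ci_low`,
#'   `ci_high`, `ci_method`.
#' @export
#' @examples
#' tr <- simulate_trial(trial_design(), probit_truth(), seed = 1)
#' lc_p(fit_probit(tr, 96), 0.5)
lc_p <- function(fit, p = 0.5, method = c("delta", "fieller"), level = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  method <- match.arg(method)
  check_number(p, "p", lower = 0, upper = 1)
  stop_if(p <= 0 || p >= 1, "`p` must be strictly inside (0, 1)")
  stop_if(!fit$converged,
          "fit did not converge; LCp would not be reliable")
  stop_if(fit$beta <= 0, "non-positive slope: response not monotone increasing in dose")
  z <- stats::qnorm(p)
  g <- (z - fit$alpha) / fit$beta           # log-dose at fraction p
  V <- fit$vcov
  tcrit <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    grad <- c(-1 / fit$beta, -g / fit$beta)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    lo <- g - tcrit * se; hi <- g + tcrit * se
  } else {
    # Fieller: roots of the quadratic in g
    A <- fit$beta^2 - tcrit^2 * V[2, 2]
    B <- -2 * (fit$beta * (z - fit$alpha) + tcrit^2 * V[1, 2])
    C <- (z - fit$alpha)^2 - tcrit^2 * V[1, 1]
    disc <- B^2 - 4 * A * C
    stop_if(A <= 0 || disc < 0,
            "Fieller interval is unbounded (slope not significantly positive)")
    r <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    lo <- r[1]; hi <- r[2]
  }
  b <- fit$log_base
  structure(
    tibble::tibble(time_h = fit$time_h, p = p, point = b^g,
                   ci_low = b^lo, ci_high = b^hi, ci_method = method),
    class = c("lc_estimate", class(tibble::tibble())))
}

#' Abbott's correction for control mortality
#'
#' Rescales each dose group's mortality fraction by the control fraction c:
#' corrected p' = (p - c) / (1 - c), floored at 0. With zero control
#' mortality the trial is returned unchanged. Corrected counts may be
#' fractional; [fit_probit()] accepts them.
#'
#' @param trial A `toxicity_trial` containing a control (concentration 0) row.
#' @return A corrected `toxicity_trial` with control mortality zeroed.
#' @export
abbott_correct <- function(trial) {
  stopifnot(inherits(trial, "toxicity_trial"))
  ctrl <- trial$concentration_mg_L == 0
  stop_if(!any(ctrl), "no control (concentration 0) record present")
  times <- observation_times(trial)
  out <- trial
  prev <- rep(0, nrow(trial))
  for (tt in times) {
    col <- sprintf("deaths_%gh", tt)
    cfrac <- trial[[col]][ctrl] / trial$n[ctrl]
    stop_if(cfrac >= 1, "control mortality is 100%; trial is uninterpretable")
    if (cfrac > 0) {
      p <- trial[[col]] / trial$n
      corr <- pmax(0, (p - cfrac) / (1 - cfrac)) * trial$n
      corr[ctrl] <- 0
      # time-varying control mortality can make corrected cumulative counts
      # dip; the running maximum restores cumulativity
      corr <- pmax(corr, prev)
      out[[col]] <- corr
    }
    prev <- out[[col]]
  }
  as_toxicity_trial(tibble::as_tibble(out))
}

#' Estimate LC50s (or LCp) across observation times
#'
#' Convenience wrapper: fits a probit at each requested time and inverts it.
#'
#' @inheritParams fit_probit
#' @inheritParams lc_p
#' @param times Observation times (h); default all in the trial.
#' @return A tibble with one row per time: `time_h`, `p`, `point` (mg/L),
#'   `ci_low`, `ci_high`, `ci_method`, `alpha`, `beta`, `converged`.
#' @export
estimate_lc50_series <- function(trial, times = observation_times(trial),
                                 p = 0.5, method = c("delta", "fieller"),
                                 log_base = 10, level = 0.95) {
  method <- match.arg(method)
  rows <- lapply(times, function(tt) {
    fit <- fit_probit(trial, tt, log_base = log_base)
    est <- lc_p(fit, p = p, method = method, level = level)
    est$alpha <- fit$alpha
    est$beta <- fit$beta
    est$converged <- fit$converged
    est
  })
  do.call(rbind, rows)
}

#' Exponential decay of LC50 with exposure time
#'
#' Fits LC50(t) = a e^(-k t) by ordinary least squares of ln(LC50) on t:
#' `a = exp(intercept)`, `k = -slope`. R-squared is reported on the fitting
#' (natural-log) scale.
#'
#' @param time_h Exposure times (h), or a data frame with columns `time_h`
#'   and `lc50` (or `point`, as produced by [estimate_lc50_series()]).
#' @param lc50 Positive LC50 values (mg/L); ignored when `time_h` is a data
#'   frame.
#' @return A `time_decay_fit`: `a`, `k`, `r_squared`, `n_points`,
#'   `intercept`, `slope`.
#' @export
#' @examples
#' fit_time_decay(c(24, 48, 72, 96), c(1.039, 0.792, 0.734, 0.655))
fit_time_decay <- function(time_h, lc50 = NULL) {
  if (is.data.frame(time_h)) {
    df <- time_h
    stop_if(!"time_h" %in% names(df), "data frame needs a `time_h` column")
    ycol <- intersect(c("lc50", "point"), names(df))
    stop_if(length(ycol) == 0, "data frame needs an `lc50` or `point` column")
    lc50 <- df[[ycol[1]]]
    time_h <- df$time_h
  }
  stop_if(length(time_h) != length(lc50), "`time_h` and `lc50` lengths differ")
  stop_if(length(time_h) < 3L, "need at least 3 (time, LC50) pairs")
  stop_if(any(lc50 <= 0), "LC50 values must be positive")
  fit <- stats::lm(log(lc50) ~ time_h)
  co <- unname(stats::coef(fit))
  structure(
    list(a = exp(co[1]), k = -co[2],
         # suppress summary.lm's note on noiseless (perfect-fit) input
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_points = length(time_h),
         intercept = co[1], slope = co[2]),
    class = "time_decay_fit")
}

#' @export
print.time_decay_fit <- function(x, ...) {
  cat(sprintf("<time_decay_fit> LC50(t) = %.4f * exp(-%.6f t), R^2 = %.4f (n = %d)\n",
              x$a, x$k, x$r_squared, x$n_points))
  invisible(x)
}

#' Predicted LC50 at a given time from a decay fit
#' @param object A `time_decay_fit`.
#' @param time_h Exposure times (h).
#' @param ... Unused.
#' @return Predicted LC50 values (mg/L).
#' @export
predict.time_decay_fit <- function(object, time_h, ...) {
  object$a * exp(-object$k * time_h)
}
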