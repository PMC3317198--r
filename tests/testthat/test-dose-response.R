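make_trial <- function(doses, deaths, n = 10, time = 96) {
  df <- data.frame(concentration_mg_L = doses, n = n)
  df[[sprintf("deaths_%gh", time)]] <- deaths
  as_toxicity_trial(df)
}

test_that("trial validation enforces the count invariants", {
  expect_error(make_trial(c(0.1, 0.1), c(1, 2)), "unique")
  expect_error(make_trial(c(0.1, 1), c(11, 2)), "0 <= deaths <= n")
  df <- data.frame(concentration_mg_L = c(0.1, 1), n = 10,
                   deaths_24h = c(3, 4), deaths_48h = c(2, 5))
  expect_error(as_toxicity_trial(df), "non-decreasing")
})

test_that("a symmetric design puts the LC50 exactly at the middle dose", {
  tr <- make_trial(c(0.1, 1, 10), c(0, 5, 10))
  fit <- fit_probit(tr, 96)
  est <- lc_p(fit, 0.5)
  expect_equal(est$point, 1.0, tolerance = 1e-6)
})

test_that("LC50 is exactly equivariant under dose rescaling", {
  tr <- random_informative_trial(11)
  fit1 <- fit_probit(tr, 96)
  tr10 <- tr
  tr10$concentration_mg_L <- tr$concentration_mg_L * 10
  fit10 <- fit_probit(as_toxicity_trial(tr10), 96)
  expect_equal(lc_p(fit10)$point, 10 * lc_p(fit1)$point, tolerance = 1e-6)
  expect_equal(fit10$beta, fit1$beta, tolerance = 1e-6)
})

test_that("the MLE matches an independent grid-search likelihood maximizer", {
  for (s in 1:5) {
    tr <- random_informative_trial(100 + s)
    fit <- fit_probit(tr, 96)
    d <- tr$deaths_96h; n <- tr$n
    orc <- oracle_grid_mle(log10(tr$concentration_mg_L), d, n)
    expect_equal(fit$alpha, orc$alpha, tolerance = 1e-4)
    expect_equal(fit$beta, orc$beta, tolerance = 1e-4)
    # and the MLE's likelihood is no worse anywhere on the oracle's grid
    expect_gte(fit$loglik, orc$loglik - 1e-6)
  }
})

test_that("lc_p closed form, root-finding oracle, and monotonicity in p", {
  tr <- make_trial(c(0.1, 1, 10), c(0, 5, 10))
  fit <- fit_probit(tr, 96)
  fit$alpha <- 0; fit$beta <- 2  # closed-form case
  expect_equal(lc_p(fit, 0.5)$point, 1.0)

  fit <- fit_probit(random_informative_trial(42), 96)
  est <- lc_p(fit, 0.5)
  root <- uniroot(function(ld) pnorm(fit$alpha + fit$beta * ld) - 0.5,
                  c(-10, 10), tol = 1e-12)$root
  expect_equal(est$point, 10^root, tolerance = 1e-8)

  ps <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  pts <- vapply(ps, function(pp) lc_p(fit, pp)$point, numeric(1))
  expect_true(all(diff(pts) > 0))
})

test_that("delta and Fieller intervals are ordered around the point estimate", {
  fit <- fit_probit(random_informative_trial(77), 96)
  for (m in c("delta", "fieller")) {
    est <- lc_p(fit, 0.5, method = m)
    expect_lt(est$ci_low, est$point)
    expect_gt(est$ci_high, est$point)
    expect_true(all(c(est$ci_low, est$ci_high) > 0))
  }
})

test_that("degenerate dose grids are rejected or flagged", {
  expect_error(fit_probit(make_trial(0.5, 3), 96), "at least 2")
  expect_error(fit_probit(make_trial(c(0.1, 0.5), c(0, 0)), 96), "informative")
  expect_error(fit_probit(make_trial(c(0.1, 0.5), c(10, 10)), 96), "informative")
  # complete separation: flagged, not silently returned
  sep <- fit_probit(make_trial(c(0.1, 0.2, 1, 2), c(0, 0, 10, 10)), 96)
  expect_true(sep$separation)
  expect_false(sep$converged)
  expect_error(lc_p(sep), "converge")
  # non-zero control mortality must be corrected first
  tr <- make_trial(c(0, 0.1, 1, 10), c(2, 0, 5, 10))
  expect_error(fit_probit(tr, 96), "abbott_correct")
})

test_that("Abbott correction: identity at zero control, (p-c)/(1-c) otherwise", {
  tr0 <- make_trial(c(0, 0.1, 1, 10), c(0, 0, 5, 10))
  expect_equal(as.data.frame(abbott_correct(tr0)), as.data.frame(tr0))
  fit_raw <- fit_probit(tr0, 96)
  fit_cor <- fit_probit(abbott_correct(tr0), 96)
  expect_equal(fit_cor$alpha, fit_raw$alpha)
  expect_equal(fit_cor$beta, fit_raw$beta)

  tr <- make_trial(c(0, 0.5), c(2, 6))
  cor <- abbott_correct(tr)
  expect_equal(cor$deaths_96h[cor$concentration_mg_L == 0.5] / 10, 0.5)
  trbad <- make_trial(c(0, 0.5), c(10, 6))
  expect_error(abbott_correct(trbad), "100%")
  expect_error(abbott_correct(make_trial(c(0.1, 0.5), c(1, 6))), "control")
})

test_that("time-decay fit: noiseless recovery and closed-form OLS agreement", {
  tt <- c(12, 36, 60, 84)
  fit <- fit_time_decay(tt, 2 * exp(-0.01 * tt))
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$k, 0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # closed-form simple-regression oracle on the observed LC50 series
  obs <- demo_lc50_series()
  fit <- fit_time_decay(obs$time_h, obs$lc50)
  x <- obs$time_h; y <- log(obs$lc50)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  expect_equal(fit$slope, slope, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)

  expect_error(fit_time_decay(c(24, 48), c(1, 0.9)), "at least 3")
  expect_error(fit_time_decay(c(24, 48, 72), c(1, -0.9, 0.8)), "positive")
  # data-frame input (as produced by estimate_lc50_series) works too
  expect_equal(fit_time_decay(obs)$a, fit$a)
})

test_that("natural-log dose metameter gives the same LC50", {
  tr <- random_informative_trial(5)
  p10 <- lc_p(fit_probit(tr, 96, log_base = 10))$point
  pe <- lc_p(fit_probit(tr, 96, log_base = exp(1)))$point
  expect_equal(p10, pe, tolerance = 1e-6)
})

test_that("trial CSV round-trips through read/write", {
  tr <- simulate_trial(trial_design(), probit_truth(), seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  back <- read_trial_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  expect_equal(observation_times(back), observation_times(tr))
})
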