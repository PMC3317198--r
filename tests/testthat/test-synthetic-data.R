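test_that("design and truth constructors reject invalid inputs", {
  expect_error(trial_design(concentrations = c(0.2, 0.1)), "increasing")
  expect_error(trial_design(concentrations = c(-1, 1)), "positive")
  expect_error(trial_design(n_per_tank = 0), ">=")
  expect_error(trial_design(observation_times = c(48, 24)), "increasing")
  expect_error(probit_truth(lc50_at_ref_time = -1), "> 0")
  expect_error(probit_truth(slope = 0), "> 0")
  expect_error(probit_truth(decay_rate = -0.1), ">=")
  expect_error(season_spec("Na", "summer", 0, 1, 5), "unknown season")
  expect_error(season_spec("Na", "dry", 0, 0, 5), "> 0")
})

test_that("infinite slope gives a step response around the LC50", {
  des <- trial_design()  # doses 0.05..1.42, n = 10
  tru <- probit_truth(lc50_at_ref_time = 0.655, slope = Inf, decay_rate = 0)
  tr <- simulate_trial(des, tru, seed = 7)
  d96 <- tr$deaths_96h
  below <- tr$concentration_mg_L < 0.655
  expect_true(all(d96[below] == 0))
  expect_true(all(d96[!below & tr$concentration_mg_L > 0.655] == 10))
})

test_that("same seed reproduces tables exactly; control mortality is zero", {
  des <- trial_design()
  tru <- probit_truth()
  expect_identical(simulate_trial(des, tru, seed = 3),
                   simulate_trial(des, tru, seed = 3))
  expect_false(identical(simulate_trial(des, tru, seed = 3),
                         simulate_trial(des, tru, seed = 4)))
  tr <- simulate_trial(des, tru, seed = 3)
  ctrl <- tr[tr$concentration_mg_L == 0, ]
  expect_true(all(ctrl[grep("^deaths_", names(ctrl))] == 0))

  sp <- list(season_spec_from_moments("Na_mg_L", "dry", 126, 43, 14),
             season_spec_from_moments("Na_mg_L", "wet", 49, 31, 13))
  expect_identical(simulate_seasonal_series(sp, seed = 5),
                   simulate_seasonal_series(sp, seed = 5))
})

test_that("cumulative deaths are pathwise monotone in time and stochastically in dose", {
  des <- trial_design(observation_times = c(12, 24, 48, 72, 96))
  tru <- probit_truth(decay_rate = 0.01)
  for (s in 1:20) {
    tr <- simulate_trial(des, tru, seed = s)
    d <- as.matrix(tr[grep("^deaths_", names(tr))])
    expect_true(all(t(apply(d, 1, diff)) >= 0))
  }
  # stochastic dose monotonicity: mean final deaths increase along the grid
  tot <- Reduce(`+`, lapply(1:200, function(s) {
    tr <- simulate_trial(des, tru, seed = s)
    tr$deaths_96h[tr$concentration_mg_L > 0]
  }))
  expect_true(all(diff(tot) >= 0))
})

test_that("empirical mortality matches the probit curve", {
  # at c = LC50(96 h) the death fraction converges to Phi(0) = 0.5
  des <- trial_design(concentrations = 0.655, observation_times = 96,
                      control_included = FALSE)
  tru <- probit_truth(lc50_at_ref_time = 0.655, slope = 4, decay_rate = 0)
  deaths <- vapply(1:500, function(s)
    simulate_trial(des, tru, seed = s)$deaths_96h, numeric(1))
  frac <- sum(deaths) / (500 * 10)
  se <- sqrt(0.5 * 0.5 / (500 * 10))
  expect_lt(abs(frac - 0.5), 3 * se)

  # three doses against their probit probabilities, 1000 reps, 3 binomial SDs
  doses <- c(0.3, 0.655, 1.1)
  des3 <- trial_design(concentrations = doses, observation_times = 96,
                       control_included = FALSE)
  deaths <- Reduce(`+`, lapply(1:1000, function(s) {
    simulate_trial(des3, tru, seed = 1000 + s)$deaths_96h
  }))
  p_true <- pnorm(4 * (log10(doses) - log10(0.655)))
  for (i in 1:3) {
    sd_i <- sqrt(p_true[i] * (1 - p_true[i]) / (1000 * 10))
    expect_lt(abs(deaths[i] / (1000 * 10) - p_true[i]), 3 * sd_i)
  }
})

test_that("background mortality enables non-zero control deaths", {
  des <- trial_design()
  tru <- probit_truth(background_mortality = 0.4)
  deaths <- vapply(1:100, function(s) {
    tr <- simulate_trial(des, tru, seed = s)
    tr$deaths_96h[tr$concentration_mg_L == 0]
  }, numeric(1))
  expect_gt(mean(deaths), 0.5)  # E = 4 per tank of 10
})

test_that("seasonal generator: identical specs give a null dm, separated specs a large one", {
  null_sp <- list(season_spec_from_moments("x", "dry", 100, 20, 14),
                  season_spec_from_moments("x", "wet", 100, 20, 13))
  hits <- vapply(1:40, function(s) {
    tab <- simulate_seasonal_series(null_sp, seed = s)
    r <- dm_statistic(tab$x[tab$season == "dry"], tab$x[tab$season == "wet"],
                      B = 200, seed = s)
    abs(r$dm) < 2
  }, logical(1))
  expect_gte(sum(hits), 36)  # |dm| < 2 in >= ~95% of seeds

  # Na-like separation: dry 126 +/- 43 (n 14) vs wet 49 +/- 31 (n 13)
  na_sp <- list(season_spec_from_moments("Na_mg_L", "dry", 126, 43, 14),
                season_spec_from_moments("Na_mg_L", "wet", 49, 31, 13))
  hits <- vapply(1:20, function(s) {
    tab <- simulate_seasonal_series(na_sp, seed = s)
    r <- dm_statistic(tab$Na_mg_L[tab$season == "dry"],
                      tab$Na_mg_L[tab$season == "wet"], B = 200, seed = s)
    r$dm > 2
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("tiny seasons (n = 2) still run, with wide SEs", {
  sp <- list(season_spec_from_moments("x", "dry", 10, 5, 2),
             season_spec_from_moments("x", "wet", 10, 5, 2))
  tab <- simulate_seasonal_series(sp, seed = 1)
  expect_equal(nrow(tab), 4)
  r <- dm_statistic(tab$x[tab$season == "dry"], tab$x[tab$season == "wet"],
                    B = 500, seed = 1)
  expect_true(is.finite(r$dm))
})

test_that("generated dates land in the right season and CSV round-trips", {
  sp <- specs_from_summary(demo_seasonal_summary())
  tab <- simulate_seasonal_series(sp, seed = 2)
  expect_identical(unname(classify_season(tab$date)), tab$season)
  # DOC only exists in the dry season rows
  expect_true(all(is.na(tab$DOC_mg_L[tab$season == "wet"])))
  f <- withr::local_tempfile(fileext = ".csv")
  write_monitoring_csv(tab, f)
  back <- read_monitoring_csv(f)
  expect_equal(back$Na_mg_L, tab$Na_mg_L)
  expect_equal(back$date, tab$date)
})
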