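# Independent oracles, deliberately implemented apart from the package's
# own code paths (plain loops, no shared helpers).

# Binomial probit log-likelihood at (a, b) for log10-dose data
oracle_loglik <- function(a, b, ld, d, n) {
  ll <- 0
  for (i in seq_along(ld)) {
    p <- pnorm(a + b * ld[i])
    p <- min(max(p, 1e-12), 1 - 1e-12)
    ll <- ll + d[i] * log(p) + (n[i] - d[i]) * log(1 - p)
  }
  ll
}

# 2-D grid maximizer with repeated zooming; resolves (a, b) to ~1e-5
oracle_grid_mle <- function(ld, d, n, a_lim = c(-25, 25), b_lim = c(-25, 25)) {
  best <- c(NA, NA)
  for (level in 1:7) {
    a_seq <- seq(a_lim[1], a_lim[2], length.out = 61)
    b_seq <- seq(b_lim[1], b_lim[2], length.out = 61)
    best_ll <- -Inf
    for (a in a_seq) for (b in b_seq) {
      ll <- oracle_loglik(a, b, ld, d, n)
      if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
    }
    da <- (a_lim[2] - a_lim[1]) / 60
    db <- (b_lim[2] - b_lim[1]) / 60
    a_lim <- best[1] + c(-1.5, 1.5) * da
    b_lim <- best[2] + c(-1.5, 1.5) * db
  }
  list(alpha = best[1], beta = best[2], loglik = best_ll)
}

# Random small informative trial (single observation time) for oracle checks:
# rejects degenerate draws (all-dead/all-alive or completely separated).
random_informative_trial <- function(seed, n_doses = 5, n = 10) {
  set.seed(seed)
  repeat {
    doses <- sort(round(10^runif(n_doses, -1.2, 0.5), 4))
    if (anyDuplicated(doses)) next
    lc50 <- 10^runif(1, -0.7, 0.2)
    slope <- runif(1, 1.5, 6)
    p <- pnorm(slope * (log10(doses) - log10(lc50)))
    d <- rbinom(n_doses, n, p)
    if (all(d == 0) || all(d == n)) next
    # at least two doses with partial mortality, so the MLE is interior and
    # the likelihood peak well-conditioned (no quasi-separation ridge)
    if (sum(d > 0 & d < n) < 2) next
    return(as_toxicity_trial(data.frame(
      concentration_mg_L = doses, n = n, deaths_96h = d)))
  }
}
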