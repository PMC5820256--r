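make_record <- function(times, durs = c(60, 60, 60), unit = "u") {
  b <- cumsum(c(0, durs))
  spike_record(unit, times,
               data.frame(period = c("OFF", "ON", "POST"),
                          start_s = b[1:3], end_s = b[2:4]))
}

test_that("rate models reproduce closed-form intensities and integrals", {
  rec <- make_record(seq(0.5, 59.5, length.out = 60))
  m <- fit_rate(rec, "OFF", "constant")
  expect_equal(m$rate_fn(10), 1)
  expect_equal(m$integral_fn(60), 60)

  # piecewise: 30 events in the first half, 60 in the second
  t2 <- c(seq(0.5, 29.9, length.out = 30), seq(30.1, 59.9, length.out = 60))
  m2 <- fit_rate(make_record(t2), "OFF", "piecewise",
                 bandwidth_or_binwidth_s = 30)
  expect_equal(m2$rate_fn(10), 1)
  expect_equal(m2$rate_fn(45), 2)
  expect_equal(m2$integral_fn(60), 90)
  expect_equal(m2$integral_fn(45), 30 + 2 * 15)

  # kernel fit on no events falls back to constant zero
  empty <- make_record(numeric(0))
  expect_warning(m0 <- fit_rate(empty, "OFF", "kernel"), "0 events")
  expect_equal(m0$rate_fn(30), 0)
})

test_that("kernel rate estimates track a sinusoidal intensity", {
  # lambda(t) = 10 + 5 sin(2 pi t / 10) on [0, 200], simulated by thinning;
  # the seed-averaged estimate isolates the estimator's bias from the
  # per-realization Poisson noise (sd ~ sqrt(lambda / (2 sqrt(pi) h)))
  lam <- function(t) 10 + 5 * sin(2 * pi * t / 10)
  grid <- seq(5, 195, by = 1)   # keep clear of edge effects
  est <- vapply(1:20, function(seed) {
    set.seed(seed)
    cand <- cumsum(rexp(4000, 15))
    cand <- cand[cand < 200]
    keep <- runif(length(cand)) < lam(cand) / 15
    rec <- make_record(cand[keep], durs = c(200, 1, 1))
    m <- fit_rate(rec, "OFF", "kernel", bandwidth_or_binwidth_s = 1)
    m$rate_fn(grid)
  }, numeric(length(grid)))
  rms <- sqrt(mean((rowMeans(est) - lam(grid))^2))
  expect_lt(rms / 10, 0.10)
})

test_that("time rescaling matches closed forms and preserves counts", {
  rec <- make_record(c(5, 15, 25, 40))
  m <- fit_rate(rec, "OFF", "constant")   # lambda = 4/60
  tau <- time_rescale(c(5, 15, 25, 40), m)
  expect_equal(as.numeric(tau), (4 / 60) * c(5, 15, 25, 40))
  expect_length(tau, 4)
  expect_equal(attr(tau, "total_rescaled_time"), 4)

  # piecewise 1 Hz before t = 10, 2 Hz after: spike at 15 -> tau = 20
  t3 <- c(seq(0.5, 9.5, length.out = 10), seq(10.5, 29.5, length.out = 40))
  m3 <- fit_rate(make_record(t3, durs = c(30, 1, 1)), "OFF", "piecewise",
                 bandwidth_or_binwidth_s = 10)
  expect_equal(m3$rate_fn(5), 1)
  expect_equal(m3$rate_fn(15), 2)
  tau3 <- time_rescale(15, m3)
  expect_equal(as.numeric(tau3), 10 * 1 + 2 * 5)

  expect_error(time_rescale(c(70), m), "outside the model support")
})

test_that("rescaled ISIs of a true-model Poisson train pass the exponentiality KS test", {
  pass <- vapply(1:100, function(seed) {
    set.seed(seed)
    t <- cumsum(rexp(300, 5))
    t <- t[t < 50]
    m <- structure(list(kind = "constant",
                        rate_fn = function(x) rep(5, length(x)),
                        integral_fn = function(x) 5 * x,
                        t0 = 0, t1 = 50, n_events = length(t)),
                   class = "rate_model")
    tau <- time_rescale(t, m)
    u <- 1 - exp(-diff(c(0, as.numeric(tau))))
    suppressWarnings(ks.test(u, "punif")$p.value) > 0.05
  }, logical(1))
  # nominal 95% acceptance, allow binomial slack
  expect_gte(mean(pass), 0.88)
  expect_lte(mean(pass), 1.0)
})

test_that("the Ogata quartet rejects deterministic and silenced alternatives", {
  # perfectly regular train: exponentiality must reject hard
  tau <- seq(1, 200)
  g <- ogata_tests(tau, 200, alpha = 0.05)
  expect_lt(g$test_exponentiality["p"], 1e-6)
  expect_true(g$rejected[["exponentiality"]])
  expect_true(g$overall_reject)

  # silenced unit: no events over a large expected count
  g0 <- ogata_tests(numeric(0), total_rescaled_time = 1080, alpha = 0.05)
  expect_true(g0$underpowered)
  expect_true(g0$rejected[["counting_band"]])
  expect_true(g0$overall_reject)

  # a healthy unit-rate train is accepted most of the time (spot check)
  set.seed(4)
  tau2 <- cumsum(rexp(200))
  g2 <- ogata_tests(tau2, tau2[200] + rexp(1), alpha = 0.05)
  expect_false(g2$overall_reject)
})

test_that("photosensitivity classification hits planted responders and respects the null", {
  # strong responder: detected in >= 80% of seeds
  hits <- vapply(1:50, function(s) {
    rec <- make_spike_trains(list(spike_ground_truth(18.2, 1.5)),
                             rng_seed = s)$records[[1]]
    isTRUE(suppressWarnings(classify_photosensitive(rec))$photosensitive)
  }, logical(1))
  expect_gte(mean(hits), 0.80)

  # null units: false-positive rate within the nominal band
  fp <- vapply(1:100, function(s) {
    rec <- make_spike_trains(list(spike_ground_truth(18.2, 1.0)),
                             rng_seed = 5000 + s)$records[[1]]
    d <- suppressWarnings(classify_photosensitive(rec))
    isTRUE(d$photosensitive)
  }, logical(1))
  sem <- sqrt(0.05 * 0.95 / 100)
  expect_lte(mean(fp), 0.05 + 2 * sem)

  # a silenced unit (empty ON period) is photosensitive
  off_t <- cumsum(rexp(2000, 18)); off_t <- off_t[off_t < 60]
  post_t <- 120 + cumsum(rexp(2000, 18)); post_t <- post_t[post_t < 180]
  rec0 <- make_record(c(off_t, post_t))
  d0 <- suppressWarnings(classify_photosensitive(rec0))
  expect_true(isTRUE(d0$photosensitive))
  expect_equal(d0$rate_on_hz, 0)
})

test_that("population statistics match independent ANOVA and Tukey computations", {
  set.seed(80)
  n <- 17
  off <- rnorm(n, 18.2, 4)
  on <- off * runif(n, 1.2, 1.7)
  post <- off + rnorm(n, 0, 0.8)
  dec <- lapply(seq_len(n), function(i)
    unit_decision(paste0("u", i), TRUE, off[i], on[i], post[i]))
  ps <- population_stats(dec)
  expect_equal(ps$fraction_pct, 100)
  expect_equal(ps$rates$mean_hz, c(mean(off), mean(on), mean(post)))

  # oracle: stats::aov with an Error stratum
  df <- data.frame(y = c(off, on, post),
                   period = factor(rep(c("OFF", "ON", "POST"), each = n)),
                   unit = factor(rep(seq_len(n), 3)))
  aov_fit <- summary(stats::aov(y ~ period + Error(unit), data = df))
  tab <- aov_fit[["Error: Within"]][[1]]
  expect_equal(ps$anova$F, tab["period", "F value"], tolerance = 1e-8)
  expect_equal(ps$anova$p, tab["period", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(ps$anova$df1, tab["period", "Df"])

  # Greenhouse-Geisser epsilon oracle via eigenvalues of the
  # double-centered covariance matrix
  X <- cbind(off, on, post)
  S <- cov(X)
  J <- 3
  Cc <- diag(J) - 1 / J
  lam <- eigen(Cc %*% S %*% Cc, symmetric = TRUE)$values[1:(J - 1)]
  eps_oracle <- sum(lam)^2 / ((J - 1) * sum(lam^2))
  expect_equal(ps$anova$epsilon_gg, eps_oracle, tolerance = 1e-8)
  expect_equal(ps$anova$p_gg,
               pf(ps$anova$F, eps_oracle * 2, eps_oracle * 2 * (n - 1),
                  lower.tail = FALSE), tolerance = 1e-8)

  # Tukey oracle from the error mean square
  ms_err <- tab["Residuals", "Mean Sq"]
  q_oracle <- abs(mean(on) - mean(off)) / sqrt(ms_err / n)
  p_oracle <- ptukey(q_oracle, 3, tab["Residuals", "Df"],
                     lower.tail = FALSE)
  row <- ps$tukey[ps$tukey$comparison == "ON - OFF", ]
  expect_equal(row$p_adj, p_oracle, tolerance = 1e-8)

  # Shapiro-Wilk on the ON - OFF differences
  expect_equal(unname(ps$shapiro["p"]),
               shapiro.test(on - off)$p.value, tolerance = 1e-10)
})

test_that("population fractions follow the exact count arithmetic", {
  mk <- function(k, n) {
    lapply(seq_len(n), function(i)
      unit_decision(paste0("u", i), i <= k))
  }
  expect_warning(p1 <- population_stats(mk(8, 27)), "fewer than 3|ANOVA")
  expect_equal(p1$fraction_pct, 100 * 8 / 27)
  expect_equal(round(p1$fraction_pct, 1), 29.6)
  expect_warning(p2 <- population_stats(mk(9, 36)), "fewer than 3|ANOVA")
  expect_equal(p2$fraction_pct, 25)

  # unclassifiable units are excluded from the denominator
  dec <- c(mk(2, 4), list(unit_decision("x", NA)))
  expect_warning(p3 <- population_stats(dec), "fewer than 3|ANOVA")
  expect_equal(p3$n_units, 4)
  expect_equal(p3$fraction_pct, 50)
})

test_that("fluorescence change and the exact Wilcoxon signed-rank test", {
  out <- fluorescence_change(rep(100, 10), rep(155.7, 10))
  expect_equal(out$pct_change, 55.7)

  # n = 10 one-signed differences: exact two-sided p = 2 / 2^10
  set.seed(90)
  before <- runif(10, 90, 110)
  after <- before + runif(10, 1, 5)
  out2 <- fluorescence_change(before, after)
  expect_equal(out2$p_value, 2 / 1024)
  expect_equal(out2$p_value, 0.001953125)
  expect_equal(round(out2$p_value, 3), 0.002)

  expect_warning(out3 <- fluorescence_change(rep(1, 6), rep(1, 6)),
                 "all paired differences are zero")
  expect_equal(out3$pct_change, 0)
  expect_equal(out3$p_value, 1)
})
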