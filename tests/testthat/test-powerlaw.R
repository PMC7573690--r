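# Power-law fitting: log-log OLS, discrete MLE, KS distance, cutoff scan,
# bootstrap goodness of fit.

test_that("log-log OLS reproduces exact power laws and the model slope", {
  f <- stats::setNames(c(2, 4, 8)^-2, c(2, 4, 8))
  # an exact power law triggers lm's perfect-fit warning, expected here
  fit <- suppressWarnings(loglog_ols_fit(f))
  expect_equal(fit$exponent, -2)
  expect_equal(fit$r.squared, 1)

  k <- c(2, 4, 6, 8)
  fit2 <- loglog_ols_fit(stats::setNames(k / 2^k, k))
  # frozen closed-form OLS slope Sxy/Sxx on the four log-pairs
  expect_equal(fit2$exponent, -1.9180439166, tolerance = 1e-9)
  # slope t-test oracle: p = 2 * P(T_2 < -|slope/se|) computed by hand
  expect_equal(fit2$p_slope, 0.0441583868, tolerance = 1e-8)
  expect_equal(fit2$n_points, 4L)

  expect_error(loglog_ols_fit(stats::setNames(c(1, 2), c(1, 2))),
               class = "homomer_insufficient_data")
  expect_error(loglog_ols_fit(stats::setNames(c(1, 0, 2), c(1, 2, 3))),
               class = "homomer_invalid_parameter")
})

test_that("discrete MLE matches the likelihood grid-search oracle", {
  vals <- c(8, 9, 10, 12, 16, 24, 40)
  g_hat <- mle_gamma(vals, 8)
  expect_equal(g_hat, grid_mle_gamma(vals, 8), tolerance = 2e-4)
  # frozen grid argmax at step 1e-4
  expect_equal(g_hat, 2.5289, tolerance = 2e-4)

  expect_error(mle_gamma(rep(8, 20), 8),
               class = "homomer_divergent_estimate")
  expect_error(mle_gamma(c(3, 9), 8), class = "homomer_invalid_parameter")
})

test_that("MLE recovers the generating exponent at large n", {
  kk <- 5:10000
  set.seed(401)
  x <- sample(kk, 10000, replace = TRUE, prob = kk^(-2.5))
  expect_lt(abs(mle_gamma(x, 5) - 2.5), 0.05)
})

test_that("MLE stays near the continuous-approximation estimator", {
  kk <- 8:100000
  for (gamma in c(2, 2.5, 3)) {
    set.seed(round(100 * gamma))
    x <- sample(kk, 10000, replace = TRUE, prob = kk^(-gamma))
    approx <- 1 + length(x) / sum(log(x / (8 - 0.5)))
    expect_lt(abs(mle_gamma(x, 8) - approx), 0.1)
  }
})

test_that("KS distance is bounded and matches hand-tabulated partial sums", {
  # toy tail {8, 8, 16} against gamma = 2, k_min = 8: CDF from direct
  # zeta partial sums (frozen from a 2e6-term summation)
  expect_equal(ks_statistic(c(8, 8, 16), 2, 8), 0.549306366558,
               tolerance = 1e-9)
  kk <- 5:5000
  set.seed(19)
  x <- sample(kk, 2000, replace = TRUE, prob = kk^(-2.2))
  D <- ks_statistic(x, 2.2, 5)
  expect_gte(D, 0)
  expect_lte(D, 1)
  expect_lt(D, 0.05)  # model-generated data sit close to the model CDF
})

test_that("KS distance agrees with an independent Riemann-zeta route", {
  skip_if_not_installed("pracma")
  # k_min = 1 makes the Hurwitz normalizer a Riemann zeta value
  x <- c(1, 1, 1, 2, 3, 5, 9)
  g <- 2.3
  z <- pracma::zeta(g)
  v <- sort(unique(x))
  ecdfv <- sapply(v, function(k) mean(x <= k))
  modelv <- sapply(v, function(k) sum((1:k)^(-g)) / z)
  expect_equal(ks_statistic(x, g, 1), max(abs(ecdfv - modelv)),
               tolerance = 1e-10)
})

test_that("cutoff scan selects small k_min on pure power-law samples", {
  p <- network_sim_params(10000, gamma = 2.5, k_min = 1, head_mean = 0,
                          seed = 23)
  d <- generate_degree_sequence(p)
  fit <- select_kmin(d)
  expect_lte(fit$k_min, unname(stats::quantile(d, 0.9)))
  expect_s3_class(fit, "power_law_fit")
  expect_true(all(c("k_min", "gamma", "n_tail", "ks_D") %in%
                    names(fit$scan)))
})

test_that("cutoff scan recovers a planted cutoff across seeds", {
  # KS-minimizing cutoff selection concentrates on the planted cutoff but
  # drifts upward in a minority of runs (every candidate above the true
  # cutoff is also correctly specified, so near-ties in D occur); the
  # frozen expectations are what the seeded recovery experiment supports
  sel <- vapply(1:50, function(s) {
    d <- generate_degree_sequence(
      network_sim_params(5000, gamma = 2.5, k_min = 8, seed = 1000 + s))
    select_kmin(d[d > 0])$k_min
  }, numeric(1))
  expect_equal(stats::median(sel), 8)
  expect_gte(mean(sel >= 6 & sel <= 10), 0.7)
})

test_that("cutoff scan is permutation-invariant and respects min_tail", {
  d <- generate_degree_sequence(network_sim_params(2000, seed = 3))
  d <- d[d > 0]
  f1 <- select_kmin(d)
  f2 <- select_kmin(sample(d))
  expect_equal(f1$k_min, f2$k_min)
  expect_equal(f1$gamma, f2$gamma)
  expect_error(suppressWarnings(select_kmin(c(3, 5, 8, 9, 11))),
               class = "homomer_insufficient_data")
})

test_that("count-table input is equivalent to raw values", {
  d <- c(5, 5, 5, 6, 6, 7, 8, 8, 9, 12, 15, 20)
  tab <- as.data.frame(table(k = d), stringsAsFactors = FALSE)
  names(tab) <- c("k", "count")
  tab$k <- as.numeric(tab$k)
  f1 <- suppressWarnings(select_kmin(d, min_tail = 5))
  f2 <- suppressWarnings(select_kmin(tab, min_tail = 5))
  expect_equal(f1$gamma, f2$gamma)
  expect_equal(f1$k_min, f2$k_min)
})

test_that("bootstrap rejects a heavily truncated geometric sample", {
  set.seed(42)
  x <- pmin(1L + stats::rgeom(5000, prob = 0.05), 60L)
  fit <- fit_degree_powerlaw(x, n_boot = 100, seed = 7)
  expect_lt(fit$p_boot, 0.1)
  expect_equal(fit$n_boot, 100L)
  expect_equal(fit$seed, 7)
})

test_that("bootstrap validates its replicate count", {
  d <- generate_degree_sequence(network_sim_params(500, seed = 1))
  fit <- select_kmin(d[d > 0])
  expect_error(bootstrap_pvalue(fit = fit, n_boot = 0),
               class = "homomer_invalid_parameter")
})

test_that("simulate draws replicates of the original size", {
  d <- generate_degree_sequence(network_sim_params(1000, seed = 2))
  fit <- select_kmin(d[d > 0])
  reps <- simulate(fit, nsim = 3, seed = 5)
  expect_length(reps, 3)
  expect_true(all(lengths(reps) == fit$n))
  expect_true(all(unlist(reps) >= 0))
})

test_that("fit serialization round-trips the headline fields", {
  dir <- withr::local_tempdir()
  d <- generate_degree_sequence(network_sim_params(1000, seed = 4))
  fit <- select_kmin(d[d > 0])
  write_powerlaw_fit(fit, file.path(dir, "fit.json"))
  j <- jsonlite::read_json(file.path(dir, "fit.json"))
  expect_equal(j$gamma, fit$gamma)
  expect_equal(j$k_min, fit$k_min)
  expect_equal(length(j$scan), nrow(fit$scan))
})
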