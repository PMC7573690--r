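# Discrete power-law fitting for degree data, and log-log least squares
# for small frequency tables.
#
# The degree-data route is the standard cutoff-scan procedure: at each
# candidate lower cutoff k_min the tail exponent gamma is estimated by
# zeta-normalized maximum likelihood, the Kolmogorov-Smirnov distance
# between empirical and model tail CDFs is computed, and the k_min
# minimizing the KS distance is selected. A semiparametric bootstrap (each
# replicate refitted with its own k_min and gamma) yields the
# goodness-of-fit p value: p > 0.1 means the power law cannot be rejected.

# Coerce raw value vectors or k -> count tables to a value vector.
as_value_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("k", "count") %in% names(x))) {
      stop_invalid_parameter("count table must have columns 'k' and 'count'")
    }
    return(rep.int(as.numeric(x$k), as.integer(x$count)))
  }
  if (is.numeric(x) && !is.null(names(x)) &&
      !anyNA(suppressWarnings(as.numeric(names(x))))) {
    return(rep.int(as.numeric(names(x)), as.integer(x)))
  }
  as.numeric(x)
}

#' Log-log least-squares power-law fit
#'
#' Fits `log f = intercept + exponent * log k` by ordinary least squares —
#' the appropriate reading for small frequency tables (e.g. the four
#' even-oligomer points), where a reported R-squared and slope p value
#' imply OLS on the transformed values. The p value is the two-sided
#' t-test on the slope with n - 2 degrees of freedom; the base of the
#' logarithm affects neither the exponent nor R-squared.
#'
#' @param points named numeric vector (names are k, values positive
#'   frequencies) or a two-column data frame `k`, `f`.
#' @return object of class `ols_power_fit`: `exponent` (slope; its
#'   magnitude corresponds to gamma in P(k) ~ k^-gamma), `intercept`,
#'   `r.squared`, `p_slope`, `n_points`, and the underlying `lm` fit.
#' @examples
#' loglog_ols_fit(stats::setNames((2:5)^-2, 2:5))  # exponent -2, R^2 = 1
#' @export
loglog_ols_fit <- function(points) {
  if (is.data.frame(points)) {
    k <- points$k; f <- points$f
  } else {
    if (is.null(names(points))) {
      stop_invalid_parameter("points must be named by k or be a data frame")
    }
    k <- as.numeric(names(points)); f <- unname(points)
  }
  if (length(k) < 3) {
    stop_insufficient_data("need at least 3 points for a log-log OLS fit")
  }
  if (any(!is.finite(f)) || any(f <= 0) || any(k <= 0)) {
    stop_invalid_parameter("all k and frequencies must be positive")
  }
  fit <- stats::lm(log(f) ~ log(k), data = data.frame(k = k, f = f))
  sm <- summary(fit)
  structure(
    list(exponent = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r.squared = sm$r.squared,
         p_slope = unname(sm$coefficients[2, 4]),
         n_points = length(k),
         lm = fit),
    class = "ols_power_fit"
  )
}

#' @export
print.ols_power_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Log-log OLS power-law fit (n = %d)\n", x$n_points))
  cat(sprintf("  P(k) ~ k^%s   R-squared = %s   p(slope) = %s\n",
              format(x$exponent, digits = digits),
              format(x$r.squared, digits = digits),
              format(x$p_slope, digits = digits)))
  invisible(x)
}

#' @export
coef.ols_power_fit <- function(object, ...) {
  c(intercept = object$intercept, exponent = object$exponent)
}

#' Maximum-likelihood tail exponent of a discrete power law
#'
#' Estimates gamma in `p(k) = k^-gamma / zeta(gamma, k_min)` for integer
#' observations `>= k_min`, maximizing the likelihood numerically (Brent
#' search, tolerance below 1e-6) with the Hurwitz-zeta normalizer. Samples
#' with fewer than two distinct values push the likelihood upward without
#' bound and raise a divergent-estimate error.
#'
#' @param tail_values integer observations, all >= `k_min`.
#' @param k_min lower cutoff.
#' @param gamma_max upper end of the search bracket.
#' @return the estimate gamma-hat.
#' @export
mle_gamma <- function(tail_values, k_min, gamma_max = 25) {
  tail_values <- as_value_vector(tail_values)
  if (length(tail_values) == 0) stop_insufficient_data("empty tail")
  if (any(tail_values < k_min)) {
    stop_invalid_parameter("all tail values must be >= k_min")
  }
  if (length(unique(tail_values)) < 2) {
    stop_divergent_estimate(
      "all tail values identical: likelihood increases without bound in gamma")
  }
  n <- length(tail_values)
  sumlog <- sum(log(tail_values))
  negll <- function(g) n * log(hurwitz_zeta(g, k_min)) + g * sumlog
  opt <- stats::optimize(negll, interval = c(1 + 1e-7, gamma_max),
                         tol = 1e-8)
  if (opt$minimum > gamma_max - 0.05) {
    stop_divergent_estimate(
      "gamma estimate ran into the search bound (%.1f); tail too degenerate",
      gamma_max)
  }
  opt$minimum
}

#' Kolmogorov-Smirnov distance between tail data and a discrete power law
#'
#' `D = max over observed k of |empirical CDF - model CDF|`, both CDFs
#' conditioned on the tail `k >= k_min`; the model CDF uses partial
#' Hurwitz-zeta sums.
#'
#' @param tail_values integer observations, all >= `k_min`.
#' @param gamma tail exponent (> 1).
#' @param k_min lower cutoff.
#' @return D in [0, 1].
#' @export
ks_statistic <- function(tail_values, gamma, k_min) {
  tail_values <- as_value_vector(tail_values)
  if (length(tail_values) == 0) stop_insufficient_data("empty tail")
  if (any(tail_values < k_min)) {
    stop_invalid_parameter("all tail values must be >= k_min")
  }
  if (gamma <= 1) stop_invalid_parameter("gamma must exceed 1")
  n <- length(tail_values)
  v <- sort(unique(tail_values))
  ecdf_v <- cumsum(tabulate(match(tail_values, v), length(v))) / n
  z <- hurwitz_zeta(gamma, k_min)
  partial <- plaw_partial_sums(gamma, k_min, max(v))
  model_v <- partial[v - k_min + 1] / z
  max(abs(ecdf_v - model_v))
}

#' Scan lower cutoffs and fit the discrete power law
#'
#' Runs the cutoff-scan fit: candidate `k_min` values are the distinct
#' observed degrees whose tail holds at least `min_tail` observations
#' (and two distinct values); each candidate is refitted by [mle_gamma()]
#' and scored by [ks_statistic()]; the candidate minimizing D wins, ties
#' going to the smallest `k_min` (largest retained tail).
#'
#' @param values integer observations (raw vector, named k -> count
#'   vector, or `k`/`count` data frame).
#' @param min_tail smallest acceptable tail size for a candidate.
#' @param gamma_max passed to [mle_gamma()].
#' @return object of class `power_law_fit`: `gamma`, `k_min`, `n_tail`,
#'   `ks_D`, `p_boot` (NA until [bootstrap_pvalue()] runs), `n_boot`,
#'   `seed`, `scan` (the candidate table), `n`, and the input `values`.
#' @export
select_kmin <- function(values, min_tail = 10, gamma_max = 25) {
  values <- as_value_vector(values)
  if (length(values) < 10) {
    warning("fewer than 10 observations; cutoff selection will be unstable")
  }
  cand <- sort(unique(values))
  tail_sizes <- vapply(cand, function(c0) sum(values >= c0), numeric(1))
  distinct_above <- vapply(cand, function(c0)
    length(unique(values[values >= c0])), numeric(1))
  cand <- cand[tail_sizes >= min_tail & distinct_above >= 2 & cand >= 1]
  if (length(cand) == 0) {
    stop_insufficient_data(
      "no candidate k_min leaves a tail of at least %d observations", min_tail)
  }
  rows <- lapply(cand, function(c0) {
    tail <- values[values >= c0]
    g <- tryCatch(mle_gamma(tail, c0, gamma_max = gamma_max),
                  homomer_divergent_estimate = function(e) NA_real_)
    if (is.na(g)) {
      return(data.frame(k_min = c0, gamma = NA_real_,
                        n_tail = length(tail), ks_D = NA_real_))
    }
    data.frame(k_min = c0, gamma = g, n_tail = length(tail),
               ks_D = ks_statistic(tail, g, c0))
  })
  scan <- do.call(rbind, rows)
  ok <- which(!is.na(scan$ks_D))
  if (length(ok) == 0) {
    stop_insufficient_data("no candidate k_min admits a finite fit")
  }
  best <- ok[which.min(scan$ks_D[ok])]  # which.min takes the first = smallest k_min on ties
  structure(
    list(gamma = scan$gamma[best],
         k_min = scan$k_min[best],
         n_tail = scan$n_tail[best],
         ks_D = scan$ks_D[best],
         p_boot = NA_real_,
         n_boot = 0L,
         seed = NULL,
         min_tail = min_tail,
         gamma_max = gamma_max,
         scan = scan,
         n = length(values),
         values = values),
    class = "power_law_fit"
  )
}

# One semiparametric replicate dataset of size n from a fitted power law:
# head values resampled empirically, tail regenerated from the fitted
# discrete power law truncated at k_max.
rplaw_semiparametric <- function(fit, n, k_max) {
  head_vals <- fit$values[fit$values < fit$k_min]
  p_tail <- fit$n_tail / fit$n
  m_tail <- stats::rbinom(1, n, p_tail)
  tail_part <- sample_plaw_tail(m_tail, fit$gamma, fit$k_min, k_max)
  head_part <- if (n - m_tail > 0) {
    sample(head_vals, n - m_tail, replace = TRUE)
  } else integer(0)
  c(head_part, tail_part)
}

#' Bootstrap goodness-of-fit p value for a power-law fit
#'
#' Semiparametric bootstrap: each replicate resamples the sub-cutoff head
#' empirically and regenerates the tail from the fitted power law, then is
#' refitted from scratch — its own cutoff scan and exponent — and its KS
#' distance recorded. `p` is the fraction of replicates whose KS distance
#' is at least the observed one; `p > 0.1` means the power-law hypothesis
#' cannot be rejected. Refitting the cutoff in every replicate is the
#' conservative (full) procedure; fixing it would inflate p.
#'
#' @param values the original observations (only used if `fit` lacks
#'   them).
#' @param fit a `power_law_fit` from [select_kmin()].
#' @param n_boot number of replicates (>= 1; hundreds recommended).
#' @param seed integer seed or NULL.
#' @param k_max truncation for tail regeneration.
#' @return the fit, updated with `p_boot`, `n_boot`, `seed`.
#' @export
bootstrap_pvalue <- function(values = NULL, fit, n_boot = 1000, seed = NULL,
                             k_max = 10000) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (length(n_boot) != 1L || !is.finite(n_boot) || n_boot < 1) {
    stop_invalid_parameter("n_boot must be a positive count")
  }
  if (!is.null(values)) fit$values <- as_value_vector(values)
  set_seed_if(seed)
  d_rep <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    x <- rplaw_semiparametric(fit, fit$n, k_max)
    rf <- tryCatch(
      select_kmin(x, min_tail = fit$min_tail, gamma_max = fit$gamma_max),
      homomer_error = function(e) NULL)
    if (!is.null(rf)) d_rep[b] <- rf$ks_D
  }
  used <- sum(!is.na(d_rep))
  if (used == 0) stop_insufficient_data("every bootstrap replicate failed to fit")
  fit$p_boot <- sum(d_rep >= fit$ks_D, na.rm = TRUE) / used
  fit$n_boot <- as.integer(n_boot)
  fit$seed <- seed
  fit
}

#' Fit a discrete power law to degree data
#'
#' The user-facing fitting routine: cutoff scan + maximum-likelihood
#' exponent via [select_kmin()], optionally followed by the bootstrap
#' goodness-of-fit test of [bootstrap_pvalue()].
#'
#' @param values integer observations (raw vector, named k -> count
#'   vector, or `k`/`count` data frame).
#' @param min_tail smallest acceptable tail for a candidate cutoff.
#' @param n_boot bootstrap replicates; 0 skips the test.
#' @param seed integer seed for the bootstrap (recorded in the result).
#' @param k_max truncation used when regenerating bootstrap tails.
#' @return a `power_law_fit`; see [select_kmin()].
#' @examples
#' d <- generate_degree_sequence(network_sim_params(2000, seed = 1))
#' fit <- fit_degree_powerlaw(d[d > 0])
#' fit
#' @export
fit_degree_powerlaw <- function(values, min_tail = 10, n_boot = 0,
                                seed = NULL, k_max = 10000) {
  fit <- select_kmin(values, min_tail = min_tail)
  if (n_boot > 0) {
    fit <- bootstrap_pvalue(fit = fit, n_boot = n_boot, seed = seed,
                            k_max = k_max)
  }
  fit
}

#' @export
print.power_law_fit <- function(x, digits = 4, ...) {
  cat("Discrete power-law fit (MLE + KS cutoff scan)\n")
  cat(sprintf("  P(k) ~ k^-%s for k >= %d   (n_tail = %d of %d)\n",
              format(x$gamma, digits = digits), x$k_min, x$n_tail, x$n))
  cat(sprintf("  KS distance D = %s", format(x$ks_D, digits = digits)))
  if (!is.na(x$p_boot)) {
    cat(sprintf("   bootstrap p = %s (n_boot = %d)",
                format(x$p_boot, digits = digits), x$n_boot))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.power_law_fit <- function(object, ...) {
  print(object)
  cat("\nCutoff scan (first rows):\n")
  print(utils::head(object$scan, 10))
  invisible(object)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  v <- sort(unique(x$values[x$values >= 1]))
  surv <- vapply(v, function(c0) mean(x$values >= c0), numeric(1))
  graphics::plot(v, surv, log = "xy", pch = 1, cex = 0.6,
                 xlab = "degree k", ylab = "P(K >= k)",
                 main = "Degree distribution and power-law tail fit", ...)
  kk <- seq.int(x$k_min, max(v))
  z <- hurwitz_zeta(x$gamma, x$k_min)
  tail_surv <- (z - c(0, plaw_partial_sums(x$gamma, x$k_min, max(v) - 1)
                      [seq_len(length(kk) - 1)])) / z
  p_tail <- x$n_tail / x$n
  graphics::lines(kk, p_tail * tail_surv, col = 2)
  graphics::abline(v = x$k_min, lty = 3)
  invisible(x)
}

#' Simulate replicate datasets from a fitted power law
#'
#' Draws semiparametric replicates (empirical head, model tail) of the
#' same size as the original data — the same mechanism the bootstrap uses.
#'
#' @param object a `power_law_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed or NULL.
#' @param k_max tail truncation.
#' @param ... unused.
#' @return list of integer vectors.
#' @export
simulate.power_law_fit <- function(object, nsim = 1, seed = NULL,
                                   k_max = 10000, ...) {
  set_seed_if(seed)
  lapply(seq_len(nsim), function(i)
    rplaw_semiparametric(object, object$n, k_max))
}

#' Serialize a power-law fit to JSON
#'
#' Writes all fit fields, the full candidate-cutoff scan table, and the
#' bootstrap seed.
#'
#' @param fit a `power_law_fit` or `ols_power_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_powerlaw_fit <- function(fit, path) {
  if (inherits(fit, "power_law_fit")) {
    out <- list(type = "discrete_mle", gamma = fit$gamma, k_min = fit$k_min,
                n_tail = fit$n_tail, ks_D = fit$ks_D, p_boot = fit$p_boot,
                n_boot = fit$n_boot, seed = fit$seed, n = fit$n,
                scan = fit$scan)
  } else if (inherits(fit, "ols_power_fit")) {
    out <- list(type = "loglog_ols", exponent = fit$exponent,
                intercept = fit$intercept, r_squared = fit$r.squared,
                p_slope = fit$p_slope, n_points = fit$n_points)
  } else {
    stop_invalid_parameter("fit must be a power_law_fit or ols_power_fit")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
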