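# Resource-precision model for homo-oligomer frequencies.
#
# A protein complex of k identical subunits costs energy roughly linear in k
# (protein synthesis) while the number of distinguishable binding
# micro-states grows as 2^k, so the relative precision of the reaction it
# carries scales as 2^-k. Balancing the two predicts the proteome frequency
# of k-subunit homo-oligomers, f_s(k), to be proportional to k / 2^k, and
# the product c(k) = f_s(k) * k plays the role of an information capacity
# (k bits at M = 2^k signal levels).

#' Energy cost of synthesizing a k-subunit homo-oligomer
#'
#' ATP cost of translating k identical chains of average length
#' `length_aa`, at `atp_per_aa` ATP per residue: `atp_per_aa * length_aa *
#' k`. The default cost per residue is 4.5 ATP; typical average protein
#' lengths are ~270 aa in bacteria and ~360 aa in eukaryotes. The value is
#' a proportionality anchor, not an exact budget.
#'
#' @param k number of identical subunits (vectorized, each >= 1).
#' @param length_aa average protein length in amino acids.
#' @param atp_per_aa ATP molecules consumed per amino acid.
#' @return numeric vector of ATP counts.
#' @examples
#' energy_cost(1)          # 1215
#' energy_cost(4, length_aa = 360)
#' @export
energy_cost <- function(k, length_aa = 270, atp_per_aa = 4.5) {
  if (length(k) == 0 || any(!is.finite(k)) || any(k < 1)) {
    stop_invalid_parameter("k must contain finite values >= 1")
  }
  if (length_aa <= 0 || atp_per_aa <= 0) {
    stop_invalid_parameter("length_aa and atp_per_aa must be positive")
  }
  atp_per_aa * length_aa * k
}

#' Number of statistical arrangements of a k-subunit complex
#'
#' Each of the k subunits carries one binding site with M distinguishable
#' occupancy states, so the complex has `M^k` statistical arrangements.
#' With binary occupancy (M = 2, the default) a trimeric enzyme has
#' 2^3 = 8 arrangements and a DNA-binding dimer 2^2 = 4.
#'
#' @param k number of subunits (vectorized, each >= 0).
#' @param M states per binding site (>= 1).
#' @return numeric vector of exact counts (exact up to 2^53).
#' @examples
#' n_arrangements(3)      # 8
#' n_arrangements(2)      # 4
#' @export
n_arrangements <- function(k, M = 2) {
  if (length(k) == 0 || any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop_invalid_parameter("k must contain nonnegative integers")
  }
  if (length(M) != 1L || !is.finite(M) || M < 1) {
    stop_invalid_parameter("M must be a single value >= 1")
  }
  out <- M^k
  if (any(out > 2^53)) {
    warning("arrangement count exceeds 2^53; result no longer exact")
  }
  out
}

#' Relative precision of a k-subunit biochemical reaction
#'
#' Precision is inversely proportional to the number of binary
#' micro-states of the complex: `2^-k`. It is the reciprocal of
#' [n_arrangements()] at M = 2.
#'
#' @param k number of subunits (vectorized, each >= 0).
#' @return numeric vector of relative precisions in (0, 1].
#' @examples
#' precision(0)  # 1
#' precision(3)  # 0.125
#' @export
precision <- function(k) {
  if (length(k) == 0 || any(!is.finite(k)) || any(k < 0)) {
    stop_invalid_parameter("k must contain nonnegative values")
  }
  2^(-k)
}

#' Model frequencies f_s(k) proportional to k / 2^k
#'
#' Evaluates the resource-precision weight `w(k) = k / 2^k` on a support of
#' subunit numbers. In `"normalized"` mode the weights are divided by their
#' sum so they form a probability distribution over the support; in
#' `"scaled"` mode the raw weights are returned for later least-squares
#' scaling.
#'
#' @param support integer vector of subunit numbers (nonempty, each >= 1).
#' @param mode `"normalized"` or `"scaled"`.
#' @return named numeric vector, names are the k values.
#' @examples
#' model_frequency(c(2, 4, 6, 8))   # 4/7, 2/7, 3/28, 1/28
#' @export
model_frequency <- function(support, mode = c("normalized", "scaled")) {
  mode <- match.arg(mode)
  if (length(support) == 0) {
    stop_invalid_parameter("support must be nonempty")
  }
  if (any(!is.finite(support)) || any(support < 1)) {
    stop_invalid_parameter("all support values must be >= 1")
  }
  w <- support / 2^support
  if (mode == "normalized") w <- w / sum(w)
  names(w) <- as.character(support)
  w
}

#' Fit the resource-precision model to an empirical distribution
#'
#' Fits `f_s(k) = A * k / 2^k` to empirical homo-oligomer frequencies on a
#' chosen support (default the even oligomers 2, 4, 6, 8). In `"scaled"`
#' mode the single scale A minimizes the residual sum of squares and has
#' the closed form `A = sum(f * w) / sum(w^2)`; in `"normalized"` mode A is
#' fixed by normalization over the support (no free parameter). The
#' goodness of fit is `r.squared = 1 - SSres / SStot` with SStot taken
#' about the empirical mean.
#'
#' @param empirical an [oligomer_frequency()] result or a named numeric
#'   vector of frequencies keyed by k.
#' @param support subunit numbers to fit over; every one must be present in
#'   `empirical`.
#' @param mode `"scaled"` (least-squares scale) or `"normalized"`.
#' @return an object of class `resource_model_fit` with components
#'   `support`, `mode`, `scale`, `empirical`, `predicted`, `residuals`,
#'   `r.squared`.
#' @examples
#' f <- model_frequency(c(2, 4, 6, 8))
#' fit <- fit_resource_model(f, mode = "normalized")
#' fit$r.squared  # 1: self-fit
#' @export
fit_resource_model <- function(empirical, support = c(2, 4, 6, 8),
                               mode = c("scaled", "normalized")) {
  mode <- match.arg(mode)
  if (inherits(empirical, "oligomer_distribution")) {
    f_emp <- empirical$freqs
  } else if (is.numeric(empirical) && !is.null(names(empirical))) {
    f_emp <- empirical
  } else {
    stop_invalid_parameter(
      "empirical must be an oligomer_distribution or a named numeric vector")
  }
  if (length(support) == 0 || any(support < 1)) {
    stop_invalid_parameter("support must be nonempty with all k >= 1")
  }
  keys <- as.character(support)
  missing_k <- setdiff(keys, names(f_emp))
  if (length(missing_k) > 0) {
    stop_invalid_parameter("empirical distribution lacks support k = %s",
                           paste(missing_k, collapse = ", "))
  }
  f <- unname(f_emp[keys])
  if (any(!is.finite(f))) {
    stop_invalid_parameter("empirical frequencies must be finite on the support")
  }
  w <- support / 2^support
  if (mode == "scaled") {
    A <- sum(f * w) / sum(w^2)
  } else {
    A <- 1 / sum(w)
  }
  pred <- A * w
  res <- f - pred
  ss_res <- sum(res^2)
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  structure(
    list(support = support, mode = mode, scale = A,
         empirical = stats::setNames(f, keys),
         predicted = stats::setNames(pred, keys),
         residuals = stats::setNames(res, keys),
         r.squared = r2),
    class = "resource_model_fit"
  )
}

#' @export
print.resource_model_fit <- function(x, digits = 4, ...) {
  cat("Resource-precision model fit: f_s(k) = A * k / 2^k\n")
  cat(sprintf("  support: k = {%s}   mode: %s\n",
              paste(x$support, collapse = ", "), x$mode))
  cat(sprintf("  scale A = %s   R-squared = %s\n",
              format(x$scale, digits = digits),
              format(x$r.squared, digits = digits)))
  invisible(x)
}

#' @export
coef.resource_model_fit <- function(object, ...) {
  c(scale = object$scale)
}

#' @export
residuals.resource_model_fit <- function(object, ...) {
  object$residuals
}

#' Predict model frequencies at new subunit numbers
#'
#' @param object a `resource_model_fit`.
#' @param newdata subunit numbers; defaults to the fitted support.
#' @param ... unused.
#' @return named numeric vector of predicted frequencies `A * k / 2^k`.
#' @export
predict.resource_model_fit <- function(object, newdata = NULL, ...) {
  k <- newdata %||% object$support
  if (any(k < 1)) stop_invalid_parameter("all k must be >= 1")
  stats::setNames(object$scale * k / 2^k, as.character(k))
}

#' @export
plot.resource_model_fit <- function(x, ...) {
  k <- x$support
  graphics::plot(k, x$empirical, pch = 19, xlab = "subunit number k",
                 ylab = expression(f[s](k)),
                 main = "Resource-precision model fit", ...)
  kk <- seq(min(k), max(k), length.out = 200)
  graphics::lines(kk, x$scale * kk / 2^kk, col = 2)
  graphics::legend("topright", legend = c("empirical", "A k/2^k"),
                   pch = c(19, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Information-capacity statistic c(k) = f_s(k) * k
#'
#' Treating the k subunits as k bits (M = 2^k signal levels) and f_s as a
#' bandwidth, the product `c(k) = f_s(k) * k` is analogous to the capacity
#' of a communication channel. For the normalized model k/2^k on the even
#' support {2,4,6,8}, c(2) = c(4) = 8/7.
#'
#' @param distribution an [oligomer_frequency()] result or named numeric
#'   vector of frequencies keyed by k.
#' @return a data frame of class `capacity_curve` with columns `k`, `f_s`
#'   and `capacity`, plus a `label` attribute.
#' @examples
#' capacity(model_frequency(c(2, 4, 6, 8)))
#' @export
capacity <- function(distribution) {
  if (inherits(distribution, "oligomer_distribution")) {
    f <- distribution$freqs
    label <- distribution$label
  } else if (is.numeric(distribution) && !is.null(names(distribution))) {
    f <- distribution
    label <- "distribution"
  } else {
    stop_invalid_parameter(
      "distribution must be an oligomer_distribution or a named numeric vector")
  }
  k <- as.numeric(names(f))
  keep <- is.finite(k)
  k <- k[keep]
  f <- unname(f[keep])
  out <- data.frame(k = k, f_s = f, capacity = f * k)
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("capacity_curve", "data.frame")
  out
}

#' @export
plot.capacity_curve <- function(x, type = "b", ...) {
  graphics::plot(x$k, x$capacity, type = type, pch = 19,
                 xlab = "subunit number k (bits)", ylab = "c(k)",
                 main = "Information capacity c(k) = f_s(k) * k", ...)
  invisible(x)
}

#' Euler totient function
#'
#' Number of integers in 1..d coprime to d, computed from the prime
#' factorization of d by trial division.
#'
#' @param d positive integer (vectorized).
#' @return integer-valued numeric vector phi(d).
#' @examples
#' euler_totient(12)  # 4
#' @export
euler_totient <- function(d) {
  if (length(d) == 0 || any(!is.finite(d)) || any(d < 1) || any(d != floor(d))) {
    stop_invalid_parameter("d must contain positive integers")
  }
  vapply(d, function(m) {
    phi <- m
    n <- m
    p <- 2
    while (p * p <= n) {
      if (n %% p == 0) {
        while (n %% p == 0) n <- n %/% p
        phi <- phi - phi / p
      }
      p <- p + 1
    }
    if (n > 1) phi <- phi - phi / n
    phi
  }, numeric(1))
}

#' Binary necklace count
#'
#' Number of binary strings of length k distinct under rotation,
#' `(1/k) * sum over divisors d of k of phi(d) * 2^(k/d)` — the arrangement
#' count appropriate for self-assembling cyclic homo-oligomers, where
#' rotated occupancy patterns are physically identical.
#'
#' @param k positive integer (vectorized).
#' @return integer-valued numeric vector of necklace counts.
#' @examples
#' necklace_count(4)  # 6
#' necklace_count(6)  # 14
#' @export
necklace_count <- function(k) {
  if (length(k) == 0 || any(!is.finite(k)) || any(k < 1) || any(k != floor(k))) {
    stop_invalid_parameter("k must contain positive integers")
  }
  vapply(k, function(m) {
    divs <- which(m %% seq_len(m) == 0)
    sum(euler_totient(divs) * 2^(m / divs)) / m
  }, numeric(1))
}

#' Hill response function
#'
#' Fractional response `H = s^n / (s^n + Kd)` of a cooperative binding
#' reaction with Hill coefficient n, dissociation constant Kd and free
#' ligand concentration s; n = 1 recovers the Michaelis-Menten hyperbola
#' and n > 1 gives the ultrasensitive sigmoid characteristic of
#' multi-subunit binding. The denominator uses Kd as written (not Kd^n),
#' which makes the half-maximal point s = Kd^(1/n); set `kd_raised = TRUE`
#' for the dimensionally consistent variant `s^n / (s^n + Kd^n)` with
#' half-maximum at s = Kd.
#'
#' @param s free ligand/protein concentration (vectorized, >= 0).
#' @param n Hill coefficient (> 0).
#' @param Kd dissociation constant (> 0).
#' @param kd_raised raise Kd to the n-th power in the denominator.
#' @return numeric vector of responses in [0, 1].
#' @examples
#' hill_response(1, n = 2, Kd = 1)  # 0.5
#' @export
hill_response <- function(s, n, Kd, kd_raised = FALSE) {
  if (length(s) == 0 || any(!is.finite(s)) || any(s < 0)) {
    stop_invalid_parameter("s must contain nonnegative values")
  }
  if (length(n) != 1L || !is.finite(n) || n <= 0) {
    stop_invalid_parameter("Hill coefficient n must be positive")
  }
  if (length(Kd) != 1L || !is.finite(Kd) || Kd <= 0) {
    stop_invalid_parameter("Kd must be positive")
  }
  denom_kd <- if (kd_raised) Kd^n else Kd
  s^n / (s^n + denom_kd)
}
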