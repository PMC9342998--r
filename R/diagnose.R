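#' Normalized one-step-ahead residuals
#'
#' `r(t) = (y(t) - H E[n(t)]) / sd_pred(t)` per observable, where the
#' prediction is the one-step-ahead mean and the divisor the predicted
#' standard deviation (innovation SD for the Kalman filter, the
#' independent-draw SD for the rate-equation baseline). At the true
#' parameters the filter's residuals form a unit-variance white-noise
#' process; the baseline's do not.
#'
#' @inheritParams kf_loglik
#' @param method `"kf"` or `"re"`.
#' @return Tibble of class `residual_series`: `time`, `conc`, `obs`,
#'   `r`; the initialization sample of each trace is dropped.
#' @export
normalized_residuals <- function(traces, scheme, rates, noise,
                                 method = c("kf", "re"),
                                 observe = NULL) {
  method <- match.arg(method)
  pred <- if (method == "kf") {
    kf_filter(traces, scheme, rates, noise, observe)
  } else {
    re_filter(traces, scheme, rates, noise, observe)
  }
  if (any(pred$pred_sd[!pred$first] <= 0))
    stop("zero predicted variance")
  out <- dplyr::transmute(dplyr::filter(pred, !.data$first),
                          time = .data$time, conc = .data$conc,
                          obs = .data$obs,
                          r = (.data$y - .data$pred_mean) / .data$pred_sd)
  class(out) <- c("residual_series", class(out))
  out
}

#' Autocorrelation of a residual series
#'
#' Standard biased ACF estimator with the +/- 2/sqrt(N) white-noise
#' null bands, per observable (and pooling across traces by averaging
#' per-trace estimates weighted by length).
#'
#' @param r Numeric vector, or a `residual_series` tibble.
#' @param max_lag Largest lag to estimate.
#' @return Tibble `lag`, `acf`, `band` (the white-noise band
#'   half-width), plus `obs`/`conc` columns when `r` is grouped.
#' @export
residual_acf <- function(r, max_lag = 20) {
  if (inherits(r, "residual_series") || is.data.frame(r)) {
    return(dplyr::group_modify(
      dplyr::group_by(r, .data$obs, .data$conc),
      ~ residual_acf(.x$r, max_lag)))
  }
  n <- length(r)
  if (n <= max_lag) stop("series shorter than max_lag")
  if (stats::sd(r) == 0) stop("constant series: variance undefined")
  a <- stats::acf(r, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[-1]
  tibble::tibble(lag = seq_len(max_lag), acf = as.numeric(a),
                 band = 2 / sqrt(n))
}

#' Euclidean accuracy summary of a point estimate
#'
#' `sum_i (theta_i / theta_true_i - 1)^2` over the supplied parameters
#' (as printed: a sum of squared relative deviations, no square root;
#' conventionally computed over the rates and equilibrium constants of
#' the rate matrix, with the marginal posterior medians as the point
#' estimate).
#'
#' @param theta Named point estimates.
#' @param theta_true Named true values (same names, nonzero).
#' @return Scalar error.
#' @export
euclidean_error <- function(theta, theta_true) {
  theta <- unlist(theta); theta_true <- unlist(theta_true)
  if (!setequal(names(theta), names(theta_true)) ||
      length(theta) != length(theta_true))
    stop("parameter sets do not match")
  theta_true <- theta_true[names(theta)]
  if (any(theta_true == 0)) stop("true values must be nonzero")
  sum((theta / theta_true - 1)^2)
}

#' Highest-density credible interval of a sample
#'
#' Shortest interval containing the requested empirical probability
#' mass (sorted-window method). HDCIs are nested in the mass.
#'
#' @param x Numeric draws (>= 1000 recommended).
#' @param mass Probability mass in (0, 1).
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
hdci <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  j <- which.min(width)
  c(x[j], x[j + k])
}

#' Probability mass to cover the truth: histogram method
#'
#' Bins the n-dimensional draws on a regular grid, ranks bins by count
#' (density) in descending order and accumulates probability mass until
#' the bin containing `theta_true` is absorbed -- the mass of the
#' smallest highest-density credible volume that covers the truth. A
#' truth outside every occupied bin returns 1 with attribute
#' `out_of_support = TRUE`.
#'
#' @param samples Matrix or data frame of draws (rows) x dimensions.
#' @param theta_true Numeric true vector.
#' @param bins Bins per axis; default `ceiling(S^(1/(d+2)))`.
#' @return Mass in (0, 1], with attribute `out_of_support`.
#' @export
mass_to_cover_histogram <- function(samples, theta_true, bins = NULL) {
  X <- as.matrix(samples)
  if (!nrow(X)) stop("empty samples")
  d <- ncol(X)
  if (is.null(bins)) bins <- max(2L, ceiling(nrow(X)^(1 / (d + 2))))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  binned <- vapply(seq_len(d), function(j)
    pmin(pmax(ceiling((X[, j] - lo[j]) / span[j] * bins), 1), bins),
    numeric(nrow(X)))
  binned <- matrix(binned, ncol = d)
  key <- apply(binned, 1, paste, collapse = "/")
  counts <- sort(table(key), decreasing = TRUE)
  tb <- ceiling((theta_true - lo) / span * bins)
  outside <- any(theta_true < lo | theta_true > hi)
  tb <- pmin(pmax(tb, 1L), bins)
  tkey <- paste(tb, collapse = "/")
  if (outside || !tkey %in% names(counts)) {
    return(structure(1, out_of_support = TRUE))
  }
  cum <- cumsum(counts) / nrow(X)
  structure(unname(cum[[match(tkey, names(counts))]]),
            out_of_support = FALSE)
}

#' Probability mass to cover the truth: Mahalanobis method
#'
#' Analytic counterpart of the histogram volume count under a
#' multivariate-normal approximation: the mass inside the ellipsoid
#' through the truth is `pchisq(d_Mah^2, dim)` with `d_Mah` the
#' Mahalanobis distance of the truth from the sample mean under the
#' sample covariance. In one dimension, `d_Mah = 1` recovers the usual
#' 0.682.
#'
#' @param samples Matrix or data frame of draws.
#' @param theta_true Numeric true vector.
#' @return Mass in [0, 1).
#' @export
mass_to_cover_mahalanobis <- function(samples, theta_true) {
  X <- as.matrix(samples)
  mu <- colMeans(X)
  S <- stats::cov(X)
  ch <- tryCatch(chol(S), error = function(e)
    stop("singular sample covariance"))
  z <- backsolve(ch, theta_true - mu, transpose = TRUE)
  stats::pchisq(sum(z^2), df = ncol(X))
}

#' Beta posterior over a binomial coverage rate
#'
#' Conjugate `Beta(1 + successes, 1 + trials - successes)` update of a
#' flat prior on the true success probability of a coverage test
#' (e.g. how often a 0.95 HDCI contains the truth).
#'
#' @param successes,trials Non-negative counts, successes <= trials.
#' @return Tibble with `shape1`, `shape2`, `mean`, `lo`, `hi` (central
#'   0.95 interval).
#' @export
coverage_calibration <- function(successes, trials) {
  stopifnot(successes >= 0, successes <= trials)
  a <- 1 + successes
  b <- 1 + trials - successes
  tibble::tibble(shape1 = a, shape2 = b, mean = a / (a + b),
                 lo = stats::qbeta(0.025, a, b),
                 hi = stats::qbeta(0.975, a, b))
}

#' Joint lower bound for simultaneous credible intervals
#'
#' Under independence, the probability that `k` marginal intervals of
#' mass `p` all cover simultaneously is at least `p^k` (e.g.
#' `0.95^6 = 0.735`); treating them as one interval gives the upper
#' bound `p`.
#'
#' @param p Marginal interval mass.
#' @param k Number of simultaneous intervals.
#' @return `p^k`.
#' @export
joint_coverage_lower_bound <- function(p, k) p^k

#' Fit the error-scaling law a / sqrt(Nch)
#'
#' Least-squares fit on the log scale with the exponent fixed at -1/2:
#' `log(err) = log(a) - 0.5 log(Nch)`. The ratio of two fitted
#' coefficients (baseline over filter) is the benchmark error ratio. A
#' large residual SD on the log scale flags series that do not follow
#' the law.
#'
#' @param errors Positive error values.
#' @param nch Matching channel counts.
#' @param flag_sd Residual-SD threshold for the misfit flag.
#' @return List with `a`, `resid_sd`, `flagged`.
#' @export
fit_error_scaling <- function(errors, nch, flag_sd = 0.5) {
  stopifnot(length(errors) == length(nch), length(errors) >= 3)
  if (any(errors <= 0) || any(nch <= 0))
    stop("errors and nch must be positive")
  la <- mean(log(errors) + 0.5 * log(nch))
  resid <- log(errors) + 0.5 * log(nch) - la
  list(a = exp(la), resid_sd = stats::sd(resid),
       flagged = stats::sd(resid) > flag_sd)
}

#' Flag draws piling against the sampling box
#'
#' Operational improper-posterior detection: a parameter is flagged
#' when at least `frac` of its draws lie within `tol` (relative to the
#' box width) of a finite prior bound -- the sample-based criterion for
#' a posterior that is only confined by the sampling box.
#'
#' @param fit A `pkf_fit`.
#' @param priors The prior list used for the fit (defaults to the one
#'   stored in the fit).
#' @param frac Flag threshold on the edge fraction (default 0.01).
#' @param tol Relative edge width (default 0.001).
#' @return Tibble `term`, `edge_frac`, `improper`.
#' @export
improper_flags <- function(fit, priors = NULL, frac = 0.01,
                           tol = 0.001) {
  if (is.null(priors)) priors <- attr(fit, "meta")$priors
  pars <- intersect(names(priors), names(fit))
  purrr::map_dfr(pars, function(p) {
    pr <- priors[[p]]
    v <- fit[[p]]
    ef <- if (is.finite(pr$lower) && is.finite(pr$upper)) {
      w <- (pr$upper - pr$lower) * tol
      mean(v < pr$lower + w | v > pr$upper - w)
    } else NA_real_
    tibble::tibble(term = p, edge_frac = ef,
                   improper = isTRUE(ef >= frac))
  })
}
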