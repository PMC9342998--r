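#' Prior specifications
#'
#' One prior per sampled parameter. Supported laws: `uniform(lo, hi)`
#' on the natural scale (the package default for rates, mirroring the
#' plain-uniform sampling-box convention), `normal(mean, sd)`,
#' `gamma(shape, rate)`, and `beta_mr(a, b)` -- a beta draw on (0, 1)
#' feeding the hierarchical microscopic-reversibility transform of a
#' declared loop. Every prior also fixes the sampling-box support
#' (`lower`, `upper`); the log-posterior is `-Inf` outside it.
#'
#' @param lo,hi Uniform bounds (0 < lo < hi for rates).
#' @name priors
#' @return A `prior` object (list with `dist`, `args`, `lower`,
#'   `upper`).
NULL

new_prior <- function(dist, args, lower, upper) {
  structure(list(dist = dist, args = args, lower = lower, upper = upper),
            class = "prior")
}

#' @rdname priors
#' @export
prior_uniform <- function(lo, hi) {
  stopifnot(hi > lo)
  new_prior("uniform", c(lo = lo, hi = hi), lo, hi)
}

#' @rdname priors
#' @param mean,sd Normal moments.
#' @param lower,upper Optional truncation / sampling-box bounds.
#' @export
prior_normal <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0)
  new_prior("normal", c(mean = mean, sd = sd), lower, upper)
}

#' @rdname priors
#' @param shape,rate Gamma parameters.
#' @export
prior_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  new_prior("gamma", c(shape = shape, rate = rate), 0, Inf)
}

#' @rdname priors
#' @param a,b Beta hyperparameters; the default `beta(100.01, 100.01)`
#'   concentrates the completed loop rate within +/- 0.5 percent of
#'   strict microscopic reversibility.
#' @export
prior_beta_mr <- function(a = 100.01, b = 100.01) {
  stopifnot(a > 0, b > 0)
  new_prior("beta_mr", c(a = a, b = b), 0, 1)
}

log_prior_one <- function(pr, x) {
  if (x < pr$lower || x > pr$upper) return(-Inf)
  switch(pr$dist,
         uniform = -log(pr$args[["hi"]] - pr$args[["lo"]]),
         normal = stats::dnorm(x, pr$args[["mean"]], pr$args[["sd"]],
                               log = TRUE),
         gamma = stats::dgamma(x, pr$args[["shape"]],
                               rate = pr$args[["rate"]], log = TRUE),
         beta_mr = stats::dbeta(x, pr$args[["a"]], pr$args[["b"]],
                                log = TRUE))
}

draw_prior_one <- function(pr) {
  switch(pr$dist,
         uniform = stats::runif(1, pr$args[["lo"]], pr$args[["hi"]]),
         normal = {
           repeat {
             x <- stats::rnorm(1, pr$args[["mean"]], pr$args[["sd"]])
             if (x >= pr$lower && x <= pr$upper) break
           }
           x
         },
         gamma = stats::rgamma(1, pr$args[["shape"]],
                               rate = pr$args[["rate"]]),
         beta_mr = stats::rbeta(1, pr$args[["a"]], pr$args[["b"]]))
}

#' Complete a rate set through the microscopic-reversibility transform
#'
#' Given the free rates of a declared loop and a hierarchical draw
#' `k1star` in (0, 1), the loop's target rate is set to
#' `R * (0.995 + 0.01 * k1star)` where
#' `R = prod(numer) / prod(denom)` is the rate that would enforce
#' strict microscopic reversibility; the completed set's loop imbalance
#' therefore lies within +/- 0.005 of 1. The map between
#' (free rates, k1star) and completed sets is a bijection on the band.
#'
#' @param scheme A `kinetic_scheme` with a declared loop.
#' @param rates Named rates containing `numer` and `denom` parameters.
#' @param k1star Hierarchical draw in (0, 1) (typically
#'   [prior_beta_mr()]).
#' @param loop Loop index (default 1).
#' @return `rates` with the target parameter filled in.
#' @export
micro_reversibility_transform <- function(scheme, rates, k1star,
                                          loop = 1) {
  rates <- unlist(rates)
  lp <- scheme$loops[[loop]]
  if (is.null(lp)) stop("scheme declares no loop ", loop)
  if (k1star <= 0 || k1star >= 1) stop("k1star must lie in (0, 1)")
  den <- prod(rates[lp$denom])
  if (den == 0) stop("zero denominator rate in loop")
  R <- prod(rates[lp$numer]) / den
  rates[lp$target] <- R * (0.995 + 0.01 * k1star)
  rates
}

# assemble the full rate set (and theta) from sampled + fixed parts,
# applying the micro-reversibility transform if a *_star parameter is
# present for a loop target.
assemble_rates <- function(scheme, sampled, fixed_rates) {
  rates <- fixed_rates
  star <- grep("_star$", names(sampled), value = TRUE)
  plain <- setdiff(names(sampled), star)
  rates[plain] <- sampled[plain]
  for (s in star) {
    rates <- micro_reversibility_transform(scheme, rates, sampled[[s]])
  }
  rates
}

#' Log posterior density of the model parameters
#'
#' Sum of the log-likelihood (Kalman filter or rate-equation baseline)
#' and the log priors of the sampled parameters; `-Inf` outside the
#' sampling box. Deterministic in `theta` for fixed data.
#'
#' @param theta Named numeric vector of sampled parameters. Rate
#'   parameters not listed are taken from `rates`; noise parameters
#'   present in `theta` (`i`, `sigma_m`, `sigma_op`, `lambda_b`,
#'   `sigma_back`, `nch`) override `noise`. A parameter named
#'   `<x>_star` is a microscopic-reversibility draw completing the
#'   scheme's loop target.
#' @param traces A `trace_set`.
#' @param scheme A `kinetic_scheme`.
#' @param priors Named list of [priors] for every entry of `theta`.
#' @param rates Fixed/true rates supplying unsampled parameters.
#' @param noise A [noise_params()] vector for unsampled noise terms.
#' @param method `"kf"` or `"re"`.
#' @param loglik_weight Set to 0 to switch the likelihood off
#'   (prior-only target, used for sampler validation).
#' @return Scalar log posterior.
#' @export
log_posterior <- function(theta, traces, scheme, priors, rates,
                          noise = noise_params(),
                          method = c("kf", "re"), loglik_weight = 1) {
  method <- match.arg(method)
  lp <- 0
  for (nm in names(theta)) {
    lp <- lp + log_prior_one(priors[[nm]], theta[[nm]])
    if (!is.finite(lp)) return(-Inf)
  }
  if (loglik_weight == 0) return(lp)
  for (nm in intersect(names(theta), names(noise)))
    noise[[nm]] <- theta[[nm]]
  full <- assemble_rates(scheme, theta, unlist(rates))
  ll <- tryCatch(
    if (method == "kf") kf_loglik(traces, scheme, full, noise)
    else re_loglik(traces, scheme, full, noise),
    error = function(e) {
      warning("likelihood failure at theta = ",
              paste(signif(theta, 4), collapse = ", "), ": ",
              conditionMessage(e))
      -Inf
    })
  lp + loglik_weight * ll
}

# unconstrained internal scale per prior: log for positive supports,
# logit for boxes, identity otherwise; log|Jacobian| included so the
# user-declared prior applies on the natural scale.
par_transform <- function(pr) {
  if (is.finite(pr$lower) && is.finite(pr$upper)) {
    lo <- pr$lower; hi <- pr$upper
    list(fwd = function(x) stats::qlogis((x - lo) / (hi - lo)),
         bwd = function(z) lo + (hi - lo) * stats::plogis(z),
         ljac = function(z) log(hi - lo) + stats::plogis(z, log.p = TRUE) +
           stats::plogis(-z, log.p = TRUE))
  } else if (is.finite(pr$lower)) {
    lo <- pr$lower
    list(fwd = function(x) log(x - lo),
         bwd = function(z) lo + exp(z),
         ljac = function(z) z)
  } else {
    list(fwd = identity, bwd = identity, ljac = function(z) 0)
  }
}

#' Sample the posterior over model parameters
#'
#' Built-in adaptive random-walk Metropolis sampler (the pluggable
#' default backend): parameters are mapped to an unconstrained scale
#' (log for positive, logit for boxed supports, Jacobians included),
#' the proposal covariance and step size are adapted during warmup
#' (Robbins-Monro toward 0.234 acceptance) and frozen afterwards.
#' Chains run sequentially from a single seed; identical seeds give
#' identical draws.
#'
#' @inheritParams log_posterior
#' @param chains Number of chains.
#' @param iter Post-warmup draws per chain.
#' @param warmup Adaptation iterations (discarded).
#' @param seed Integer seed.
#' @param init `"prior"` (draw until finite, 50 tries) or a named
#'   vector of starting values.
#' @param chain_drop_tol With multiple chains, a chain whose best log
#'   posterior trails the best chain's by more than this is treated as
#'   stuck in a minor mode and dropped from the returned draws (the
#'   count is recorded in the fit metadata). Set to `Inf` to keep all
#'   chains.
#' @param backend A function with this signature to delegate sampling
#'   to; the default runs the built-in sampler.
#' @return A `pkf_fit`: tibble of draws (columns `.chain`, `.iter`,
#'   one per parameter, `lp`) with sampler metadata in attributes.
#' @export
sample_posterior <- function(traces, scheme, priors, rates,
                             noise = noise_params(),
                             method = c("kf", "re"), chains = 2,
                             iter = 500, warmup = 500, seed = 1,
                             init = "prior", loglik_weight = 1,
                             chain_drop_tol = 50, backend = NULL) {
  method <- match.arg(method)
  if (!is.null(backend))
    return(backend(traces, scheme, priors, rates, noise, method,
                   chains, iter, warmup, seed, init))
  set.seed(seed)
  pars <- names(priors)
  trans <- lapply(priors, par_transform)
  lp_fun <- function(theta)
    log_posterior(theta, traces, scheme, priors, rates, noise, method,
                  loglik_weight)
  target <- function(z) {
    theta <- vapply(seq_along(pars),
                    function(j) trans[[j]]$bwd(z[j]), numeric(1))
    names(theta) <- pars
    lj <- sum(vapply(seq_along(pars),
                     function(j) trans[[j]]$ljac(z[j]), numeric(1)))
    lp <- lp_fun(theta)
    list(lp = lp + lj, lp_nat = lp, theta = theta)
  }
  d <- length(pars)
  draws <- list()
  acc_tot <- 0
  for (ch in seq_len(chains)) {
    # initialization: prior draws until the posterior is finite
    z <- NULL
    for (try in 1:50) {
      theta0 <- if (is.character(init) && init == "prior") {
        vapply(priors, draw_prior_one, numeric(1))
      } else unlist(init)[pars]
      names(theta0) <- pars
      z0 <- vapply(seq_along(pars),
                   function(j) trans[[j]]$fwd(theta0[[j]]), numeric(1))
      if (is.finite(target(z0)$lp)) { z <- z0; break }
      if (!is.character(init)) stop("supplied init has -Inf posterior")
    }
    if (is.null(z)) stop("no finite initialization found in 50 prior draws")
    cur <- target(z)
    scale <- 2.38 / sqrt(d)
    cov_L <- diag(d)
    zbar <- z
    zcov <- diag(1e-4, d)
    nacc <- 0
    out <- matrix(NA_real_, iter, d + 1)
    for (it in seq_len(warmup + iter)) {
      prop <- z + scale * as.numeric(cov_L %*% stats::rnorm(d))
      cand <- target(prop)
      a <- cand$lp - cur$lp
      if (is.finite(a) && log(stats::runif(1)) < a) {
        z <- prop; cur <- cand; nacc <- nacc + 1
      }
      if (it <= warmup) {
        eta <- 1 / (it + 10)^0.6
        acc <- if (is.finite(a)) min(1, exp(a)) else 0
        scale <- scale * exp(eta * (acc - 0.234))
        dz <- z - zbar
        zbar <- zbar + eta * dz
        zcov <- zcov + eta * (tcrossprod(dz) - zcov)
        if (it %% 50 == 0) {
          ch_try <- tryCatch(chol(zcov + diag(1e-10, d)),
                             error = function(e) NULL)
          if (!is.null(ch_try)) cov_L <- t(ch_try)
        }
      } else {
        out[it - warmup, ] <- c(cur$theta, cur$lp_nat)
      }
    }
    acc_tot <- acc_tot + nacc / (warmup + iter)
    colnames(out) <- c(pars, "lp")
    draws[[ch]] <- dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iter = seq_len(iter)),
      tibble::as_tibble(out))
  }
  fit <- dplyr::bind_rows(draws)
  dropped <- 0L
  if (chains > 1 && is.finite(chain_drop_tol)) {
    best <- tapply(fit$lp, fit$.chain, max)
    keep <- names(best)[best >= max(best) - chain_drop_tol]
    dropped <- chains - length(keep)
    if (dropped > 0) fit <- fit[fit$.chain %in% as.integer(keep), ]
  }
  attr(fit, "meta") <- list(method = method, chains = chains,
                            iter = iter, warmup = warmup, seed = seed,
                            accept_rate = acc_tot / chains,
                            dropped_chains = dropped,
                            priors = priors)
  class(fit) <- c("pkf_fit", class(fit))
  fit
}

#' @export
print.pkf_fit <- function(x, ...) {
  m <- attr(x, "meta")
  cat("<pkf_fit> method = ", m$method, ", ", m$chains, " chain(s) x ",
      m$iter, " draws (warmup ", m$warmup, "), accept = ",
      signif(m$accept_rate, 3), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries
#'
#' One row per parameter: posterior median (the package's point
#' estimate), mean, SD and the bounds of the highest-density credible
#' interval of the requested mass.
#'
#' @param x A `pkf_fit`.
#' @param mass HDCI probability mass (default 0.95).
#' @param ... Unused.
#' @return Tibble with columns `term`, `median`, `mean`, `sd`,
#'   `hdci_lo`, `hdci_hi`.
#' @export
tidy.pkf_fit <- function(x, mass = 0.95, ...) {
  pars <- setdiff(names(x), c(".chain", ".iter", "lp"))
  purrr::map_dfr(pars, function(p) {
    v <- x[[p]]
    ci <- hdci(v, mass)
    tibble::tibble(term = p, median = stats::median(v), mean = mean(v),
                   sd = stats::sd(v), hdci_lo = ci[1], hdci_hi = ci[2])
  })
}

#' One-row fit summary
#'
#' @param x A `pkf_fit`.
#' @param ... Unused.
#' @return Tibble with draw counts, acceptance rate and max log
#'   posterior.
#' @export
glance.pkf_fit <- function(x, ...) {
  m <- attr(x, "meta")
  tibble::tibble(method = m$method, chains = m$chains,
                 draws = nrow(x), accept_rate = m$accept_rate,
                 lp_max = max(x$lp))
}
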