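#' Ensemble moment state
#'
#' The filter's belief about the hidden ensemble at one time: mean
#' occupancy vector `n` (channels) and covariance matrix `P`
#' (channels^2). `P` is kept symmetric; prediction preserves the total
#' mean channel count.
#'
#' @param n Mean occupancy M-vector.
#' @param P M x M covariance matrix.
#' @return Object of class `ensemble_state`.
#' @export
ensemble_state <- function(n, P) {
  stopifnot(length(n) == nrow(P), nrow(P) == ncol(P))
  P <- 0.5 * (P + t(P))
  # PSD projection by eigenvalue clipping when P dips below the
  # -1e-8 * trace tolerance (negative mean components make Q
  # indefinite at low occupancy)
  tr <- max(sum(diag(P)), .Machine$double.xmin)
  ev <- eigen(P, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * tr) {
    P <- ev$vectors %*% diag(pmax(ev$values, 0), length(n)) %*%
      t(ev$vectors)
    P <- 0.5 * (P + t(P))
  }
  structure(list(n = as.numeric(n), P = P), class = "ensemble_state")
}

#' Equilibrium initial state of the filter
#'
#' Multinomial moments at the equilibrium occupancy `p` of K:
#' `n = Nch p`, `P = Nch (diag(p) - p p')`.
#'
#' @param K Rate matrix at the resting concentration.
#' @param nch Number of channels.
#' @return An [ensemble_state()].
#' @export
init_state <- function(K, nch) {
  p <- equilibrium_distribution(K)
  ensemble_state(nch * p, nch * (diag(p) - tcrossprod(p)))
}

#' One-step prediction of the ensemble moments
#'
#' Propagates mean and covariance through the single-channel transition
#' matrix: `n' = T n` and `P' = Q(T, n) + T P T'` with the
#' generalized-multinomial process noise
#' `Q(T, n) = diag(T n) - T diag(n) T'`. These moments are exact for
#' the count-vector dynamics of independent channels.
#'
#' @param state An [ensemble_state()].
#' @param Tm Column-stochastic transition matrix.
#' @return Predicted `ensemble_state`.
#' @export
kf_predict <- function(state, Tm) {
  n <- state$n
  Tn <- as.numeric(Tm %*% n)
  P <- diag(Tn, length(Tn)) - Tm %*% diag(n, length(n)) %*% t(Tm) +
    Tm %*% state$P %*% t(Tm)
  ensemble_state(Tn, P)
}

#' Observation model of a scheme
#'
#' Builds the observation matrix H and the state-dependent noise rule.
#' For cPCF the fluorescence row is `lambda_b * bound_ligands` and the
#' current row `i * conducting`; for PC only the current row is used.
#' Row order is recorded in `rows` and the filter is invariant to it.
#'
#' @param scheme A `kinetic_scheme`.
#' @param noise A [noise_params()] vector.
#' @param observe `"cpcf"` or `"pc"`.
#' @param rows Row order for cPCF, a permutation of
#'   `c("flu", "curr")`.
#' @return List with `H`, `rows`, `wopen` (conducting weights) and
#'   `noise`.
#' @export
observation_model <- function(scheme, noise, observe = c("cpcf", "pc"),
                              rows = c("flu", "curr")) {
  observe <- match.arg(observe)
  hcurr <- noise[["i"]] * scheme$conducting
  hflu <- noise[["lambda_b"]] * scheme$bound_ligands
  if (observe == "pc") {
    H <- matrix(hcurr, nrow = 1)
    rows <- "curr"
  } else {
    stopifnot(setequal(rows, c("flu", "curr")))
    H <- rbind(flu = hflu, curr = hcurr)[rows, , drop = FALSE]
  }
  dimnames(H) <- list(rows, scheme$states)
  list(H = H, rows = rows, wopen = scheme$conducting, noise = noise)
}

#' State-dependent observation covariance
#'
#' Diagonal noise covariance evaluated at the prior mean: the current
#' entry is `sigma_m^2 + sigma_op^2 * max(n_open, 0)` and the
#' fluorescence entry `sigma_back^2 + max((H n)_flu, 0)` (the Poisson
#' variance under its normal approximation). Occupancy-dependent terms
#' are floored at zero; the mean itself is never clamped.
#'
#' @param state An [ensemble_state()] (prior).
#' @param obs An [observation_model()].
#' @return Diagonal covariance matrix (N_obs x N_obs).
#' @export
observation_covariance <- function(state, obs) {
  ns <- obs$noise
  sig <- vapply(seq_along(obs$rows), function(r) {
    if (obs$rows[r] == "curr") {
      nop <- sum(obs$wopen * state$n)
      ns[["sigma_m"]]^2 + ns[["sigma_op"]]^2 * max(nop, 0)
    } else {
      mflu <- sum(obs$H[r, ] * state$n)
      ns[["sigma_back"]]^2 + max(mflu, 0)
    }
  }, numeric(1))
  diag(sig, length(sig))
}

#' Innovation of one data point
#'
#' Residual `y - H n`, innovation covariance `S = H P H' + Sigma`, and
#' the per-point marginal log-likelihood `log N(y | H n, S)`. If S is
#' not positive definite a jitter of `1e-10 * trace(S)` (escalated to
#' `1e-6`) is added and counted.
#'
#' @param state Prior [ensemble_state()].
#' @param obs An [observation_model()].
#' @param y Observation vector in the row order of `obs`.
#' @return List with `residual`, `S`, `loglik`, `n_jitter`.
#' @export
kf_innovation <- function(state, obs, y) {
  if (any(!is.finite(y))) stop("non-finite observation")
  H <- obs$H
  S <- H %*% state$P %*% t(H) + observation_covariance(state, obs)
  S <- 0.5 * (S + t(S))
  r <- as.numeric(y - H %*% state$n)
  njit <- 0
  jit <- 0
  tr <- max(sum(diag(S)), .Machine$double.eps)
  repeat {
    ch <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) break
    njit <- njit + 1
    jit <- if (jit == 0) 1e-10 * tr else jit * 1e2
    if (jit > 1e-4 * tr) stop("innovation covariance not positive definite")
  }
  z <- backsolve(ch, r, transpose = TRUE)
  ll <- -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                  sum(z^2))
  list(residual = r, S = S, loglik = ll, n_jitter = njit)
}

#' Correction (Bayesian update) of the ensemble state
#'
#' Minimum-variance gain `K = P H' S^-1`; mean and covariance updated as
#' `n + K (y - H n)` and `P - K S K'`. Mean components are not clamped
#' at zero (they are moments, not probabilities); the covariance is
#' re-symmetrized.
#'
#' @param state Prior [ensemble_state()].
#' @param obs An [observation_model()].
#' @param y Observation vector.
#' @param innov Optional precomputed [kf_innovation()].
#' @return Posterior `ensemble_state`.
#' @export
kf_correct <- function(state, obs, y, innov = NULL) {
  if (is.null(innov)) innov <- kf_innovation(state, obs, y)
  H <- obs$H
  K <- t(solve(innov$S, H %*% state$P))
  n <- state$n + as.numeric(K %*% innov$residual)
  P <- state$P - K %*% innov$S %*% t(K)
  ensemble_state(n, P)
}

# Split a trace_set into per-trace pieces with the arrays the compiled
# recursion needs: y matrix, per-sample transition index, transition
# matrices, and initial moments.
prepare_filter_input <- function(traces, scheme, rates, noise,
                                 observe, rows = c("flu", "curr")) {
  obs <- observation_model(scheme, noise, observe, rows)
  f_ana <- trace_meta(traces)$f_ana
  if (is.null(f_ana)) {
    dt <- diff(traces$time[traces$conc == traces$conc[1]])[1]
    f_ana <- 1 / dt
  }
  dt <- 1 / f_ana
  nch <- noise[["nch"]]
  groups <- split(traces, traces$conc)
  purrr::map(groups, function(d) {
    d <- d[order(d$time), ]
    ligs <- unique(d$ligand)
    Tlist <- lapply(ligs, function(L)
      transition_matrix(build_rate_matrix(scheme, rates, L), dt))
    seg <- match(d$ligand, ligs)
    ycols <- c(flu = "y_flu", curr = "y_curr")[obs$rows]
    y <- as.matrix(d[, ycols, drop = FALSE])
    K0 <- build_rate_matrix(scheme, rates, d$ligand[1])
    st0 <- init_state(K0, nch)
    list(y = y, seg = as.integer(seg), Tlist = Tlist,
         n0 = st0$n, P0 = st0$P, d = d)
  })
}

#' Log-likelihood of a trace set under the generalized Kalman filter
#'
#' For each concentration trace: initialize at the pre-jump equilibrium,
#' condition on the first sample, then alternate prediction and
#' correction along the analysis grid, accumulating the per-point
#' marginal normal log-likelihoods
#' `log N(y_t | H n_t, H P_t H' + Sigma_t)` from the second sample on.
#' Deterministic for fixed inputs.
#'
#' @param traces A `trace_set` tibble (columns `time`, `conc`,
#'   `ligand`, `y_curr`, optionally `y_flu`).
#' @param scheme A `kinetic_scheme`.
#' @param rates Named rate values.
#' @param noise A [noise_params()] vector (its `nch` is the channel
#'   count used by the filter).
#' @param observe `"cpcf"` or `"pc"`; default chosen from the columns
#'   present.
#' @param per_trace Return the per-trace breakdown as well.
#' @return Scalar log-likelihood, or a list with `total` and
#'   `per_trace` when `per_trace = TRUE`.
#' @export
kf_loglik <- function(traces, scheme, rates, noise,
                      observe = NULL, per_trace = FALSE) {
  if (is.null(observe))
    observe <- if ("y_flu" %in% names(traces)) "cpcf" else "pc"
  obs <- observation_model(scheme, noise, observe)
  inp <- prepare_filter_input(traces, scheme, rates, noise, observe)
  flu_row <- match("flu", obs$rows, nomatch = 0L)
  cur_row <- match("curr", obs$rows, nomatch = 0L)
  nz <- c(obs$noise[["sigma_m"]]^2, obs$noise[["sigma_op"]]^2,
          obs$noise[["sigma_back"]]^2)
  lls <- vapply(inp, function(tr) {
    kf_core(tr$y, tr$seg, tr$Tlist, obs$H, tr$n0, tr$P0, obs$wopen,
            flu_row, cur_row, nz)$loglik
  }, numeric(1))
  if (per_trace) list(total = sum(lls), per_trace = lls) else sum(lls)
}

#' Run the filter and return one-step-ahead predictions
#'
#' Like [kf_loglik()] but returns the per-point prediction means and
#' standard deviations (the ingredients of the normalized residuals)
#' in long format.
#'
#' @inheritParams kf_loglik
#' @return Tibble with columns `time`, `conc`, `obs` (observable name),
#'   `y`, `pred_mean`, `pred_sd` and `first` (TRUE for the
#'   initialization sample, which contributes no likelihood).
#' @export
kf_filter <- function(traces, scheme, rates, noise, observe = NULL) {
  if (is.null(observe))
    observe <- if ("y_flu" %in% names(traces)) "cpcf" else "pc"
  obs <- observation_model(scheme, noise, observe)
  inp <- prepare_filter_input(traces, scheme, rates, noise, observe)
  flu_row <- match("flu", obs$rows, nomatch = 0L)
  cur_row <- match("curr", obs$rows, nomatch = 0L)
  nz <- c(obs$noise[["sigma_m"]]^2, obs$noise[["sigma_op"]]^2,
          obs$noise[["sigma_back"]]^2)
  purrr::map_dfr(inp, function(tr) {
    res <- kf_core(tr$y, tr$seg, tr$Tlist, obs$H, tr$n0, tr$P0,
                   obs$wopen, flu_row, cur_row, nz, return_pred = TRUE)
    long <- purrr::map_dfr(seq_along(obs$rows), function(r) {
      tibble::tibble(time = tr$d$time, conc = tr$d$conc,
                     obs = obs$rows[r], y = tr$y[, r],
                     pred_mean = res$pred_mean[, r],
                     pred_sd = res$pred_sd[, r],
                     first = seq_len(nrow(tr$y)) == 1)
    })
    long
  })
}

#' Reference R implementation of the filter recursion
#'
#' Step-by-step filter written with [kf_predict()], [kf_innovation()]
#' and [kf_correct()]; numerically equivalent to the compiled
#' recursion used by [kf_loglik()] and kept as the readable
#' specification of the algorithm.
#'
#' @inheritParams kf_loglik
#' @return Scalar log-likelihood.
#' @export
kf_loglik_r <- function(traces, scheme, rates, noise, observe = NULL) {
  if (is.null(observe))
    observe <- if ("y_flu" %in% names(traces)) "cpcf" else "pc"
  obs <- observation_model(scheme, noise, observe)
  inp <- prepare_filter_input(traces, scheme, rates, noise, observe)
  total <- 0
  for (tr in inp) {
    st <- ensemble_state(tr$n0, tr$P0)
    for (t in seq_len(nrow(tr$y))) {
      if (t > 1) {
        st <- kf_predict(st, tr$Tlist[[tr$seg[t]]])
        inn <- kf_innovation(st, obs, tr$y[t, ])
        total <- total + inn$loglik
        st <- kf_correct(st, obs, tr$y[t, ], inn)
      } else {
        st <- kf_correct(st, obs, tr$y[t, ])
      }
    }
  }
  total
}
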