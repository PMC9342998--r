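#' Deterministic mean occupancy trajectory
#'
#' Propagates the ensemble mean from the pre-jump equilibrium with
#' `n(t+1) = T n(t)` (no data dependence): the rate-equation solution
#' on the analysis grid.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named rate values.
#' @param nch Channel count.
#' @param conc Jump concentration (uM).
#' @param t_on,t_off Segment durations (s).
#' @param f_ana Analysis frequency (Hz).
#' @param conc_rest Resting concentration (uM).
#' @return Tibble with `time`, `ligand` and one column per state.
#' @export
re_mean_trajectory <- function(scheme, rates, nch, conc, t_on = 1,
                               t_off = 1, f_ana = 250, conc_rest = 0) {
  dt <- 1 / f_ana
  times <- seq(0, t_on + t_off - dt, by = dt)
  ligand <- ifelse(times <= 0, conc_rest, ifelse(times <= t_on, conc,
                                                 conc_rest))
  K0 <- build_rate_matrix(scheme, rates, conc_rest)
  n <- nch * resting_distribution(K0)
  ligs <- unique(ligand)
  Tlist <- lapply(ligs, function(L)
    transition_matrix(build_rate_matrix(scheme, rates, L), dt))
  M <- n_states(scheme)
  out <- matrix(NA_real_, length(times), M)
  out[1, ] <- n
  for (t in seq_along(times)[-1]) {
    n <- as.numeric(Tlist[[match(ligand[t], ligs)]] %*% n)
    out[t, ] <- n
  }
  colnames(out) <- scheme$states
  dplyr::bind_cols(tibble::tibble(time = times, ligand = ligand),
                   tibble::as_tibble(out))
}

# deterministic mean trajectory along the ligand column of one trace
re_mean_for_trace <- function(d, scheme, rates, nch, f_ana) {
  dt <- 1 / f_ana
  ligs <- unique(d$ligand)
  Tlist <- lapply(ligs, function(L)
    transition_matrix(build_rate_matrix(scheme, rates, L), dt))
  K0 <- build_rate_matrix(scheme, rates, d$ligand[1])
  n <- nch * resting_distribution(K0)
  out <- matrix(NA_real_, nrow(d), length(n))
  out[1, ] <- n
  seg <- match(d$ligand, ligs)
  for (t in seq_len(nrow(d))[-1]) {
    n <- as.numeric(Tlist[[seg[t]]] %*% n)
    out[t, ] <- n
  }
  out
}

# per-point observation moments of the RE model: mean H n_t and
# covariance H C_t H' + Sigma(n_t) with the multinomial covariance
# C_t = diag(n_t) - n_t n_t' / Nch at the deterministic mean.
re_moments_for_trace <- function(d, scheme, rates, noise, obs, f_ana) {
  nch <- noise[["nch"]]
  nm <- re_mean_for_trace(d, scheme, rates, nch, f_ana)
  H <- obs$H
  nobs <- nrow(H)
  N <- nrow(d)
  mu <- nm %*% t(H)
  ns <- obs$noise
  # H C H' with C = diag(n) - n n'/Nch, vectorized over time:
  # (H C H')_rs = sum_i H_ri H_si n_i - (H_r n)(H_s n)/Nch
  Smat <- array(NA_real_, c(N, nobs, nobs))
  for (r in seq_len(nobs)) {
    for (s in seq_len(r)) {
      v <- nm %*% (H[r, ] * H[s, ]) - mu[, r] * mu[, s] / nch
      Smat[, r, s] <- v
      Smat[, s, r] <- v
    }
    Smat[, r, r] <- Smat[, r, r] + if (obs$rows[r] == "curr") {
      ns[["sigma_m"]]^2 +
        ns[["sigma_op"]]^2 * pmax(nm %*% obs$wopen, 0)
    } else {
      ns[["sigma_back"]]^2 + pmax(mu[, r], 0)
    }
  }
  list(mu = mu, S = Smat)
}

#' Rate-equation log-likelihood of a trace set
#'
#' The comparison baseline: the mean evolves deterministically from
#' equilibrium and every data point is treated as an independent draw
#' from a normal approximation to the multinomial at that mean,
#' `y_t ~ N(H n_t, H C_t H' + Sigma(n_t))` with
#' `C_t = diag(n_t) - n_t n_t'/Nch`, sharing the observation-noise law
#' of the Kalman filter but using no correction step. As with the
#' filter, the first sample of each trace is excluded from the product.
#'
#' @inheritParams kf_loglik
#' @return Scalar log-likelihood, or list with `total`/`per_trace`.
#' @export
re_loglik <- function(traces, scheme, rates, noise, observe = NULL,
                      per_trace = FALSE) {
  if (is.null(observe))
    observe <- if ("y_flu" %in% names(traces)) "cpcf" else "pc"
  obs <- observation_model(scheme, noise, observe)
  f_ana <- trace_meta(traces)$f_ana
  if (is.null(f_ana)) f_ana <- 1 / diff(traces$time[1:2])
  ycols <- c(flu = "y_flu", curr = "y_curr")[obs$rows]
  lls <- purrr::map_dbl(split(traces, traces$conc), function(d) {
    d <- d[order(d$time), ]
    y <- as.matrix(d[, ycols, drop = FALSE])
    mo <- re_moments_for_trace(d, scheme, rates, noise, obs, f_ana)
    keep <- seq_len(nrow(y))[-1]
    r <- y[keep, , drop = FALSE] - mo$mu[keep, , drop = FALSE]
    if (ncol(y) == 1) {
      s11 <- mo$S[keep, 1, 1]
      sum(-0.5 * (log(2 * pi) + log(s11) + r[, 1]^2 / s11))
    } else {
      # closed-form bivariate normal density, vectorized over time
      s11 <- mo$S[keep, 1, 1]
      s22 <- mo$S[keep, 2, 2]
      s12 <- mo$S[keep, 1, 2]
      det <- s11 * s22 - s12^2
      q <- (s22 * r[, 1]^2 - 2 * s12 * r[, 1] * r[, 2] +
              s11 * r[, 2]^2) / det
      sum(-0.5 * (2 * log(2 * pi) + log(det) + q))
    }
  })
  if (per_trace) list(total = sum(lls), per_trace = lls) else sum(lls)
}

#' One-step prediction table of the RE model
#'
#' Per-point deterministic means and dispersions in the same long
#' format as [kf_filter()], for residual diagnostics.
#'
#' @inheritParams kf_loglik
#' @return Tibble like [kf_filter()]'s.
#' @export
re_filter <- function(traces, scheme, rates, noise, observe = NULL) {
  if (is.null(observe))
    observe <- if ("y_flu" %in% names(traces)) "cpcf" else "pc"
  obs <- observation_model(scheme, noise, observe)
  f_ana <- trace_meta(traces)$f_ana
  if (is.null(f_ana)) f_ana <- 1 / diff(traces$time[1:2])
  ycols <- c(flu = "y_flu", curr = "y_curr")[obs$rows]
  purrr::map_dfr(split(traces, traces$conc), function(d) {
    d <- d[order(d$time), ]
    y <- as.matrix(d[, ycols, drop = FALSE])
    mo <- re_moments_for_trace(d, scheme, rates, noise, obs, f_ana)
    purrr::map_dfr(seq_along(obs$rows), function(r) {
      tibble::tibble(time = d$time, conc = d$conc, obs = obs$rows[r],
                     y = y[, r], pred_mean = mo$mu[, r],
                     pred_sd = sqrt(mo$S[, r, r]),
                     first = seq_len(nrow(d)) == 1)
    })
  })
}
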