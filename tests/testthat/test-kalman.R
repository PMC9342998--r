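test_that("equilibrium initial state has multinomial moments", {
  two <- two_state_scheme()
  K <- build_rate_matrix(two, c(k12 = 1, k21 = 1), 0)
  st <- init_state(K, 4)
  expect_equal(st$n, c(2, 2))
  expect_equal(unname(st$P), matrix(c(1, -1, -1, 1), 2))

  # a point-mass equilibrium has zero covariance
  K0 <- build_rate_matrix(scheme_ccco(), ccco_rates(), 0)
  st0 <- init_state(K0, 100)
  expect_equal(max(abs(st0$P)), 0)

  # trace identity: tr(P) = Nch (1 - sum p^2)
  set.seed(5)
  for (rep in 1:10) {
    p <- stats::runif(4); p <- p / sum(p)
    P <- 50 * (diag(p) - tcrossprod(p))
    expect_equal(sum(diag(P)), 50 * (1 - sum(p^2)))
  }
})

test_that("prediction propagates exact generalized-multinomial moments", {
  two <- two_state_scheme()
  K <- build_rate_matrix(two, c(k12 = 3, k21 = 7), 0)
  Tm <- transition_matrix(K, 0.01)
  st <- ensemble_state(c(30, 20), matrix(c(4, -2, -2, 4), 2))

  # identity transition: Q vanishes, state unchanged
  id <- kf_predict(st, diag(2))
  expect_equal(id$n, st$n)
  expect_equal(id$P, st$P)

  # one certain channel: one-step multinomial covariance
  st1 <- ensemble_state(c(1, 0), matrix(0, 2, 2))
  pr <- kf_predict(st1, Tm)
  expect_equal(pr$n, as.numeric(Tm %*% c(1, 0)))
  expect_equal(unname(pr$P), unname(diag(pr$n) - tcrossprod(pr$n)),
               tolerance = 1e-12)

  # mean channel count is preserved exactly
  pr2 <- kf_predict(st, Tm)
  expect_equal(sum(pr2$n), sum(st$n))
})

test_that("predicted moments match Monte-Carlo generalized-multinomial draws", {
  sch <- three_state_scheme()
  K <- build_rate_matrix(sch, c(k12 = 40, k21 = 30, k23 = 60, k32 = 50), 2)
  Tm <- transition_matrix(K, 0.004)
  n0 <- c(20, 50, 30)
  st <- ensemble_state(n0, matrix(0, 3, 3))
  pred <- kf_predict(st, Tm)
  set.seed(21)
  nrep <- 1e5
  draws <- matrix(0, 3, nrep)
  for (k in seq_len(nrep)) draws[, k] <- rgen_multinomial(n0, Tm)
  emp_mean <- rowMeans(draws)
  emp_cov <- stats::cov(t(draws))
  se_mean <- sqrt(diag(pred$P) / nrep)
  expect_true(all(abs(emp_mean - pred$n) <= 4 * se_mean))
  se_cov <- sqrt((outer(diag(pred$P), diag(pred$P)) + pred$P^2) / nrep)
  expect_true(all(abs(emp_cov - pred$P) <= 4 * se_cov))
})

test_that("process noise Q is PSD for non-negative means", {
  set.seed(22)
  for (rep in 1:200) {
    M <- sample(2:5, 1)
    Tm <- matrix(stats::runif(M * M), M)
    Tm <- sweep(Tm, 2, colSums(Tm), "/")
    n <- stats::runif(M, 0, 100)
    Q <- diag(as.numeric(Tm %*% n), M) -
      Tm %*% diag(n, M) %*% t(Tm)
    ev <- eigen(0.5 * (Q + t(Q)), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(sum(diag(Q)), 1))
  }
})

test_that("observation covariance follows the total-variance construction", {
  sch <- scheme_ccco()
  ns <- noise_params(nch = 10, i = 1, sigma_m = 1, sigma_op = sqrt(0.1),
                     lambda_b = 0.5, sigma_back = 2)
  obs <- observation_model(sch, ns)
  st <- ensemble_state(c(0, 2, 3, 10), diag(4))
  S <- observation_covariance(st, obs)
  # current entry: sigma_m^2 + sigma_op^2 * n_open = 1 + 0.1 * 10
  expect_equal(S[2, 2], 2.0)
  # fluorescence mean lambda_b (n2 + 2 n3 + 2 n4)
  expect_equal(sum(obs$H[1, ] * st$n), 0.5 * (2 + 2 * (3 + 10)))
  expect_equal(S[1, 1], 4 + 0.5 * (2 + 2 * (3 + 10)))
  # switching off state-dependent terms leaves the instrumental floor
  ns0 <- noise_params(nch = 10, i = 1, sigma_m = 1, sigma_op = 0,
                      lambda_b = 0, sigma_back = 2)
  S0 <- observation_covariance(st, observation_model(sch, ns0))
  expect_equal(unname(diag(S0)), c(4, 1))
})

test_that("innovation gives residual, covariance, and normal log-density", {
  two <- two_state_scheme()
  ns <- pc_noise(10, sigma_m = 2)
  obs <- observation_model(two, ns, "pc")
  st <- ensemble_state(c(5, 5), matrix(c(2, -1, -1, 2), 2))
  y <- sum(obs$H[1, ] * st$n)
  inn <- kf_innovation(st, obs, y)
  expect_equal(inn$residual, 0)
  expect_equal(inn$loglik, -0.5 * log(2 * pi * inn$S[1, 1]))
  # P = 0 reduces to the plain Gaussian with variance Sigma
  st0 <- ensemble_state(c(5, 5), matrix(0, 2, 2))
  inn0 <- kf_innovation(st0, obs, y + 1)
  expect_equal(inn0$S[1, 1], 4)
  expect_equal(inn0$loglik, stats::dnorm(1, 0, 2, log = TRUE))
  expect_error(kf_innovation(st, obs, NaN), "non-finite")
})

test_that("moment-matched marginal agrees with quadrature for state-dependent noise", {
  # scalar toy: y | n ~ N(n, sigma_m^2 + n sigma_op^2), n ~ N(nbar, P)
  nbar <- 20; P <- 9; sm2 <- 1; sop2 <- 0.5
  marg <- function(y) stats::integrate(function(n)
    stats::dnorm(y, n, sqrt(sm2 + pmax(n, 0) * sop2)) *
      stats::dnorm(n, nbar, sqrt(P)),
    nbar - 8 * sqrt(P), nbar + 8 * sqrt(P))$value
  ys <- seq(nbar - 15, nbar + 15, length.out = 61)
  dens <- vapply(ys, marg, numeric(1))
  dens <- dens / sum(dens)
  mu_q <- sum(ys * dens)
  var_q <- sum((ys - mu_q)^2 * dens)
  # moment-matched normal: mean nbar, variance P + sigma_m^2 + nbar sigma_op^2
  expect_equal(mu_q, nbar, tolerance = 1e-3)
  expect_equal(var_q, P + sm2 + nbar * sop2, tolerance = 0.02)
})

test_that("correction is the conjugate-normal update", {
  two <- two_state_scheme()
  # scalar toy: prior N(0, 1), H row (0, 1), Sigma = 1, y = 1
  ns <- pc_noise(1, i = 1, sigma_m = 1)
  obs <- observation_model(two, ns, "pc")
  st <- ensemble_state(c(1, 0), matrix(c(0, 0, 0, 1), 2))
  post <- kf_correct(st, obs, 1)
  expect_equal(post$n[2], 0.5)
  expect_equal(post$P[2, 2], 0.5)

  # overwhelming observation noise: posterior = prior
  nsbig <- pc_noise(10, sigma_m = 1e6)
  obsb <- observation_model(two, nsbig, "pc")
  stp <- ensemble_state(c(5, 5), matrix(c(2, -1, -1, 2), 2))
  postb <- kf_correct(stp, obsb, 50)
  expect_equal(postb$n, stp$n, tolerance = 1e-8)
  expect_equal(postb$P, stp$P, tolerance = 1e-6)

  # a zero observation row leaves the unobserved subspace unchanged
  sch3 <- three_state_scheme()
  ns3 <- pc_noise(10, sigma_m = 1)
  obs3 <- observation_model(sch3, ns3, "pc")  # H = (0, 0, i)
  st3 <- ensemble_state(c(4, 3, 3), diag(c(1, 1, 1)))
  post3 <- kf_correct(st3, obs3, 3)
  expect_equal(post3$n[1:2], st3$n[1:2])  # P diagonal: no cross info
})

test_that("compiled recursion equals the R reference filter", {
  sch <- scheme_ccco()
  ns <- noise_params(nch = 200)
  tr <- simulate_traces(sch, ccco_rates(), ns,
                        concentrations = c(0.5, 16), t_on = 0.3,
                        t_off = 0.3, f_sim = 2000, f_ana = 200,
                        seed = 31)
  ll_c <- kf_loglik(tr, sch, ccco_rates(), ns)
  ll_r <- kf_loglik_r(tr, sch, ccco_rates(), ns)
  expect_equal(ll_c, ll_r, tolerance = 1e-9)
})

test_that("trace log-likelihood is additive and order-invariant", {
  sch <- scheme_ccco()
  ns <- noise_params(nch = 100)
  tr <- simulate_traces(sch, ccco_rates(), ns,
                        concentrations = c(1, 8), t_on = 0.2,
                        t_off = 0.2, f_sim = 2000, f_ana = 200,
                        seed = 32)
  per <- kf_loglik(tr, sch, ccco_rates(), ns, per_trace = TRUE)
  expect_equal(per$total, sum(per$per_trace))
  expect_equal(kf_loglik(tr[tr$conc == 1, ], sch, ccco_rates(), ns) +
                 kf_loglik(tr[tr$conc == 8, ], sch, ccco_rates(), ns),
               per$total)

  # invariance to the ordering of observables in y
  obs_a <- observation_model(sch, ns, "cpcf", rows = c("flu", "curr"))
  obs_b <- observation_model(sch, ns, "cpcf", rows = c("curr", "flu"))
  inp <- patchkf:::prepare_filter_input(tr[tr$conc == 8, ], sch,
                                        ccco_rates(), ns, "cpcf")[[1]]
  nz <- c(ns[["sigma_m"]]^2, ns[["sigma_op"]]^2, ns[["sigma_back"]]^2)
  ya <- inp$y
  la <- kf_core(ya, inp$seg, inp$Tlist, obs_a$H, inp$n0, inp$P0,
                obs_a$wopen, 1, 2, nz)$loglik
  lb <- kf_core(ya[, 2:1], inp$seg, inp$Tlist, obs_b$H, inp$n0, inp$P0,
                obs_b$wopen, 2, 1, nz)$loglik
  expect_equal(la, lb, tolerance = 1e-10)
})

test_that("filter log-likelihood approaches the exact forward algorithm as Nch grows", {
  two <- two_state_scheme()
  rates <- c(k12 = 30, k21 = 60)
  # average the per-point |gap| over a few data sets: the normal
  # approximation error is small against the per-data-set noise
  gaps <- vapply(c(10, 50, 250), function(nch) {
    ns <- pc_noise(nch, sigma_m = 0.5)
    K <- build_rate_matrix(two, rates, 0)
    Tm <- transition_matrix(K, 1 / 250)
    p_eq <- equilibrium_distribution(K)
    mean(vapply(1:4, function(s) {
      tr <- two_state_traces(rates, ns, t_total = 2, f_ana = 250,
                             seed = 40 + nch + 1000 * s)
      ll_kf <- kf_loglik(tr, two, rates, ns)
      d <- tr[order(tr$time), ]
      ll_fw <- forward_loglik_2state(d$y_curr, Tm, nch, ns, p_eq)
      abs(ll_kf - ll_fw) / nrow(d)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))    # shrinks with Nch
  expect_lt(gaps[3], 0.002)           # small per-point gap at Nch = 250
})

test_that("normalized filter residuals are white with unit variance at truth", {
  sch <- scheme_ccco()
  ns <- noise_params(nch = 500)
  tr <- simulate_traces(sch, ccco_rates(), ns,
                        concentrations = c(0.5, 4, 64), t_on = 0.5,
                        t_off = 0.5, f_sim = 5000, f_ana = 250,
                        seed = 33)
  res <- normalized_residuals(tr, sch, ccco_rates(), ns, "kf")
  expect_equal(stats::var(res$r), 1, tolerance = 0.08)
  # pooled per-lag autocorrelation within the 3/sqrt(N) white-noise band
  a <- residual_acf(res, 8)
  pooled <- stats::aggregate(acf ~ lag + obs, data = a, FUN = mean)
  ntot <- nrow(res) / 2
  expect_true(all(abs(pooled$acf) < 3 / sqrt(ntot)))
})
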