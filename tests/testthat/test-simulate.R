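test_that("gillespie conserves channels and freezes when rates vanish", {
  two <- two_state_scheme()
  prot <- jump_protocol(1, t_on = 0.1, t_off = 0.1, f_sim = 1000)
  occ <- gillespie_ensemble(two, c(k12 = 0, k21 = 0), prot, nch = 50,
                           seed = 1)
  expect_true(all(colSums(occ$counts) == 50))
  expect_true(all(occ$counts == occ$counts[, 1]))

  occ2 <- gillespie_ensemble(two, c(k12 = 100, k21 = 100), prot,
                            nch = 200, seed = 2)
  expect_true(all(colSums(occ2$counts) == 200))
})

test_that("seeded gillespie runs are bit-reproducible", {
  sch <- scheme_ccco()
  prot <- jump_protocol(4, t_on = 0.05, t_off = 0.05, f_sim = 2000)
  a <- gillespie_ensemble(sch, ccco_rates(), prot, 100, seed = 9)
  b <- gillespie_ensemble(sch, ccco_rates(), prot, 100, seed = 9)
  expect_identical(a$counts, b$counts)
})

test_that("two-state time-averaged occupancy matches equilibrium", {
  two <- two_state_scheme()
  prot <- jump_protocol(1, t_on = 2.5, t_off = 2.5, f_sim = 1000)
  occ <- gillespie_ensemble(two, c(k12 = 50, k21 = 50), prot,
                           nch = 1000, seed = 3)
  po <- mean(occ$counts[2, ] / 1000)
  # time-averaged open fraction: ~500 effectively independent
  # snapshots (10 ms relaxation time over 5 s), each with
  # SD sqrt(0.25/1000); 3 SE ~ 2e-3, tested with slack
  se <- sqrt(0.25 / 1000) / sqrt(500)
  expect_lt(abs(po - 0.5), 4 * se)
})

test_that("ensemble mean follows the matrix-exponential propagation", {
  sch <- scheme_ccco()
  nrep <- 60
  nch <- 200
  prot <- jump_protocol(16, t_on = 0.08, t_off = 0, f_sim = 500)
  prot$segments <- prot$segments[1, ]
  runs <- lapply(seq_len(nrep), function(k)
    gillespie_ensemble(sch, ccco_rates(), prot, nch, seed = 100 + k))
  counts <- simplify2array(lapply(runs, function(o) o$counts))
  emp_mean <- apply(counts, 1:2, mean)
  # oracle: n(t) = Nch expm(K t) e1
  K <- build_rate_matrix(sch, ccco_rates(), 16)
  times <- runs[[1]]$times
  for (j in seq(2, length(times), by = 8)) {
    mu <- nch * as.numeric(Matrix::expm(K * times[j]) %*% c(1, 0, 0, 0))
    se <- sqrt(pmax(mu * (1 - mu / nch), 1e-9) / nrep)
    expect_true(all(abs(emp_mean[, j] - mu) <= 4 * se + 1e-6))
  }
})

test_that("gillespie second moments match the moment propagation", {
  sch <- three_state_scheme()
  rates <- c(k12 = 40, k21 = 30, k23 = 60, k32 = 50)
  nch <- 50
  nrep <- 500
  prot <- jump_protocol(2, t_on = 0.05, t_off = 0, f_sim = 200)
  prot$segments <- prot$segments[1, ]
  runs <- lapply(seq_len(nrep), function(k)
    gillespie_ensemble(sch, rates, prot, nch, seed = 2000 + k))
  counts <- simplify2array(lapply(runs, function(o) o$counts))
  K <- build_rate_matrix(sch, rates, 2)
  Tm <- transition_matrix(K, 1 / 200)
  st <- init_state(K0 <- build_rate_matrix(sch, rates, 0), nch)
  # propagate under the concentration of the segment from equilibrium at 0
  for (j in 2:10) {
    st <- kf_predict(st, Tm)
    emp <- counts[, j, ]
    emp_mean <- rowMeans(emp)
    emp_cov <- stats::cov(t(emp))
    se_mean <- sqrt(diag(st$P) / nrep)
    expect_true(all(abs(emp_mean - st$n) <= 4 * se_mean + 1e-8))
    # covariance entries: SE approx sqrt((P_ii P_jj + P_ij^2)/nrep)
    se_cov <- sqrt((outer(diag(st$P), diag(st$P)) + st$P^2) / nrep)
    expect_true(all(abs(emp_cov - st$P) <= 4 * se_cov + 1e-8))
  }
})

test_that("current observation has the stated mean and variance structure", {
  two <- two_state_scheme()
  occ <- structure(list(counts = rbind(rep(0, 5000), rep(10, 5000))),
                   class = "occupancy_series")
  # noiseless: exactly i * n_open
  ns0 <- noise_params(nch = 10, i = 2, sigma_m = 0, sigma_op = 0,
                      lambda_b = 0, sigma_back = 0)
  expect_equal(observe_current(occ, c(0, 1), ns0, seed = 1),
               rep(20, 5000))
  # closed ensemble: sample variance -> sigma_m^2
  occ0 <- structure(list(counts = rbind(rep(50, 2e4), rep(0, 2e4))),
                    class = "occupancy_series")
  ns1 <- noise_params(nch = 50, i = 1, sigma_m = 1.5, sigma_op = 3,
                      lambda_b = 0, sigma_back = 0)
  y0 <- observe_current(occ0, c(0, 1), ns1, seed = 2)
  expect_equal(stats::var(y0), 1.5^2, tolerance = 0.1)
  # open channels add sigma_op^2 * n_open of excess variance
  yo <- observe_current(occ, c(0, 1), noise_params(
    nch = 10, i = 1, sigma_m = 1, sigma_op = sqrt(0.1) * 1,
    lambda_b = 0, sigma_back = 0), seed = 3)
  expect_equal(stats::var(yo), 1 + 0.1 * 10, tolerance = 0.15)
})

test_that("fluorescence observation is Poisson in the bound-ligand count", {
  occ <- structure(list(counts = rbind(rep(0, 2e4), rep(1000, 2e4))),
                   class = "occupancy_series")
  ns <- noise_params(nch = 1000, lambda_b = 0.375, sigma_back = 0)
  # all channels doubly bound: mean 2 * lambda_b * Nch = 750
  y <- observe_fluorescence(occ, c(0, 2), ns, seed = 4)
  expect_equal(mean(y), 750, tolerance = 0.01)
  expect_equal(stats::var(y), 750, tolerance = 0.05)
  # zero brightness and background: identically zero
  ns0 <- noise_params(nch = 1000, lambda_b = 0, sigma_back = 0)
  expect_equal(observe_fluorescence(occ, c(0, 2), ns0, seed = 5),
               rep(0, 2e4))
})

test_that("bessel filter has unit DC gain and induces autocorrelation", {
  x <- rep(3.7, 500)
  y <- bessel_filter(x, f_cut = 500, f_sample = 1e4)
  expect_equal(tail(y, 100), rep(3.7, 100), tolerance = 1e-6)

  set.seed(11)
  w <- stats::rnorm(2e4)
  yf <- bessel_filter(w, f_cut = 1000, f_sample = 1e4)  # f_cut < f_sim/4
  ac1 <- stats::acf(yf[1000:2e4], lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(ac1, 0.2)
  expect_error(bessel_filter(w, 6000, 1e4), "Nyquist")
})

test_that("integration window sums frames and preserves Poisson law", {
  expect_equal(integrate_window(rep(2, 12), t_int = 3 / 10, f_sample = 10),
               rep(6, 4))
  x <- stats::runif(7)
  expect_equal(integrate_window(x, 1 / 10, 10), x)
  expect_error(integrate_window(1:3, 2, 2), "longer than trace")

  set.seed(12)
  y <- stats::rpois(3e4, 0.5)
  s <- integrate_window(y, 10 / 100, 100)  # windows of 10: rate 5
  expect_equal(mean(s), 5, tolerance = 0.05)
  expect_equal(stats::var(s), 5, tolerance = 0.1)
})

test_that("decimation subsamples and keeps white noise white", {
  expect_equal(decimate_trace(1:10, 100, 100), 1:10)
  expect_equal(decimate_trace(1:10, 1000, 200), c(1, 6))
  expect_error(decimate_trace(1:10, 1000, 300), "integer multiple")
  set.seed(13)
  w <- stats::rnorm(5e4)
  d <- decimate_trace(w, 1e4, 2e3)
  a <- stats::acf(d, lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(a) < 3 / sqrt(length(d))))
})

test_that("simulated trace sets carry consistent layout and metadata", {
  sch <- scheme_ccco()
  tr <- simulate_traces(sch, ccco_rates(), noise_params(nch = 100),
                        concentrations = c(1, 64), t_on = 0.2,
                        t_off = 0.2, f_sim = 2000, f_ana = 200,
                        seed = 14)
  expect_s3_class(tr, "trace_set")
  expect_equal(sort(unique(tr$conc)), c(1, 64))
  d <- tr[tr$conc == 1, ]
  expect_equal(nrow(d), 80)
  expect_true(all(diff(d$time) > 0))
  expect_equal(unique(round(diff(d$time), 10)), 1 / 200)
  expect_equal(d$ligand[1], 0)           # resting pre-jump sample
  expect_equal(trace_meta(tr)$f_ana, 200)
  # identical seed, identical data
  tr2 <- simulate_traces(sch, ccco_rates(), noise_params(nch = 100),
                         concentrations = c(1, 64), t_on = 0.2,
                         t_off = 0.2, f_sim = 2000, f_ana = 200,
                         seed = 14)
  expect_identical(tr$y_curr, tr2$y_curr)
  expect_identical(tr$y_flu, tr2$y_flu)
})
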