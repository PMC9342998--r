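# Shared fixtures and independent oracles used across the suite.

two_state_scheme <- function() {
  kinetic_scheme(
    states = c("C1", "O2"),
    edges = tibble::tribble(
      ~from, ~to, ~param, ~ligand,
      "C1", "O2", "k12", 0,
      "O2", "C1", "k21", 0),
    conducting = c(0, 1),
    bound_ligands = c(0, 0),
    name = "two-state")
}

three_state_scheme <- function() {
  kinetic_scheme(
    states = c("C1", "C2", "O3"),
    edges = tibble::tribble(
      ~from, ~to, ~param, ~ligand,
      "C1", "C2", "k12", 1,
      "C2", "C1", "k21", 0,
      "C2", "O3", "k23", 0,
      "O3", "C2", "k32", 0),
    conducting = c(0, 0, 1),
    bound_ligands = c(0, 1, 1),
    name = "three-state")
}

pc_noise <- function(nch, i = 1, sigma_m = 1, sigma_op = 0) {
  noise_params(nch = nch, i = i, sigma_m = sigma_m, sigma_op = sigma_op,
               lambda_b = 0, sigma_back = 0)
}

# One draw from the generalized multinomial: each initial
# subpopulation spreads independently by column Tm[, a].
rgen_multinomial <- function(n, Tm) {
  out <- numeric(length(n))
  for (a in seq_along(n)) {
    if (n[a] > 0)
      out <- out + as.numeric(stats::rmultinom(1, n[a], Tm[, a]))
  }
  out
}

# Exact discrete forward-algorithm log-likelihood for a two-state
# ensemble observed through the current channel, mirroring the filter's
# contract (equilibrium initial distribution, first sample conditions
# only).  State = number of open channels, transition = convolution of
# two binomials, emission = N(i * n_open, sigma_m^2 + sigma_op^2 n_open).
forward_loglik_2state <- function(y, Tm, nch, noise, p_eq) {
  stopifnot(nrow(Tm) == 2)
  n_open <- 0:nch
  i <- noise[["i"]]
  v <- noise[["sigma_m"]]^2 + noise[["sigma_op"]]^2 * n_open
  emis <- function(yt) stats::dnorm(yt, i * n_open, sqrt(v))
  # A[n', n]: P(next open count = n' | current = n)
  A <- matrix(0, nch + 1, nch + 1)
  for (n in 0:nch) {
    from_open <- stats::dbinom(0:n, n, Tm[2, 2])
    from_closed <- stats::dbinom(0:(nch - n), nch - n, Tm[2, 1])
    A[, n + 1] <- convolve(from_open, rev(from_closed),
                           type = "open")[1:(nch + 1)]
  }
  alpha <- stats::dbinom(n_open, nch, p_eq[2]) * emis(y[1])
  alpha <- alpha / sum(alpha)         # condition on y1, no likelihood
  ll <- 0
  for (t in seq_along(y)[-1]) {
    alpha <- (A %*% alpha)[, 1] * emis(y[t])
    s <- sum(alpha)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}

# stationary two-state PC trace set on a uniform grid (no binding, so
# the jump concentration is inert)
two_state_traces <- function(rates, noise, t_total = 4, f_ana = 500,
                             seed = 1) {
  two <- two_state_scheme()
  simulate_traces(two, rates, noise, concentrations = 1,
                  t_on = t_total / 2, t_off = t_total / 2,
                  f_sim = f_ana * 2, f_ana = f_ana, observe = "pc",
                  seed = seed)
}
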