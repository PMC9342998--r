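#' Scaled-down filter-versus-baseline error benchmark
#'
#' For each channel count: simulate a data set, sample short posterior
#' chains (relative to a production analysis) for both the generalized
#' Kalman filter and the rate-equation baseline, summarize each
#' posterior by its marginal medians, and score the Euclidean error
#' over the rates and equilibrium constants. The `a / sqrt(Nch)` law
#' is then fitted per method and the benchmark statistic is the error
#' ratio `a_RE / a_KF`. Full-scale versions of this comparison require
#' cluster-scale sampling; this helper deliberately runs a reduced
#' grid and by default starts chains at the true parameters so that
#' the short warmup adapts locally instead of hunting for the mode --
#' each chain still drifts to wherever its own posterior concentrates,
#' which is exactly the bias the benchmark measures.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates True rates (the sampled parameters).
#' @param noise A [noise_params()] vector; its `nch` is overridden by
#'   `nch_values`.
#' @param nch_values Channel counts of the grid (>= 3 for the scaling
#'   fit).
#' @param concentrations Ligand concentrations to simulate.
#' @param observe `"cpcf"` or `"pc"`.
#' @param t_on,t_off,f_sim,f_ana Simulation / analysis settings.
#' @param iter,warmup Chain lengths per fit.
#' @param prior_span Uniform prior span: each rate's sampling box is
#'   `true / prior_span` to `true * prior_span`.
#' @param init `"truth"` (default) or `"prior"` chain initialization.
#' @param seed Integer seed.
#' @return List with `errors` (tibble: nch, method, error), `a_kf`,
#'   `a_re` (scaling coefficients) and `error_ratio`.
#' @export
error_ratio_benchmark <- function(scheme, rates, noise = noise_params(),
                                  nch_values = c(500, 2000, 8000),
                                  concentrations = c(0.5, 4, 64),
                                  observe = "cpcf", t_on = 0.5,
                                  t_off = 0.5, f_sim = 2000,
                                  f_ana = 200, iter = 500,
                                  warmup = 700, prior_span = 10,
                                  init = "truth", seed = 1) {
  stopifnot(length(nch_values) >= 3)
  rates <- unlist(rates)
  priors <- lapply(rates, function(v)
    prior_uniform(v / prior_span, v * prior_span))
  truth <- c(rates, rate_ratios(scheme, rates))
  rows <- purrr::map_dfr(seq_along(nch_values), function(k) {
    nch <- nch_values[k]
    ns <- noise
    ns[["nch"]] <- nch
    tr <- simulate_traces(scheme, rates, ns,
                          concentrations = concentrations,
                          t_on = t_on, t_off = t_off, f_sim = f_sim,
                          f_ana = f_ana, observe = observe,
                          seed = seed + k)
    purrr::map_dfr(c("kf", "re"), function(m) {
      fit <- sample_posterior(tr, scheme, priors, rates, ns,
                              method = m, chains = 1, iter = iter,
                              warmup = warmup, seed = seed + 100 * k,
                              init = if (identical(init, "truth"))
                                rates else init)
      s <- tidy(fit)
      med <- stats::setNames(s$median, s$term)
      est <- c(med, rate_ratios(scheme, med))
      tibble::tibble(nch = nch, method = m,
                     error = euclidean_error(est, truth))
    })
  })
  ek <- rows[rows$method == "kf", ]
  er <- rows[rows$method == "re", ]
  a_kf <- fit_error_scaling(ek$error, ek$nch)$a
  a_re <- fit_error_scaling(er$error, er$nch)$a
  list(errors = rows, a_kf = a_kf, a_re = a_re,
       error_ratio = a_re / a_kf)
}
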