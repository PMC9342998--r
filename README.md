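# patchkf

Bayesian inference of ion-channel kinetic schemes from macroscopic
patch-clamp (PC) and confocal patch-clamp fluorometry (cPCF)
recordings, built around a **generalized Kalman filter with
state-dependent observation noise**.

## The problem and who this is for

Electrophysiologists model ligand-gated channel gating as a
continuous-time Markov chain over a few conformational/binding states
with rate matrix *K* (binding rates scale with the ligand
concentration *L*). Macroscopic recordings observe an ensemble of
*N*<sub>ch</sub> channels through one or two noisy linear projections
— current through open channels, photons from bound ligands. The
classical analysis fits deterministic rate-equation (RE) relaxations
and throws away the information in the stochastic gating fluctuations,
which also makes its uncertainties overconfident: the data points are
treated as independent although the underlying ensemble state carries
first-order Markov memory.

`patchkf` treats the channel-count vector *n(t)* as the hidden state
of a Kalman filter whose moments are exact for ensembles of
independent Markov channels:

- prediction: n̄′ = *T* n̄, *P*′ = *Q*(*T*, n̄) + *T P T*ᵀ with
  *T* = exp(*K*Δt) and the generalized-multinomial process noise
  *Q*(*T*, n̄) = diag(*T* n̄) − *T* diag(n̄) *T*ᵀ;
- observation: y = *H* n + ν with **state-dependent** noise variance —
  σ²<sub>m</sub> + σ²<sub>op</sub>·n<sub>open</sub> for the current
  (open-channel noise), σ²<sub>back</sub> + (*H* n̄)<sub>flu</sub> for
  photon counts (Poisson, normal-approximated);
- per-point marginal likelihood N(y | *H* n̄, *H P H*ᵀ + Σ) and
  minimum-variance correction with gain *P H*ᵀ *S*⁻¹.

Around the filter the package provides the full study tool-chain: an
exact Gillespie ensemble simulator with the complete measurement-noise
stack (Bessel filtering, finite frame integration), the RE baseline
likelihood for comparison, adaptive-MCMC posterior sampling with a
hierarchical microscopic-reversibility prior for cyclic schemes, and
the uncertainty diagnostics (normalized residuals and their
autocorrelation, highest-density credible intervals/volumes, binomial
coverage calibration, error-scaling fits).

## Worked example

Simulate cPCF data for the four-state CCCO scheme (two binding steps,
one opening step) at three ligand concentrations, evaluate the filter
likelihood, check the residuals, and sample a posterior over the first
binding step:

```r
library(patchkf)

sch <- scheme_ccco()
ns  <- noise_params(nch = 1000)           # i = 1, sigma_m = 1, sigma_op^2 = 0.1, lambda_b = 0.375
tr  <- simulate_traces(sch, ccco_rates(), ns,
                       concentrations = c(0.5, 4, 64),
                       t_on = 0.5, t_off = 0.5,
                       f_sim = 5000, f_ana = 250, seed = 1)

kf_loglik(tr, sch, ccco_rates(), ns, per_trace = TRUE)
#> $total
#> [1] -4659.129
#> $per_trace
#>       0.5         4        64
#> -1265.502 -1635.278 -1758.350

var(normalized_residuals(tr, sch, ccco_rates(), ns, "kf")$r)
#> [1] 1.038342

pri <- list(kon1 = prior_uniform(2, 200), koff1 = prior_uniform(4, 400))
fit <- sample_posterior(tr, sch, pri, ccco_rates(), ns,
                        chains = 2, iter = 300, warmup = 500, seed = 2)
tidy(fit)
#> # A tibble: 2 × 6
#>   term  median  mean    sd hdci_lo hdci_hi
#> 1 kon1    20.3  20.3 0.707    19.1    21.7
#> 2 koff1   39.9  40.0 1.24     37.1    42.1
```

Reading the numbers: the per-trace log-likelihoods are the summed
per-point marginal normal densities of the filter (the first sample of
each trace only conditions the state). The residual variance near 1
says the filter's predictive dispersions match the data at the true
parameters — the model whitens the signal. The posterior medians
recover the true binding rates (`kon1 = 20` µM⁻¹s⁻¹, `koff1 = 40`
s⁻¹) within a few percent, with 0.95 highest-density intervals
covering the truth.

`autoplot(tr)` plots the traces, `autoplot(fit, true = ccco_rates())`
the marginal posteriors, `plot_residual_acf()` the residual
autocorrelation with white-noise bands. `re_loglik()` /
`normalized_residuals(..., method = "re")` run the RE baseline on the
same data; its residuals show the long-lived autocorrelation the
filter removes. A thin command-line wrapper with `simulate`, `loglik`,
`fit`, `diagnose` and `run` subcommands lives in
`inst/scripts/patchkf`.

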