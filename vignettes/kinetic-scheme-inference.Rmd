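---
title: "Inferring ion-channel kinetic schemes from ensemble recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ion-channel kinetic schemes from ensemble recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(patchkf)
library(dplyr)
```

## The inference problem

A patch of membrane holds an ensemble of `Nch` identical, non-interacting
ligand-gated channels. Each channel moves between a handful of
conformational and binding states following a continuous-time Markov
chain with rate matrix $K$ (column generator: $K_{ij}$ is the rate from
state $j$ to $i$, binding steps scale linearly with the ligand
concentration $L$). The experiment records one or two macroscopic
signals: the summed current through open channels and, in confocal
patch-clamp fluorometry (cPCF), the photon count from bound labelled
ligands. The goal is the rate matrix — absolute rates and equilibrium
constants — with honest uncertainties.

The hidden quantity is the occupancy vector $n(t)$, the channel counts
per state. Conditional on $n(t)$, one sampling step later $n(t+1)$ is a
sum of independent multinomials (one per source state), the
"generalized multinomial" law, whose exact first two moments are

$$\bar n(t+1) = T\,\bar n(t), \qquad
P(t+1) = \underbrace{\mathrm{diag}(T\bar n) - T\,\mathrm{diag}(\bar n)\,T^\top}_{Q(T,\bar n)} + T P T^\top,$$

with $T = \exp(K\Delta t)$ the single-channel transition matrix. The
filter propagates exactly these moments, so its process model is exact
to second order — equivalent to a time-integrated linear-noise
approximation of the chemical master equation.

## The generalized Kalman filter

The observation model is linear, $y_t = H n_t + \nu_t$, with an
observation matrix whose current row is $i \times$ (conducting map) and
whose fluorescence row is $\lambda_b \times$ (bound-ligand map). The
noise covariance $\Sigma_t$ is *state dependent*:

* current: $\sigma_m^2 + \sigma_{op}^2\,\max(\bar n_{open}, 0)$ —
  instrumental noise plus open-channel excess noise;
* fluorescence: $\sigma_{back}^2 + \max((H\bar n)_{flu}, 0)$ — the
  Poisson photon-count variance in its normal approximation plus
  background.

State-dependent noise breaks the conjugacy that gives the textbook
filter its closed form; matching the first two moments of the exact
one-point marginal (total-variance decomposition) restores a normal
recursion that is exact to second order. Each step evaluates
$\Sigma_t$ once, at the prior mean. The per-point marginal likelihood
is $\mathcal N(y_t \mid H\bar n_t,\; H P_t H^\top + \Sigma_t)$; the
correction uses the minimum-variance gain
$K = P H^\top (H P H^\top + \Sigma)^{-1}$. A trace is initialized at
the multinomial equilibrium moments of the pre-jump concentration, the
first sample only conditions the state (no likelihood term), and the
product runs over the remaining samples.

Two numerical safeguards, both logged: the innovation covariance gets
an escalating relative jitter ($10^{-10}\to10^{-6}$ of its trace) if a
Cholesky fails, and the state covariance is projected back onto the
PSD cone by eigenvalue clipping when its smallest eigenvalue falls
below $-10^{-8}\,\mathrm{tr}\,P$. The latter matters because posterior
mean occupancies may legitimately go slightly negative at low
occupancy — they are moments, not probabilities, and are deliberately
not clamped — which makes $Q$ indefinite in that regime. The
occupancy-dependent *noise* terms do floor at zero.

The recursion is implemented twice: a readable R version
(`kf_predict()`, `kf_innovation()`, `kf_correct()`, `kf_loglik_r()`)
that serves as the specification, and a compiled version behind
`kf_loglik()`/`kf_filter()` used in sampling; the test suite asserts
they agree to near machine precision.

## The rate-equation baseline

`re_loglik()` keeps the same observation model but propagates only the
deterministic mean from equilibrium and treats every data point as an
independent draw with multinomial covariance
$C_t = \mathrm{diag}(\bar n_t) - \bar n_t\bar n_t^\top/N_{ch}$ at that
mean — no correction step, no use of the fluctuations' memory. The
variance form is a reconstruction from the published description of
the approach (the original appendix is not available); any deviation
from the historical implementation shifts baseline numbers, which is
why benchmark comparisons against it are tolerance-banded. On a
single contributing data point the two likelihoods coincide exactly,
which the tests exploit as a contract check.

## What the simulator emulates

`simulate_traces()` generates the study conditions end to end:

* exact Doob–Gillespie trajectories of the summed count vector
  (propensities $n_j k_{ij}$, so cost scales with events, not
  channels), sampled on the `f_sim` grid; concentration jumps are
  ideal steps;
* per-sample current noise $\mathcal N(0, \sigma_m^2 + n_{open}\sigma_{op}^2)$;
* per-frame photon counts $\mathrm{Pois}(\lambda_b \sum_\alpha
  b_\alpha n_\alpha)$ plus Gaussian background;
* optionally a single-pass digital fourth-order Bessel low-pass on the
  current (group delay uncompensated, emulating the analog
  anti-aliasing filter), and finite frame integration by window
  summation with the $\lambda_b/T_{int}$ brightness convention.

The canonical model is the four-state CCCO scheme (two sequential
binding steps, one opening step, only the fully liganded state
conducts) with the shipped rates `ccco_rates()`: dissociation
constants 2 and 10 µM and an open/closed equilibrium of 3, placing the
activation midpoint inside the standard 0.0625–64 µM concentration
ladder. These are the package's own documented defaults of the
conventional orders of magnitude; the benchmark figures they mimic
publish their exact rates only graphically, so no claim is made to
reproduce figure-specific values. Default conditions: $N_{ch} = 10^3$,
$i = 1$, $\sigma_m = i$, $\sigma_{op}^2 = 0.1\,i^2$,
$\lambda_b = 0.375$, 10 kHz simulation, 250 Hz analysis for cPCF.

What the generator does **not** emulate: solution-exchange kinetics,
series-resistance/capacitance artifacts, drift, photobleaching, and
the detailed bulk-subtraction noise of the instrument — the background
term is a zero-mean Gaussian stand-in for the instrument's
difference-of-Poissons (Skellam-type) noise, defensible at the photon
rates used here. Passing tests therefore validate the algorithmic
chain under its own assumptions, not instrument-specific behaviour on
real recordings.

```{r traces}
sch <- scheme_ccco()
ns <- noise_params(nch = 1000)
tr <- simulate_traces(sch, ccco_rates(), ns,
                      concentrations = c(0.5, 4, 64),
                      t_on = 0.5, t_off = 0.5,
                      f_sim = 5000, f_ana = 250, seed = 1)
autoplot(tr)
```

## Residual diagnostics

At the true parameters the filter's normalized one-step-ahead
residuals $r_t = (y_t - H\bar n_t)/\mathrm{sd}_{pred}(t)$ are a
unit-variance white-noise process; the baseline's are not, because its
predictions ignore the fluctuations' first-order Markov memory. The
divisor is the predicted standard deviation (the notation some sources
use writes the variance under the bar; unit-variance residuals pin
down the SD reading).

```{r residuals}
rk <- normalized_residuals(tr, sch, ccco_rates(), ns, "kf")
rr <- normalized_residuals(tr, sch, ccco_rates(), ns, "re")
c(kf_var = var(rk$r), re_var = var(rr$r))
plot_residual_acf(rk %>% filter(conc == 4), max_lag = 10)
plot_residual_acf(rr %>% filter(conc == 4), max_lag = 10)
```

## Posterior sampling

`sample_posterior()` wraps a pluggable backend; the built-in default
is an adaptive random-walk Metropolis kernel: parameters map to an
unconstrained scale (log for positive supports, logit for boxes, with
Jacobians so the declared prior applies on the natural scale), the
proposal covariance and step size adapt during warmup (Robbins–Monro
toward 0.234 acceptance) and freeze afterwards. Gradient-based
samplers plug in through the `backend` argument; the built-in kernel
keeps the package dependency-free and is adequate at the problem sizes
used here. Two design choices deserve a note:

* **Priors.** The default for rates is uniform on the natural scale
  inside a sampling box — deliberately matching the plain-uniform
  convention of the comparison literature even though it biases scale
  parameters toward faster rates; normal and gamma priors are
  available where noise parameters are well characterized. Draws
  piling against a box bound (`improper_flags()`: ≥1 % of draws within
  0.1 % of a bound) are the operational signature of an improper
  posterior, i.e. unidentified parameters.
* **Stuck chains.** With multiple chains, a chain whose best log
  posterior trails the best chain by more than `chain_drop_tol` (50 by
  default) is dropped and counted. Aliased sampling of fast kinetics
  creates a genuine secondary mode at implausibly fast rates; multi-
  start sampling plus this rule is the standard remedy, and the
  dropped count is reported rather than hidden.

Microscopic reversibility for cyclic schemes is a hierarchical prior,
not a hard constraint: a Beta(100.01, 100.01) draw $k^\star$ completes
the loop's target rate as $R\,(0.995 + 0.01 k^\star)$, where $R$ is
the value that balances the directed rate products, so every draw
keeps the loop imbalance within ±0.5 %. (One source line prints the
hyperparameters as 100/100 elsewhere; the constructor takes them as
arguments.) The affine form is the only reading of the published
transform that actually yields the stated band, and it is a bijection
between $(free\ rates, k^\star)$ and completed rate sets.

## Uncertainty quantification

`hdci()` returns shortest (highest-density) intervals by the sorted-
window method. For joint statements over all rate-matrix parameters
the package counts the *probability mass needed to cover the truth*
two ways: ranking n-dimensional histogram bins by density
(`mass_to_cover_histogram()`, default $\lceil S^{1/(d+2)}\rceil$ bins
per axis — no published binning rule exists, so the default is an
explicit, configurable choice) and the $\chi^2$ CDF of the Mahalanobis
distance under a normal approximation
(`mass_to_cover_mahalanobis()`). For normal posteriors the two agree
up to binning error, which is O(bin width) and biased upward for the
histogram rank — the tests bracket rather than pin the closed form.
Coverage over repeated data sets is calibrated with the conjugate
Beta(1,1) binomial update (`coverage_calibration()`); six simultaneous
0.95 intervals have joint coverage between $0.95^6 \approx 0.735$ and
$0.95$.

Accuracy is summarized by the Euclidean error
$\sum_i (\theta_i/\theta_{i,true} - 1)^2$ over rates and equilibrium
constants — as printed in the source literature, a sum of squares
without the square root, kept that way so error ratios remain
comparable; the point estimate is the vector of marginal posterior
medians.

## Benchmark scaling and problem sizes

`error_ratio_benchmark()` fits the $a/\sqrt{N_{ch}}$ error law per
method and reports $a_{RE}/a_{KF}$. The published version of this
comparison ran on a compute cluster with long HMC chains over large
$N_{ch}$ grids; the package runs a deliberately reduced design chosen
once and documented here:

* PC: $\sigma_m = 1$, $\sigma_{op} = 0.01$, concentrations
  {0.25, 4, 64} µM, 1 kHz analysis, $N_{ch} \in \{2000, 8000, 32000\}$
  (pure-current posteriors are improper below about $2\times10^3$
  channels);
* cPCF: $\sigma_m = 0.5$, $\sigma_{op} = 0.05$, $\lambda_b = 5$,
  concentrations {0.0625, 1, 16} µM, 250 Hz analysis,
  $N_{ch} \in \{500, 2000, 8000\}$;
* one data set per $N_{ch}$, single chains of 700 warmup + 500 draws,
  initialized at the true parameters so the short warmup adapts
  locally instead of hunting for the mode — each chain still drifts to
  wherever its own posterior concentrates, which is exactly the bias
  being measured.

The analysis frequencies matter: the baseline's independence
assumption costs accuracy where sampling resolves the relaxation
(eigenvalue) time scales, so the current channel is analyzed near the
fastest kinetics and the cPCF grid includes a slowly relaxing low
concentration. At this scale only the *direction* of the comparison
(ratio above 1 for both data types) is a stable statement; the
magnitude has large per-data-set scatter and is not asserted.

Other problem sizes used by the test suite (all chosen as the smallest
sizes at which the statistical statements are stable): $10^5$
generalized-multinomial draws for the moment oracle; the exact
count-space forward algorithm up to $N_{ch} = 250$ for the
normal-approximation gap; ten seeded replicates of the two-state
recovery study at $N_{ch} = 10^3$, 1 kHz (above the 300 s⁻¹ relaxation
rate — aliased sampling leaves only the rate ratio identifiable).

## Known limitations

* The normal approximation degrades for $N_{ch} \lesssim 10^2$ and for
  photon rates where Poisson skewness matters; count-space forward
  algorithms or particle filters are the right tools there.
* No smoothing pass, no colored-noise state augmentation, no
  voltage-clamp artifact modelling.
* The built-in sampler is a random-walk kernel: adequate for the 2–8
  parameter problems here, but long-tailed or strongly correlated
  posteriors (complex schemes from current-only data) warrant an
  external gradient-based backend via `backend`.
* Time is seconds, concentration µM, frequency Hz throughout; state
  indexing is 1-based in all user-facing structures.
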