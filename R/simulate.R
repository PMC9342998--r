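#' Noise and ensemble parameters of the signal model
#'
#' Collects the parameters of the observation model: `nch` channels per
#' patch, single-channel current `i` (signal units), instrumental
#' current noise SD `sigma_m`, per-open-channel excess noise SD
#' `sigma_op` (open-channel noise variance grows as
#' `sigma_op^2 * n_open`), mean photons per bound ligand per frame
#' `lambda_b`, and background-fluorescence SD `sigma_back` (a Gaussian
#' stand-in for the bulk-subtraction noise).
#'
#' Defaults are the package's canonical simulation conditions:
#' `nch = 1e3`, `i = 1`, `sigma_m = i`, `sigma_op^2 = 0.1 i^2`,
#' `lambda_b = 0.375`.
#'
#' @param nch Number of channels in the patch (>= 1).
#' @param i Mean single-channel current.
#' @param sigma_m Instrumental current-noise SD.
#' @param sigma_op Open-channel excess noise SD (per open channel).
#' @param lambda_b Mean photons per bound ligand per frame.
#' @param sigma_back Background fluorescence SD.
#' @return Named numeric vector of class `noise_params`.
#' @export
noise_params <- function(nch = 1e3, i = 1, sigma_m = 1,
                         sigma_op = sqrt(0.1), lambda_b = 0.375,
                         sigma_back = 1) {
  p <- c(nch = nch, i = i, sigma_m = sigma_m, sigma_op = sigma_op,
         lambda_b = lambda_b, sigma_back = sigma_back)
  if (any(!is.finite(p)) || any(p < 0)) stop("noise parameters must be >= 0")
  if (nch < 1) stop("nch must be >= 1")
  structure(p, class = "noise_params")
}

#' Concentration-jump protocol
#'
#' Piecewise-constant ligand concentration: the patch rests at
#' `conc_rest` (equilibrium initial condition), jumps to `conc` for
#' `t_on` seconds (activation) and back to `conc_rest` for `t_off`
#' seconds (deactivation). Jumps are ideal steps.
#'
#' @param conc Ligand concentration of the activation segment (uM).
#' @param t_on,t_off Segment durations in seconds (> 0).
#' @param conc_rest Resting concentration (uM), default 0.
#' @param f_sim Simulation sampling frequency in Hz (default 10 kHz;
#'   use 100 kHz for filter/integration studies).
#' @return List with `segments` (tibble of duration, conc), `conc_init`
#'   and `f_sim`.
#' @export
jump_protocol <- function(conc, t_on = 1, t_off = 1, conc_rest = 0,
                          f_sim = 1e4) {
  stopifnot(t_on > 0, t_off >= 0, conc >= 0, conc_rest >= 0, f_sim > 0)
  seg <- tibble::tibble(duration = c(t_on, t_off),
                        conc = c(conc, conc_rest))
  list(segments = seg[seg$duration > 0, ],
       conc_init = conc_rest, f_sim = f_sim)
}

#' The standard ten-concentration ladder
#'
#' @return Numeric vector of ligand concentrations (uM).
#' @export
standard_concentrations <- function() {
  c(0.0625, 0.125, 0.25, 0.5, 1, 2, 4, 8, 16, 64)
}

#' Exact stochastic simulation of a channel ensemble
#'
#' Doob-Gillespie simulation of the summed count vector n(t) of `nch`
#' independent channels under a concentration-jump protocol, sampled on
#' the `f_sim` grid. The initial ensemble is a multinomial draw from the
#' equilibrium occupancy at the resting concentration; concentration
#' jumps are applied instantaneously at segment boundaries.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named rate values.
#' @param protocol A protocol from [jump_protocol()].
#' @param nch Number of channels (>= 1).
#' @param seed Optional integer seed.
#' @return Object of class `occupancy_series`: list with `times` (s),
#'   `counts` (M x N integer matrix, columns sum to `nch`) and `nch`.
#' @export
gillespie_ensemble <- function(scheme, rates, protocol, nch,
                               seed = NULL) {
  stopifnot(nch >= 1)
  if (!is.null(seed)) set.seed(seed)
  seg <- protocol$segments
  seg_end <- cumsum(seg$duration)
  Klist <- lapply(seg$conc, function(L) build_rate_matrix(scheme, rates, L))
  K0 <- build_rate_matrix(scheme, rates, protocol$conc_init)
  p0 <- resting_distribution(K0)
  n0 <- as.integer(stats::rmultinom(1, nch, p0))
  times <- seq(0, seg_end[length(seg_end)] - 1 / protocol$f_sim,
               by = 1 / protocol$f_sim)
  counts <- gillespie_core(Klist, seg_end, times, n0)
  idx <- findInterval(times, c(0, seg_end), left.open = TRUE,
                      rightmost.closed = TRUE)
  ligand <- seg$conc[pmin(pmax(idx, 1L), nrow(seg))]
  ligand[1] <- protocol$conc_init  # t = 0: still at the resting state
  structure(list(times = times, counts = counts, ligand = ligand,
                 nch = nch, states = scheme$states),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat("<occupancy_series> ", length(x$times), " samples, ",
      nrow(x$counts), " states, Nch = ", x$nch, "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.occupancy_series <- function(x, ...) {
  d <- tibble::as_tibble(t(x$counts), .name_repair = "minimal")
  names(d) <- x$states
  dplyr::bind_cols(tibble::tibble(time = x$times, ligand = x$ligand), d)
}

#' Noisy current observation of an occupancy series
#'
#' `y_curr(t) = i * n_open(t) + nu(t)` with
#' `nu ~ N(0, sigma_m^2 + n_open(t) * sigma_op^2)`, independent per
#' sample: instrumental noise plus open-channel excess noise whose
#' variance scales with the number of open channels.
#'
#' @param occ An `occupancy_series`.
#' @param conducting Conducting multipliers per state (0/1).
#' @param noise A [noise_params()] vector.
#' @param seed Optional integer seed.
#' @return Numeric vector of current samples.
#' @export
observe_current <- function(occ, conducting, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_open <- as.numeric(conducting %*% occ$counts)
  v <- noise[["sigma_m"]]^2 + n_open * noise[["sigma_op"]]^2
  noise[["i"]] * n_open + stats::rnorm(length(n_open), 0, sqrt(v))
}

#' Photon-count observation of an occupancy series
#'
#' Per frame, `y_flu ~ Poisson(lambda_b * sum_a bound_a * n_a(t))` plus
#' a zero-mean Gaussian background term with SD `sigma_back` (the bulk
#' signal after reference subtraction).
#'
#' @param occ An `occupancy_series`.
#' @param bound_ligands Bound-ligand counts per state.
#' @param noise A [noise_params()] vector.
#' @param seed Optional integer seed.
#' @return Numeric vector of fluorescence samples.
#' @export
observe_fluorescence <- function(occ, bound_ligands, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam <- noise[["lambda_b"]] * as.numeric(bound_ligands %*% occ$counts)
  y <- stats::rpois(length(lam), lam)
  if (noise[["sigma_back"]] > 0)
    y <- y + stats::rnorm(length(lam), 0, noise[["sigma_back"]])
  y
}

#' Four-pole low-pass Bessel filter (single forward pass)
#'
#' Digital emulation of the analog anti-aliasing filter of a patch-clamp
#' amplifier: the analog Bessel prototype (poles of the reverse Bessel
#' polynomial, frequency-scaled so the -3 dB point sits at `f_cut`) is
#' discretized by the bilinear transform with prewarping and applied in
#' a single forward pass, so the group delay is not compensated --
#' exactly what an analog filter does to the signal.
#'
#' @param x Numeric signal vector.
#' @param f_cut -3 dB cut-off frequency in Hz (must be below Nyquist).
#' @param f_sample Sampling frequency of `x` in Hz.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bessel_filter <- function(x, f_cut, f_sample, order = 4) {
  if (f_cut >= f_sample / 2)
    stop("f_cut must be below the Nyquist frequency")
  ba <- bessel_coefficients(f_cut, f_sample, order)
  as.numeric(signal::filter(ba$b, ba$a, x))
}

# Digital coefficients of an order-n Bessel low-pass.  The reverse
# Bessel polynomial is built by the recursion
# theta_n(s) = (2n - 1) theta_{n-1}(s) + s^2 theta_{n-2}(s); its roots
# are the analog prototype poles.  The -3 dB frequency of the prototype
# is located numerically and used to rescale the poles, then the
# bilinear transform (with prewarping of f_cut) maps them to the z
# plane.
bessel_coefficients <- function(f_cut, f_sample, order = 4) {
  stopifnot(order >= 1, order <= 8)
  theta <- list(c(1), c(1, 1))                    # ascending powers of s
  for (n in 2:max(order, 2)) {
    a <- (2 * n - 1) * theta[[n]]
    b <- c(0, 0, theta[[n - 1]])
    len <- max(length(a), length(b))
    theta[[n + 1]] <- c(a, rep(0, len - length(a))) +
      c(b, rep(0, len - length(b)))
  }
  poly <- theta[[order + 1]]
  gain0 <- poly[1]
  # |H(jw)|^2 = gain0^2 / |theta(jw)|^2; find w with |H|^2 = 1/2
  mag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    Mod(sum(poly * s^(seq_along(poly) - 1)))^2
  }
  w3 <- stats::uniroot(function(w) gain0^2 / mag2(w) - 0.5,
                       c(1e-3, 50))$root
  p <- polyroot(poly) / w3                        # -3 dB at w = 1
  # bilinear transform with prewarping: s = c (z-1)/(z+1),
  # c = wc / tan(pi f_cut / f_sample) maps the analog wc to f_cut
  wc <- 2 * pi * f_cut
  cc <- wc / tan(pi * f_cut / f_sample)
  pa <- p * wc
  pz <- (1 + pa / cc) / (1 - pa / cc)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))   # zeros at z = -1
  # unit DC gain
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Finite frame-integration of a fluorescence trace
#'
#' Sums non-overlapping windows of `m = T_int * f_sample` samples,
#' emulating the finite integration time of confocal frame acquisition
#' (a Riemann sum of the analog signal over each frame). The output
#' rate is `1 / T_int`. Rescaling the brightness so that
#' `lambda_b / T_int` stays constant is the caller's responsibility;
#' [rescale_brightness()] documents the convention.
#'
#' @param x Numeric signal vector (per-sample photon counts).
#' @param t_int Integration time in seconds; must be a multiple of the
#'   sample interval.
#' @param f_sample Sampling frequency of `x` in Hz.
#' @return Numeric vector of window sums, length `floor(length(x)/m)`.
#' @export
integrate_window <- function(x, t_int, f_sample) {
  m <- t_int * f_sample
  if (abs(m - round(m)) > 1e-8)
    stop("t_int must be a multiple of the sample interval")
  m <- as.integer(round(m))
  if (m > length(x)) stop("integration window longer than trace")
  nwin <- length(x) %/% m
  as.numeric(tapply(x[seq_len(nwin * m)],
                    rep(seq_len(nwin), each = m), sum))
}

#' Brightness rescaling for integrated frames
#'
#' When frames are integrated over `t_int`, keeping the signal-to-noise
#' per output point comparable across integration times requires
#' `lambda_b / t_int = const`: the per-sample brightness to simulate at
#' `f_sample` is `lambda_b_frame / (t_int * f_sample)`.
#'
#' @param lambda_b_frame Target mean photons per bound ligand per
#'   output frame.
#' @param t_int Integration time (s).
#' @param f_sample Simulation frequency (Hz).
#' @return Per-sample brightness.
#' @export
rescale_brightness <- function(lambda_b_frame, t_int, f_sample) {
  lambda_b_frame / (t_int * f_sample)
}

#' Decimate a trace to the analysis frequency
#'
#' Keeps every `f_sample / f_ana`-th sample (subsampling, not
#' averaging), starting at the first sample.
#'
#' @param x Numeric signal vector.
#' @param f_sample Sampling frequency of `x` (Hz).
#' @param f_ana Target analysis frequency (Hz); `f_sample` must be an
#'   integer multiple.
#' @return Subsampled vector.
#' @export
decimate_trace <- function(x, f_sample, f_ana) {
  stride <- f_sample / f_ana
  if (abs(stride - round(stride)) > 1e-8)
    stop("f_sample must be an integer multiple of f_ana")
  x[seq(1, length(x), by = as.integer(round(stride)))]
}

#' Simulate a full PC / cPCF data set
#'
#' For each ligand concentration: an exact Gillespie ensemble
#' trajectory under the jump protocol, the current observation with
#' instrumental + open-channel noise (optionally Bessel-filtered at
#' `f_cut` before decimation to `f_ana`), and, for cPCF, per-frame
#' Poisson photon counts plus Gaussian background at the frame rate
#' `f_ana` (or integrated over `t_int`). The fluorescence monitors the
#' full conducting ensemble (`Nch_FL = Nch_I`).
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named rate values.
#' @param noise A [noise_params()] vector (includes `nch`).
#' @param concentrations Ligand concentrations (uM), one trace each.
#' @param t_on,t_off Activation / deactivation durations (s).
#' @param f_sim Simulation frequency (Hz).
#' @param f_ana Analysis/frame frequency (Hz); must divide `f_sim`.
#' @param observe `"cpcf"` (current + fluorescence) or `"pc"`.
#' @param f_cut Optional Bessel cut-off (Hz) applied to the current at
#'   `f_sim` before decimation.
#' @param t_int Optional fluorescence integration time (s); photon
#'   counts are then simulated at `f_sim` with per-sample brightness
#'   `lambda_b / (t_int * f_sim)` and summed per frame.
#' @param seed Optional integer seed (one seed drives the whole set).
#' @return A tibble of class `trace_set` with columns `time`, `conc`
#'   (the jump concentration labelling the trace), `ligand` (bath
#'   concentration governing the interval ending at each sample),
#'   `y_curr` and (for cPCF) `y_flu`; attributes carry `f_ana`,
#'   `noise`, `scheme_name`, `t_on`, `conc_rest` and `seed`.
#' @examples
#' tr <- simulate_traces(scheme_ccco(), ccco_rates(), noise_params(nch = 100),
#'                       concentrations = c(1, 64), t_on = 0.2, t_off = 0.2,
#'                       f_sim = 2000, f_ana = 200, seed = 1)
#' dplyr::count(tr, conc)
#' @export
simulate_traces <- function(scheme, rates, noise = noise_params(),
                            concentrations = standard_concentrations(),
                            t_on = 1, t_off = 1, f_sim = 1e4,
                            f_ana = 250, observe = c("cpcf", "pc"),
                            f_cut = NULL, t_int = NULL, seed = NULL) {
  observe <- match.arg(observe)
  if (!is.null(seed)) set.seed(seed)
  stride <- f_sim / f_ana
  if (abs(stride - round(stride)) > 1e-8)
    stop("f_sim must be an integer multiple of f_ana")
  nch <- noise[["nch"]]
  traces <- purrr::map(concentrations, function(L) {
    prot <- jump_protocol(L, t_on = t_on, t_off = t_off, f_sim = f_sim)
    occ <- gillespie_ensemble(scheme, rates, prot, nch)
    y_curr <- observe_current(occ, scheme$conducting, noise)
    if (!is.null(f_cut))
      y_curr <- bessel_filter(y_curr, f_cut, f_sim)
    keep <- seq(1, length(occ$times), by = as.integer(round(stride)))
    d <- tibble::tibble(time = occ$times[keep],
                        conc = L,
                        ligand = occ$ligand[keep],
                        y_curr = y_curr[keep])
    if (observe == "cpcf") {
      if (is.null(t_int)) {
        occ_f <- list(counts = occ$counts[, keep, drop = FALSE])
        d$y_flu <- observe_fluorescence(
          structure(occ_f, class = "occupancy_series"),
          scheme$bound_ligands, noise)
      } else {
        if (abs(t_int * f_ana - 1) > 1e-8)
          stop("with finite integration the frame rate 1/t_int must equal f_ana")
        lam_s <- rescale_brightness(noise[["lambda_b"]], t_int, f_sim)
        ns <- noise
        ns[["lambda_b"]] <- lam_s
        ns[["sigma_back"]] <- 0
        yf <- observe_fluorescence(occ, scheme$bound_ligands, ns)
        yi <- integrate_window(yf, t_int, f_sim)
        if (noise[["sigma_back"]] > 0)
          yi <- yi + stats::rnorm(length(yi), 0, noise[["sigma_back"]])
        nfr <- length(yi)
        d <- d[seq_len(min(nrow(d), nfr)), ]
        d$y_flu <- yi[seq_len(nrow(d))]
      }
    }
    d
  })
  out <- dplyr::bind_rows(traces)
  new_trace_set(out, f_ana = f_ana, noise = noise,
                scheme_name = scheme$name, t_on = t_on, t_off = t_off,
                conc_rest = 0, f_cut = f_cut, t_int = t_int, seed = seed)
}

new_trace_set <- function(d, ...) {
  meta <- list(...)
  attr(d, "meta") <- meta
  class(d) <- c("trace_set", class(d))
  d
}

#' Metadata of a trace set
#' @param traces A `trace_set`.
#' @return Named list (f_ana, noise, scheme_name, ...).
#' @export
trace_meta <- function(traces) attr(traces, "meta")
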