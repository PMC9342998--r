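#' Write / read a trace set as a source-data style directory
#'
#' On-disk layout mirrors the conventional source-data folders: a
#' shared `Time.txt` (one time column, seconds), `Current.txt` and
#' optionally `Fluorescence.txt` with one whitespace-separated column
#' per ligand concentration, plus a `meta.json` sidecar holding the
#' concentrations, analysis frequency, protocol timing and noise
#' parameters. Raw (unnormalized) signals are stored; any display
#' normalization is a view, never written.
#'
#' @param traces A `trace_set` tibble.
#' @param dir Directory to create/write.
#' @return `dir`, invisibly.
#' @export
write_trace_dir <- function(traces, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- trace_meta(traces)
  concs <- unique(traces$conc)
  wide <- function(col) {
    sapply(concs, function(L) traces[[col]][traces$conc == L])
  }
  t0 <- traces$time[traces$conc == concs[1]]
  utils::write.table(data.frame(time = t0),
                     file.path(dir, "Time.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(wide("y_curr"), file.path(dir, "Current.txt"),
                     row.names = FALSE, col.names = FALSE)
  if ("y_flu" %in% names(traces))
    utils::write.table(wide("y_flu"), file.path(dir, "Fluorescence.txt"),
                       row.names = FALSE, col.names = FALSE)
  side <- list(concentrations = concs,
               f_ana = meta$f_ana, t_on = meta$t_on, t_off = meta$t_off,
               conc_rest = if (is.null(meta$conc_rest)) 0 else meta$conc_rest,
               noise = as.list(unclass(meta$noise)),
               scheme = meta$scheme_name, seed = meta$seed)
  jsonlite::write_json(side, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @param dir Directory written by [write_trace_dir()].
#' @rdname write_trace_dir
#' @return `read_trace_dir` returns a `trace_set` tibble; without a
#'   `Fluorescence.txt` a PC-only set is returned.
#' @export
read_trace_dir <- function(dir) {
  tfile <- file.path(dir, "Time.txt")
  if (!file.exists(tfile)) stop("no Time.txt in ", dir)
  times <- scan(tfile, quiet = TRUE)
  if (any(diff(times) <= 0)) stop("non-monotone time axis")
  side <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cur <- as.matrix(utils::read.table(file.path(dir, "Current.txt")))
  if (nrow(cur) != length(times)) stop("ragged columns in Current.txt")
  ffile <- file.path(dir, "Fluorescence.txt")
  flu <- if (file.exists(ffile))
    as.matrix(utils::read.table(ffile)) else NULL
  concs <- side$concentrations
  if (ncol(cur) != length(concs))
    stop("column count does not match concentrations in meta.json")
  rest <- if (is.null(side$conc_rest)) 0 else side$conc_rest
  out <- purrr::map_dfr(seq_along(concs), function(k) {
    lig <- ifelse(times <= 0, rest,
                  ifelse(times <= side$t_on, concs[k], rest))
    d <- tibble::tibble(time = times, conc = concs[k], ligand = lig,
                        y_curr = cur[, k])
    if (!is.null(flu)) d$y_flu <- flu[, k]
    d
  })
  noise <- do.call(noise_params, side$noise[c("nch", "i", "sigma_m",
                                              "sigma_op", "lambda_b",
                                              "sigma_back")])
  new_trace_set(out, f_ana = side$f_ana, noise = noise,
                scheme_name = side$scheme, t_on = side$t_on,
                t_off = side$t_off, conc_rest = rest, seed = side$seed)
}

#' Run the simulate - fit - diagnose pipeline
#'
#' Seeded end-to-end run: simulate a data set (or read one from
#' `config$data_dir`), sample the posterior with the requested method
#' and produce residual/coverage summaries. All randomness flows from
#' the single `seed`; stage seeds are derived from it.
#'
#' @param config Named list: `scheme` (a `kinetic_scheme` or YAML
#'   path), `rates` (named true/starting rates), `noise`
#'   ([noise_params()] arguments or vector), `concentrations`, `t_on`,
#'   `t_off`, `f_sim`, `f_ana`, `observe`, `method` ("kf"/"re"),
#'   `priors`, `chains`, `iter`, `warmup`, `seed`, optional `data_dir`
#'   (read instead of simulating) and `out_dir` (write artifacts).
#' @return List with `traces`, `fit` (a `pkf_fit`), `summary`
#'   ([tidy()]), `residuals` and `log` (stage seeds and versions).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  scheme <- if (inherits(cfg$scheme, "kinetic_scheme")) cfg$scheme
            else read_scheme(cfg$scheme)
  noise <- if (inherits(cfg$noise, "noise_params")) cfg$noise
           else do.call(noise_params, as.list(cfg$noise))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  log <- list(seed = seed, sim_seed = seed, fit_seed = seed + 1L,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("patchkf")))
  traces <- if (!is.null(cfg$data_dir)) {
    read_trace_dir(cfg$data_dir)
  } else {
    simulate_traces(scheme, cfg$rates, noise,
                    concentrations = cfg$concentrations %||%
                      standard_concentrations(),
                    t_on = cfg$t_on %||% 1, t_off = cfg$t_off %||% 1,
                    f_sim = cfg$f_sim %||% 1e4,
                    f_ana = cfg$f_ana %||% 250,
                    observe = cfg$observe %||% "cpcf",
                    f_cut = cfg$f_cut, t_int = cfg$t_int,
                    seed = log$sim_seed)
  }
  method <- cfg$method %||% "kf"
  fit <- sample_posterior(traces, scheme, cfg$priors, cfg$rates, noise,
                          method = method,
                          chains = cfg$chains %||% 2,
                          iter = cfg$iter %||% 500,
                          warmup = cfg$warmup %||% 500,
                          seed = log$fit_seed)
  summ <- tidy(fit)
  med <- stats::setNames(summ$median, summ$term)
  full <- assemble_rates(scheme, med, unlist(cfg$rates))
  resid <- normalized_residuals(traces, scheme, full, noise,
                                method = method)
  out <- list(traces = traces, fit = fit, summary = summ,
              residuals = resid, log = log)
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    write_trace_dir(traces, file.path(cfg$out_dir, "traces"))
    utils::write.csv(fit, file.path(cfg$out_dir, "samples.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summ, log = log,
           residual_variance = stats::var(resid$r)),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
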