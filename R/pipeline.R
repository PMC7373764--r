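# End-to-end driver: simulate/read -> calibrate -> extract rates -> fit ->
# derive -> report. All machine outputs are CSV/JSON with '#' metadata
# headers; nothing time-stamped, so a rerun with the same config and seed is
# byte-identical.

#' Percent degradation between two concentrations
#'
#' Endpoint summary `100 * (c0 - ct) / c0`, clipped to `[0, 100]`. Final
#' concentrations slightly above the initial one (within `tolerance`,
#' measurement scatter) clip to 0% rather than going negative; larger
#' excesses are an error, as is a non-positive starting concentration.
#'
#' @param c0 Initial concentration(s), mg/L; > 0.
#' @param ct Final concentration(s), mg/L.
#' @param tolerance Allowed fractional excess of `ct` over `c0`
#'   (default 0.02).
#' @return Percent degradation in `[0, 100]`.
#' @examples
#' percent_degradation(240, 240 * (1 - 0.949))  # 94.9
#' @export
percent_degradation <- function(c0, ct, tolerance = 0.02) {
  if (!is.numeric(c0) || !is.numeric(ct) || any(is.na(c0)) || any(is.na(ct)))
    stop("'c0' and 'ct' must be numeric with no missing values", call. = FALSE)
  if (any(c0 <= 0))
    stop("initial concentration 'c0' must be > 0", call. = FALSE)
  if (any(ct < 0) || any(ct > c0 * (1 + tolerance)))
    stop("'ct' must lie in [0, c0*(1+tolerance)]", call. = FALSE)
  pmin(pmax(100 * (c0 - ct) / c0, 0), 100)
}

#' Assemble a pipeline configuration
#'
#' Either build the list in R or load it from a YAML file with
#' [read_pipeline_config()]. Exactly one input mode is used: `simulate` (a
#' scenario block; the generator produces the curves) or `input_csv` (a
#' batch-curve CSV as read by [read_batch_curves()]).
#'
#' @param simulate Optional [simulation_scenario()].
#' @param input_csv Optional path to a batch-curve CSV.
#' @param calibration Optional named list with elements `phenol` and/or
#'   `biomass`, each a [linear_calibration()], applied when the input
#'   carries raw `a500` / `od600` columns.
#' @param branches Which branches to fit: subset of
#'   `c("growth", "degradation")`.
#' @param window `"full"` (default: conventional whole-series fit over the usable
#'   series) or `"auto"` ([select_exponential_window()] per curve).
#' @param rate_source `"curves"` (default: rates extracted from the batch
#'   time-courses by log-linear regression, as from real data) or
#'   `"direct"` (simulation only: [generate_rate_points()] evaluates the
#'   rate law at each s0, bypassing the time-course layer — the mode for
#'   fit-level validation, where curve-level windowing bias is out of
#'   scope).
#' @param fit Options list for [fit_haldane()]: `n_starts`, `seed`,
#'   `weights`.
#' @param outdir Output directory; created if absent.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, input_csv = NULL,
                            calibration = NULL,
                            branches = c("growth", "degradation"),
                            window = c("full", "auto"),
                            rate_source = c("curves", "direct"),
                            fit = list(), outdir = tempfile("haldane_run")) {
  window <- match.arg(window)
  rate_source <- match.arg(rate_source)
  branches <- match.arg(branches, several.ok = TRUE)
  if (rate_source == "direct" && is.null(simulate))
    stop("configuration error: rate_source 'direct' requires a 'simulate' block",
         call. = FALSE)
  if (is.null(simulate) && is.null(input_csv))
    stop("configuration error: one of 'simulate' or 'input_csv' is required",
         call. = FALSE)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "simulation_scenario"))
  structure(
    list(simulate = simulate, input_csv = input_csv,
         calibration = calibration, branches = branches, window = window,
         rate_source = rate_source,
         fit = utils::modifyList(
           list(n_starts = 10L, seed = 1L, weights = "none"), fit),
         outdir = outdir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a structured config file. Recognised top-level keys: `input_csv`,
#' `calibration` (sub-keys `phenol`/`biomass`, each with `slope`,
#' `intercept`, optional `range`, `dilution`), `simulate` (sub-keys
#' `growth`/`degradation` with `rate_star`, `ks`, `ki`, plus any
#' [simulation_scenario()] field), `branches`, `window`, `fit`, `outdir`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cal <- NULL
  if (!is.null(y$calibration)) {
    cal <- lapply(y$calibration, function(b)
      linear_calibration(slope = b$slope, intercept = b$intercept,
                         range = unlist(b$range) %||% c(0, 1200),
                         dilution = b$dilution %||% 1))
  }
  scn <- NULL
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    mk <- function(b, branch) haldane_params(b$rate_star, b$ks,
                                             b$ki %||% Inf, branch = branch)
    scn <- simulation_scenario(
      growth_params = mk(sim$growth, "growth"),
      degradation_params = mk(sim$degradation, "degradation"),
      s0_grid = unlist(sim$s0_grid) %||%
        c(41, 100, 200, 400, 600, 800, 980, 1117),
      x0 = sim$x0 %||% 25, lag = sim$lag_threshold %||% 1000,
      sampling_interval = sim$sampling_interval %||% 12,
      horizon = sim$horizon %||% 120,
      noise_cv = sim$noise_cv %||% 0.05,
      replicates = sim$replicates %||% 3L, seed = sim$seed %||% 1L)
  }
  pipeline_config(
    simulate = scn, input_csv = y$input_csv, calibration = cal,
    branches = y$branches %||% c("growth", "degradation"),
    window = y$window %||% "full",
    rate_source = y$rate_source %||% "curves",
    fit = y$fit %||% list(),
    outdir = y$outdir %||% tempfile("haldane_run"))
}

pipeline_metadata <- function(config) {
  # hash the scientific content only: the output location is not part of the
  # analysis, and the lag closure's environment does not serialize stably
  cfg_for_hash <- config[setdiff(names(config), "outdir")]
  cfg_for_hash$simulate <- if (is.null(config$simulate)) NULL else
    config$simulate[setdiff(names(config$simulate), "lag")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg_for_hash, tmp, version = 2)
  c(tool = paste0("haldane ",
                  as.character(utils::packageVersion("haldane"))),
    seed = as.character(config$fit$seed),
    config_hash = unname(tools::md5sum(tmp)))
}

write_table_with_metadata <- function(df, path, metadata) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full kinetics pipeline
#'
#' Executes, in order: data acquisition (simulate the scenario, or read and
#' calibrate a CSV), per-replicate rate extraction for each requested
#' branch, Haldane fitting on the pooled (s0, rate) points, derivation of
#' Sm and the true maximum rate, and report emission. Every numeric in the
#' report is traceable to a stage output file in `outdir`:
#' `curves.csv` (when simulating), `rates.csv` (per-replicate estimates),
#' `rates_summary.csv` (mean and SD per s0), `report.csv`, `report.txt`,
#' and `summary.json`. Fitted-parameter tables round to 2 decimals for the
#' growth branch and 3 for the degradation branch, matching the customary
#' reporting precision of each; nothing is rounded internally.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return Invisibly, a list with `fits` (per branch), `rates`
#'   (data.frame), `report` (data.frame, unrounded), and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  meta <- pipeline_metadata(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  # stage 1: curves
  if (!is.null(config$simulate)) {
    scn <- config$simulate
    curves <- unlist(lapply(scn$s0_grid, function(s0)
      simulate_batch(scn, s0)), recursive = FALSE)
    paths$curves <- file.path(config$outdir, "curves.csv")
    write_batch_curves(curves, paths$curves,
                       metadata = c(meta, sim_seed = as.character(scn$seed)))
  } else {
    curves <- tryCatch(
      read_batch_curves(config$input_csv,
                        phenol_cal = config$calibration$phenol,
                        biomass_cal = config$calibration$biomass),
      error = function(e) stop(sprintf(
        "stage 'acquire' failed on '%s': %s", config$input_csv,
        conditionMessage(e)), call. = FALSE))
  }

  # stage 2: per-replicate rates. Curves that cannot support a log-linear
  # slope (e.g. substrate already exhausted at the second sample) are
  # skipped with a warning; the branch fails later only if nothing usable
  # remains.
  if (config$rate_source == "direct") {
    rates <- do.call(rbind, lapply(config$branches, function(br) {
      pts <- generate_rate_points(config$simulate,
                                  noise_sd = config$simulate$noise_cv,
                                  branch = br)
      data.frame(s0 = pts$s0, branch = br, rate = pts$rate, r2 = NA_real_,
                 window_start = NA_real_, window_end = NA_real_,
                 n_points = NA_integer_, replicate = pts$replicate)
    }))
  } else {
    rates <- do.call(rbind, unlist(lapply(config$branches, function(br) {
      lapply(curves, function(cv) {
        series <- if (br == "growth") cv$biomass else cv$substrate
        if (is.null(series) || cv$s0 <= 0) return(NULL)
        est <- tryCatch({
          win <- if (config$window == "auto")
            select_exponential_window(cv, br)$window else NULL
          if (br == "growth") specific_growth_rate(cv, window = win)
          else specific_degradation_rate(cv, window = win)
        }, error = function(e) {
          warning(sprintf(
            "skipping %s rate for s0 = %g, replicate %s: %s",
            br, cv$s0, cv$replicate, conditionMessage(e)), call. = FALSE)
          NULL
        })
        if (is.null(est)) NULL else as.data.frame(est)
      })
    }), recursive = FALSE))
    if (is.null(rates) || nrow(rates) == 0L)
      stop("stage 'rates' failed: no curve yielded a usable rate estimate",
           call. = FALSE)
  }
  rates <- rates[order(rates$branch, rates$s0, rates$replicate), ,
                 drop = FALSE]
  rownames(rates) <- NULL
  paths$rates <- file.path(config$outdir, "rates.csv")
  write_table_with_metadata(rates, paths$rates, meta)

  # replicate aggregation: mean +/- SD per (branch, s0)
  agg <- do.call(rbind, lapply(split(rates, rates[c("branch", "s0")],
                                     drop = TRUE), function(g)
    data.frame(branch = g$branch[1], s0 = g$s0[1], rate = mean(g$rate),
               sd = if (nrow(g) > 1) stats::sd(g$rate) else 0,
               n = nrow(g))))
  agg <- agg[order(agg$branch, agg$s0), , drop = FALSE]
  rownames(agg) <- NULL
  paths$rates_summary <- file.path(config$outdir, "rates_summary.csv")
  write_table_with_metadata(agg, paths$rates_summary, meta)

  # stage 3: fit + derive
  fits <- lapply(config$branches, function(br) {
    pts <- rates[rates$branch == br, c("s0", "rate")]
    if (any(pts$rate < 0)) {
      warning(sprintf(
        "dropping %d negative %s rate estimate(s) before fitting",
        sum(pts$rate < 0), br), call. = FALSE)
      pts <- pts[pts$rate >= 0, , drop = FALSE]
    }
    tryCatch(
      fit_haldane(pts, branch = br, n_starts = config$fit$n_starts,
                  seed = config$fit$seed, weights = config$fit$weights),
      error = function(e) stop(sprintf("stage 'fit' failed (branch %s): %s",
                                       br, conditionMessage(e)),
                               call. = FALSE))
  })
  names(fits) <- config$branches

  report <- do.call(rbind, lapply(fits, function(f)
    data.frame(branch = f$params$branch, rate_star = f$params$rate_star,
               ks = f$params$ks, ki = f$params$ki, s_m = f$derived$s_m,
               true_max = f$derived$true_max_rate, r2 = f$r2,
               n_points = f$n_points, converged = f$converged)))
  rownames(report) <- NULL

  # stage 4: reports (rounding applied here only)
  rounded <- report
  for (i in seq_len(nrow(rounded))) {
    dp <- if (rounded$branch[i] == "growth") 2L else 3L
    num <- c("rate_star", "ks", "ki", "s_m", "true_max", "r2")
    rounded[i, num] <- round(rounded[i, num], dp)
  }
  paths$report_csv <- file.path(config$outdir, "report.csv")
  write_table_with_metadata(rounded, paths$report_csv, meta)

  paths$report_txt <- file.path(config$outdir, "report.txt")
  txt <- c(sprintf("# %s: %s", names(meta), meta),
           "Haldane kinetics report", "")
  for (i in seq_len(nrow(rounded)))
    txt <- c(txt, sprintf(
      "%s: rate* = %s 1/h, Ks = %s mg/L, Ki = %s mg/L, Sm = %s mg/L, true max = %s 1/h, R2 = %s (%d points%s)",
      rounded$branch[i], rounded$rate_star[i], rounded$ks[i], rounded$ki[i],
      rounded$s_m[i], rounded$true_max[i], rounded$r2[i],
      rounded$n_points[i],
      if (rounded$converged[i]) "" else ", NOT converged"))
  writeLines(txt, paths$report_txt)

  paths$summary_json <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(
    list(metadata = as.list(meta),
         fits = lapply(fits, function(f) list(
           branch = f$params$branch, rate_star = f$params$rate_star,
           ks = f$params$ks, ki = f$params$ki, s_m = f$derived$s_m,
           true_max = f$derived$true_max_rate, r2 = f$r2,
           converged = f$converged))),
    paths$summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(fits = fits, rates = rates, report = report, paths = paths))
}
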