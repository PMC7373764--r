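#' A single batch-culture time-course
#'
#' One replicate's sampled trajectory at a given initial substrate
#' concentration: dry biomass and/or residual substrate, in mg/L, at
#' strictly increasing sampling times. At least one of the two series must
#' be present with three or more points (the minimum for a log-linear slope
#' with a degree of freedom to spare).
#'
#' @param times Sampling times, h; strictly increasing.
#' @param s0 Nominal initial substrate concentration, mg/L.
#' @param biomass Optional dry biomass series, mg/L, same length as `times`.
#' @param substrate Optional substrate series, mg/L, same length as `times`.
#' @param replicate Replicate label.
#' @return An object of class `batch_curve`.
#' @export
batch_curve <- function(times, s0, biomass = NULL, substrate = NULL,
                        replicate = "r1") {
  if (!is.numeric(times) || length(times) < 3L || any(is.na(times)))
    stop("'times' must be numeric with >= 3 non-missing values", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  stop_if_not_number(s0, "s0")
  if (s0 < 0) stop("'s0' must be non-negative", call. = FALSE)
  if (is.null(biomass) && is.null(substrate))
    stop("at least one of 'biomass' or 'substrate' is required", call. = FALSE)
  for (nm in c("biomass", "substrate")) {
    v <- get(nm)
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != length(times) || any(is.na(v)))
      stop(sprintf("'%s' must be numeric, same length as 'times', no NAs", nm),
           call. = FALSE)
    if (any(v < 0))
      stop(sprintf("'%s' contains negative concentrations", nm), call. = FALSE)
  }
  if (!is.null(substrate) && s0 > 0 &&
      abs(substrate[1] - s0) > 0.10 * s0)
    warning(sprintf(
      "first substrate observation (%.4g mg/L) differs from nominal s0 (%.4g mg/L) by more than 10%%",
      substrate[1], s0), call. = FALSE)
  structure(
    list(times = as.numeric(times), s0 = s0,
         biomass = if (is.null(biomass)) NULL else as.numeric(biomass),
         substrate = if (is.null(substrate)) NULL else as.numeric(substrate),
         replicate = as.character(replicate)),
    class = "batch_curve"
  )
}

#' @export
print.batch_curve <- function(x, ...) {
  cat(sprintf(
    "Batch curve [%s], s0 = %.4g mg/L: %d samples over %g-%g h (%s%s)\n",
    x$replicate, x$s0, length(x$times), min(x$times), max(x$times),
    if (is.null(x$biomass)) "" else "biomass",
    if (is.null(x$substrate)) "" else
      paste0(if (is.null(x$biomass)) "" else " + ", "substrate")))
  invisible(x)
}

#' @export
as.data.frame.batch_curve <- function(x, ...) {
  data.frame(
    time_h = x$times,
    s0_mg_per_l = x$s0,
    replicate = x$replicate,
    biomass_mg_per_l = if (is.null(x$biomass)) NA_real_ else x$biomass,
    phenol_mg_per_l = if (is.null(x$substrate)) NA_real_ else x$substrate
  )
}

#' Read batch time-courses from CSV
#'
#' Expects a header row with columns `time_h`, `s0_mg_per_l`, `replicate`,
#' and concentration columns `biomass_mg_per_l` / `phenol_mg_per_l` or raw
#' instrument columns `od600` / `a500`. Raw columns are converted through
#' the supplied calibrations; a file carrying `od600` without a biomass
#' calibration is a configuration error. Lines starting with `#` are
#' metadata and are skipped.
#'
#' @param path CSV file path.
#' @param phenol_cal Optional [linear_calibration()] for the `a500` column.
#' @param biomass_cal Optional [linear_calibration()] for the `od600`
#'   column.
#' @return A list of [batch_curve()] objects, one per (s0, replicate).
#' @export
read_batch_curves <- function(path, phenol_cal = NULL, biomass_cal = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_h", "s0_mg_per_l", "replicate")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' must carry columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if ("od600" %in% names(df) && !"biomass_mg_per_l" %in% names(df)) {
    if (is.null(biomass_cal))
      stop(paste0("'", path, "' carries raw od600 readings but no ",
                  "OD600 -> dry-biomass calibration was supplied"),
           call. = FALSE)
    df$biomass_mg_per_l <- od_to_dry_biomass(df$od600, biomass_cal)
  }
  if ("a500" %in% names(df) && !"phenol_mg_per_l" %in% names(df)) {
    if (is.null(phenol_cal))
      stop(paste0("'", path, "' carries raw a500 readings but no phenol ",
                  "calibration was supplied"), call. = FALSE)
    df$phenol_mg_per_l <- absorbance_to_concentration(df$a500, phenol_cal)
  }
  has_x <- "biomass_mg_per_l" %in% names(df)
  has_s <- "phenol_mg_per_l" %in% names(df)
  if (!has_x && !has_s)
    stop(sprintf("'%s' carries neither biomass nor substrate columns", path),
         call. = FALSE)
  groups <- split(df, list(df$s0_mg_per_l, df$replicate), drop = TRUE)
  curves <- lapply(groups, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    batch_curve(
      times = g$time_h, s0 = g$s0_mg_per_l[1],
      biomass = if (has_x && !all(is.na(g$biomass_mg_per_l)))
        g$biomass_mg_per_l else NULL,
      substrate = if (has_s && !all(is.na(g$phenol_mg_per_l)))
        g$phenol_mg_per_l else NULL,
      replicate = g$replicate[1])
  })
  unname(curves[order(vapply(curves, `[[`, 0, "s0"),
                      vapply(curves, `[[`, "", "replicate"))])
}

#' Write batch time-courses to CSV
#'
#' Emits the schema read by [read_batch_curves()], optionally preceded by
#' `#`-prefixed metadata lines.
#'
#' @param curves A list of [batch_curve()] objects.
#' @param path Output CSV path.
#' @param metadata Optional named character vector written as
#'   `# name: value` header lines.
#' @return `path`, invisibly.
#' @export
write_batch_curves <- function(curves, path, metadata = NULL) {
  if (inherits(curves, "batch_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata), metadata), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
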