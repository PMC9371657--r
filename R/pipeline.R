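#' Write and read tidy trace tables
#'
#' The on-disk format is a long CSV with columns `cell_id`, `channel`,
#' `time_s`, `intensity_au`, `distance_um`, `laser_on` (0/1), one row per
#' frame per trace.
#'
#' @param traces Named list of [fluor_trace()].
#' @param path CSV path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   named list of [fluor_trace()].
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, channel = tr$channel,
               time_s = tr$time_s, intensity_au = tr$intensity_au,
               distance_um = tr$distance_um,
               laser_on = as.integer(tr$laser_on))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trace file")
  required <- c("cell_id", "channel", "time_s", "intensity_au",
                "distance_um", "laser_on")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("trace file is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  key <- paste(df$cell_id, df$channel, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (anyDuplicated(sub$time_s)) {
      stop(sprintf("duplicate (cell_id, channel, time) rows for cell '%s'",
                   sub$cell_id[1]))
    }
    if (is.unsorted(sub$time_s, strictly = TRUE)) {
      stop(sprintf("non-monotone times for cell '%s'", sub$cell_id[1]))
    }
    id <- sub$cell_id[1]
    out[[id]] <- fluor_trace(sub$time_s, sub$intensity_au,
                             laser_on = sub$laser_on == 1,
                             cell_id = id, channel = sub$channel[1],
                             distance_um = sub$distance_um[1])
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes `traces.csv`, `roi.csv` and `truth.csv` under `dir`.
#'
#' @param cohort A `hicr_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hicr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(traces = file.path(dir, "traces.csv"),
                roi = file.path(dir, "roi.csv"),
                truth = file.path(dir, "truth.csv"))
  write_traces(cohort$traces, paths$traces)
  utils::write.csv(cohort$roi, paths$roi, row.names = FALSE)
  utils::write.csv(cohort$truth, paths$truth, row.names = FALSE)
  invisible(paths)
}

# classify traces into roles by convention:
#   channel "eutta"            -> temperature-dye sheet ROI
#   cell_id starting with "bg" -> cell-free background ROI
#   no laser-on frames         -> unheated reference cell
split_roles <- function(traces) {
  ch <- vapply(traces, function(tr) tr$channel, character(1))
  id <- vapply(traces, function(tr) tr$cell_id, character(1))
  sheet <- traces[ch == "eutta"]
  bgroi <- traces[ch != "eutta" & grepl("^bg", id)]
  cells <- traces[ch != "eutta" & !grepl("^bg", id)]
  heated <- cells[vapply(cells, function(tr) any(tr$laser_on), logical(1))]
  unheated <- cells[!vapply(cells, function(tr) any(tr$laser_on), logical(1))]
  list(sheet = sheet, background = bgroi, heated = heated, unheated = unheated)
}

# estimate backgrounds from a cell-free ROI: laser-on mean is the laser-on
# background, off-pulse mean approximates the excitation-off background
estimate_backgrounds <- function(bg_traces) {
  if (length(bg_traces) == 0L) stop("no background ROI (cell_id 'bg*') found")
  ons <- unlist(lapply(bg_traces, function(tr) tr$intensity_au[tr$laser_on]))
  offs <- unlist(lapply(bg_traces, function(tr) tr$intensity_au[!tr$laser_on]))
  if (length(ons) == 0L) stop("background ROI has no laser-on frames")
  background_estimates(i_back = max(0, mean(offs)), i_laser = max(0, mean(ons)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis of one microheating experiment:
#' thermometry (dye-sheet profile and per-cell temperature rises), burst
#' metrics (scatter-corrected dF_max/F0 per heated cell), the
#' spontaneous-fluctuation threshold (Gaussian-CDF fit on unheated cells,
#' unless `df_th` is supplied), responder classification and the logistic
#' dose-response fit for the heat-sensitivity threshold dT_th.
#' Deterministic given `seed`; excluded cells are recorded with
#' machine-readable reason codes.
#'
#' @param traces Named list of [fluor_trace()] (e.g. from [read_traces()] or
#'   a `hicr_cohort$traces`), containing temperature-dye sheet traces
#'   (channel "eutta"), at least one cell-free background ROI (cell_id
#'   prefix "bg"), heated cells, and unheated reference cells unless `df_th`
#'   is given.
#' @param protocol A [heat_protocol()].
#' @param bg Optional [background_estimates()]; estimated from the
#'   background ROI when NULL.
#' @param cal A [calibration_curve()].
#' @param df_th Optional externally supplied responder threshold (used when
#'   no unheated fluctuation set exists, e.g. muscle runs); logged as such.
#' @param dfmax_window_s Burst analysis window after pulse onset, s.
#' @param spont_window Fluctuation window for unheated cells, s.
#' @param boot Bootstrap resamples for the dT_th CI.
#' @param seed Seed for all stochastic steps.
#' @param outdir Optional output directory: writes `report.json`,
#'   `metrics.csv` and `bins.csv`.
#' @return An object of class `hicr_report`: list with `metrics` (per-cell
#'   data frame), `profile`, `fluctuation` (a `fluctuation_fit` or NULL),
#'   `df_th`, `df_th_source`, `dose_response`, `exclusions`, `provenance`.
#' @export
run_pipeline <- function(traces, protocol, bg = NULL, cal = calibration_curve(),
                         df_th = NULL, dfmax_window_s = 20,
                         spont_window = c(10, 30), boot = 1000, seed = 1,
                         outdir = NULL) {
  if (inherits(traces, "hicr_cohort")) traces <- traces$traces
  roles <- split_roles(traces)
  if (length(roles$heated) == 0L) stop("pipeline: no heated cells found")
  if (is.null(bg)) bg <- estimate_backgrounds(roles$background)

  # -- thermometry ----------------------------------------------------------
  if (length(roles$sheet) == 0L) {
    stop("pipeline: no temperature-dye sheet traces (channel 'eutta')")
  }
  profile <- profile_from_sheet(roles$sheet, protocol, bg, cal)
  r_cells <- vapply(roles$heated, function(tr) tr$distance_um, numeric(1))
  if (any(!is.finite(r_cells))) {
    stop("pipeline: heated cells must carry distances to the heat source")
  }
  dT_cells <- assign_delta_T(profile, r_cells)

  # -- burst metrics --------------------------------------------------------
  exclusions <- data.frame(cell_id = character(0), reason = character(0))
  metrics <- list()
  for (i in seq_along(roles$heated)) {
    tr <- roles$heated[[i]]
    m <- tryCatch(dfmax(scatter_correct(tr, bg, protocol), protocol, bg,
                        window_s = dfmax_window_s),
                  error = function(e) e)
    if (inherits(m, "error")) {
      reason <- if (grepl("dead baseline", conditionMessage(m))) {
        "dead_baseline"
      } else if (grepl("window", conditionMessage(m))) {
        "incomplete_window"
      } else "metric_error"
      exclusions <- rbind(exclusions,
                          data.frame(cell_id = tr$cell_id, reason = reason))
      next
    }
    metrics[[tr$cell_id]] <- data.frame(cell_id = m$cell_id,
                                        channel = m$channel,
                                        dfmax = m$dfmax,
                                        t_peak_s = m$t_peak_s,
                                        deltaT_C = dT_cells[i])
  }
  if (length(metrics) == 0L) stop("pipeline: all heated cells were excluded")
  metrics <- do.call(rbind, c(metrics, list(make.row.names = FALSE)))

  # -- fluctuation threshold ------------------------------------------------
  fluct <- NULL
  spont_floor <- NULL
  if (is.null(df_th)) {
    if (length(roles$unheated) == 0L) {
      stop(paste("pipeline: no unheated cells for fluctuation modelling;",
                 "supply df_th explicitly"))
    }
    spont <- vapply(roles$unheated, function(tr) {
      spontaneous_dfmax(tr, bg, window = spont_window)
    }, numeric(1))
    fluct <- fit_fluctuation(spont)
    df_th <- threshold(fluct)
    df_th_source <- "fluctuation_fit"
    # observed response rate at dT = 0: spontaneous-response floor of the
    # dose-response model
    spont_floor <- mean(spont > df_th)
  } else {
    df_th_source <- "external"
  }

  # -- dose-response --------------------------------------------------------
  metrics$responder <- classify_responders(metrics$dfmax, df_th)
  dr <- fit_dose_response(metrics$deltaT_C, metrics$responder,
                          boot = boot, seed = seed, floor = spont_floor)

  report <- structure(
    list(metrics = metrics, profile = profile, fluctuation = fluct,
         df_th = df_th, df_th_source = df_th_source, dose_response = dr,
         exclusions = exclusions,
         provenance = list(seed = seed, n_heated = nrow(metrics),
                           n_unheated = length(roles$unheated),
                           n_excluded = nrow(exclusions),
                           boot = boot, method = dr$method,
                           T0 = protocol$T0,
                           package_version = as.character(utils::packageVersion("hicr")))),
    class = "hicr_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (fluctuation model, threshold, dT_th and CI, method
#' flag, provenance), `metrics.csv` (per-cell metrics) and `bins.csv`
#' (binned response curve). Byte-stable for identical inputs and seed.
#'
#' @param report A `hicr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hicr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dr <- report$dose_response
  js <- list(
    mu = if (is.null(report$fluctuation)) NA else report$fluctuation$mu,
    sigma = if (is.null(report$fluctuation)) NA else report$fluctuation$sigma,
    df_th = report$df_th,
    df_th_source = report$df_th_source,
    n_cells = nrow(report$metrics),
    n_bins = nrow(dr$curve),
    dtth = dr$dtth,
    ci_low = dr$ci_low,
    ci_high = dr$ci_high,
    method_flag = dr$method,
    provenance = report$provenance)
  paths <- list(report = file.path(dir, "report.json"),
                metrics = file.path(dir, "metrics.csv"),
                bins = file.path(dir, "bins.csv"))
  jsonlite::write_json(js, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(report$metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(as.data.frame(dr$curve), paths$bins, row.names = FALSE)
  invisible(paths)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' The file mirrors the constructor arguments: a `protocol` block
#' ([heat_protocol()] fields), optional `backgrounds` (`i_back`, `i_laser`),
#' optional `calibration` (named slopes), analysis windows, `boot`, `seed`,
#' and an optional `df_th`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of arguments suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  if (!is.null(raw$protocol)) out$protocol <- do.call(heat_protocol, raw$protocol)
  if (!is.null(raw$backgrounds)) {
    out$bg <- do.call(background_estimates, raw$backgrounds)
  }
  if (!is.null(raw$calibration)) {
    out$cal <- calibration_curve(unlist(raw$calibration))
  }
  for (f in c("df_th", "dfmax_window_s", "spont_window", "boot", "seed")) {
    if (!is.null(raw[[f]])) out[[f]] <- raw[[f]]
  }
  out
}

#' @export
print.hicr_report <- function(x, ...) {
  cat("Microheating analysis report\n")
  cat(sprintf("  %d heated cells analysed (%d excluded), %d unheated\n",
              x$provenance$n_heated, x$provenance$n_excluded,
              x$provenance$n_unheated))
  cat(sprintf("  dF_th = %.4g (%s)\n", x$df_th, x$df_th_source))
  print(x$dose_response)
  invisible(x)
}
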