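#' Write traces as tab-separated text
#'
#' One row per frame with columns `spot_id`, `frame` (0-based,
#' contiguous), `intensity`. Integer intensities round-trip
#' bit-identically through [read_traces()].
#'
#' @param traces List of `simpull_trace` (or a
#'   [simulate_population()] result).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  if (!is.null(traces$traces)) traces <- traces$traces
  rows <- lapply(traces, function(t)
    data.frame(spot_id = t$spot_id,
               frame = seq_along(t$intensities) - 1L,
               intensity = t$intensities))
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(spot_id = character(), frame = integer(),
                        intensity = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read traces from tab-separated text
#'
#' Expects a header with columns `spot_id`, `frame`, `intensity`.
#' Frames must be contiguous from 0 within each spot and all traces
#' must have the same length; violations raise a format error naming
#' the offending spot.
#'
#' @param path TSV path.
#' @param frame_interval Seconds per frame for the reconstructed
#'   traces.
#' @return List of `simpull_trace`, ordered by spot_id. An empty file
#'   (header only) returns an empty list with a warning.
#' @export
read_traces <- function(path, frame_interval = 0.1) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "frame", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("trace file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trace file: ", path)
    return(list())
  }
  by_spot <- split(df, df$spot_id)
  lens <- vapply(by_spot, nrow, 0L)
  if (length(unique(lens)) > 1L)
    stop_input("mixed trace lengths; first offender: spot_id '",
               names(by_spot)[which(lens != lens[1L])[1L]], "'")
  traces <- lapply(names(by_spot), function(id) {
    d <- by_spot[[id]]
    d <- d[order(d$frame), , drop = FALSE]
    if (!identical(as.integer(d$frame), seq_len(nrow(d)) - 1L))
      stop_input("non-contiguous frames for spot_id '", id, "'")
    new_trace(id, d$intensity, frame_interval)
  })
  traces[order(vapply(traces, function(t) t$spot_id, ""))]
}

#' Write / read a ground-truth sidecar table
#'
#' @param truth Data.frame of per-spot truth labels (as produced by
#'   [simulate_population()]).
#' @param path TSV path.
#' @return `write_truth`: invisibly, `path`. `read_truth`: the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  if (!is.null(truth$truth)) truth <- truth$truth
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.as_phys <- function(x) {
  if (inherits(x, "gfp_photophysics")) x
  else do.call(gfp_photophysics, as.list(x %||% list()))
}

.as_step_params <- function(x) {
  if (inherits(x, "step_fit_params")) x
  else do.call(step_fit_params, as.list(x %||% list()))
}

.as_correction <- function(x) {
  if (inherits(x, "correction_model")) x
  else do.call(correction_model, as.list(x %||% list()))
}

#' Run the full trace-to-report pipeline
#'
#' Executes, per condition: simulate (or read) traces, detect steps,
#' build the raw and GFP-corrected distributions, and summarize the
#' average step. Optional entries compute before/after dissolution
#' differences and condition comparisons. Results, tables and a run
#' manifest are written to `out_dir`; the tabular outputs are
#' byte-identical across reruns with the same configuration and seeds.
#'
#' @param config A configuration list or path to a YAML file with
#'   fields: `out_dir`; optional `photophysics`, `step_fit`,
#'   `correction` parameter blocks; `n_frames`; `conditions`, a list
#'   of entries each having `name` and either `simulate`
#'   (`probs` mapping size -> probability, `n_spots`, `seed`) or
#'   `traces` (path to a TSV); optional `differences`, a list of
#'   `(before, after)` condition-name pairs.
#' @return Invisibly, a list with per-condition results, the report
#'   tables, and the manifest.
#' @examples
#' \donttest{
#' cfg <- list(out_dir = tempfile("run"),
#'             conditions = list(list(name = "GFP", simulate = list(
#'               probs = list(`1` = 1.0), n_spots = 100, seed = 7))))
#' res <- run_pipeline(cfg)
#' res$tables$summary
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_input("config needs an out_dir")
  if (is.null(config$conditions) || !length(config$conditions))
    stop_input("config needs at least one condition")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  phys <- .as_phys(config$photophysics)
  sparams <- .as_step_params(config$step_fit)
  cmodel <- .as_correction(config$correction)
  n_frames <- config$n_frames %||% 1600

  stage <- "setup"
  results <- list()
  counts <- list()
  tryCatch({
    for (cond in config$conditions) {
      stage <- paste0("condition '", cond$name, "'")
      if (!is.null(cond$simulate)) {
        probs <- unlist(cond$simulate$probs)
        spec <- oligomer_spec(probs, n_spots = cond$simulate$n_spots %||% 300,
                              seed = cond$simulate$seed %||% 1)
        pop <- simulate_population(spec, phys, n_frames)
        traces <- pop$traces
      } else if (!is.null(cond$traces)) {
        traces <- read_traces(cond$traces)
      } else stop_input("condition '", cond$name,
                        "' needs 'simulate' or 'traces'")
      det <- batch_detect(traces, sparams)
      raw <- build_distribution(det, condition = cond$name)
      corrected <- correct_gfp_background(raw, cmodel)
      results[[cond$name]] <- list(
        detection = det, raw = raw, corrected = corrected,
        summary = average_step(corrected,
                               seed = config$bootstrap_seed %||% 1))
      counts[[cond$name]] <- det$summary
    }
    stage <- "differences"
    diffs <- list()
    for (dd in config$differences %||% list()) {
      key <- paste0(dd$after, "-", dd$before)
      diffs[[key]] <- dissolution_difference(results[[dd$before]]$raw,
                                             results[[dd$after]]$raw)
    }
    stage <- "report"
    tables <- write_report(results, diffs, config$out_dir)
    manifest <- .run_manifest(config, tables, counts, config$out_dir)
    invisible(list(results = results, differences = diffs,
                   tables = tables, manifest = manifest))
  }, simpullr_input_error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write report tables for analyzed conditions
#'
#' Emits `distributions.tsv` (condition, step, raw and corrected
#' frequency), `summary.tsv` (condition, average_step, sem, n_traces),
#' `differences.tsv`, and a plain-text `report.txt`. Empty results
#' produce header-only tables.
#'
#' @param results Named per-condition result list (see
#'   [run_pipeline()]).
#' @param diffs Named list of dissolution-difference tables.
#' @param out_dir Output directory.
#' @return The tables, invisibly (`distributions`, `summary`,
#'   `differences`).
#' @export
write_report <- function(results, diffs = list(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dist_tab <- data.frame(condition = character(), step = integer(),
                         raw_frequency = numeric(),
                         corrected_frequency = numeric())
  sum_tab <- data.frame(condition = character(), average_step = numeric(),
                        sem = numeric(), n_traces = integer())
  for (nm in names(results)) {
    r <- results[[nm]]
    k_max <- max(length(r$raw$frequencies), length(r$corrected$frequencies))
    pad <- function(f) c(f, numeric(k_max - length(f)))
    dist_tab <- rbind(dist_tab, data.frame(
      condition = nm, step = seq_len(k_max),
      raw_frequency = pad(r$raw$frequencies),
      corrected_frequency = pad(r$corrected$frequencies)))
    sum_tab <- rbind(sum_tab, r$summary)
  }
  diff_tab <- data.frame(comparison = character(), step = integer(),
                         before = numeric(), after = numeric(),
                         diff = numeric())
  for (nm in names(diffs))
    diff_tab <- rbind(diff_tab, cbind(comparison = nm, diffs[[nm]]))
  utils::write.table(dist_tab, file.path(out_dir, "distributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sum_tab, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(diff_tab, file.path(out_dir, "differences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- c("Photobleaching step analysis report", "",
           utils::capture.output(print(sum_tab, row.names = FALSE)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(list(distributions = dist_tab, summary = sum_tab,
                 differences = diff_tab))
}

.run_manifest <- function(config, tables, counts, out_dir) {
  files <- c("distributions.tsv", "summary.tsv", "differences.tsv")
  paths <- file.path(out_dir, files)
  manifest <- list(
    software = paste0("simpullr ",
                      as.character(utils::packageVersion("simpullr"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    outputs = lapply(stats::setNames(paths, files), function(p)
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}
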