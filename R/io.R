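## Delimited-text readers/writers for all package formats. Every file opens
## with '#'-prefixed JSON header lines carrying units and provenance;
## readers validate them.

header_lines <- function(meta) {
  paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) == 0L) {
    stop("missing '#' JSON header in ", path, call. = FALSE)
  }
  jsonlite::fromJSON(sub("^#\\s*", "", hdr[1]))
}

#' Write a trace recording to a TSV file
#'
#' Two columns (`time_s`, `current_pA`) with a JSON header line carrying
#' units, acquisition settings and the provenance hash. The truth path, if
#' present, is written to `<path>.truth.tsv`.
#'
#' @param trace A `trace_recording` with rendered current.
#' @param path Output file path.
#' @param write_truth Also write the companion truth file (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, write_truth = TRUE) {
  stopifnot(inherits(trace, "trace_recording"))
  if (is.null(trace$current)) stop("trace has no rendered current",
                                   call. = FALSE)
  acq <- trace$acquisition
  meta <- list(format = "kirsub_trace", units = list(time = "s",
                                                     current = "pA"),
               sample_rate = acq$sample_rate,
               filter_cutoff = acq$filter_cutoff, noise_sd = acq$noise_sd,
               voltage = acq$voltage, duration = acq$duration,
               seed = acq$seed, oversample = acq$oversample,
               hash = trace$provenance$hash, mode = trace$provenance$mode,
               level_currents = trace$level_currents)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(meta), con)
  writeLines("time_s\tcurrent_pA", con)
  t <- (seq_along(trace$current) - 1) / acq$sample_rate
  utils::write.table(data.frame(t, trace$current), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  if (write_truth && !is.null(trace$truth)) {
    tcon <- file(paste0(path, ".truth.tsv"), "w")
    writeLines(header_lines(list(format = "kirsub_truth",
                                 units = list(time = "s"),
                                 hash = trace$provenance$hash)), tcon)
    writeLines("t_start_s\tt_end_s\tlevel_id", tcon)
    utils::write.table(trace$truth, tcon, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    close(tcon)
  }
  invisible(path)
}

#' Read a trace recording written by [write_trace()]
#'
#' @param path Trace TSV path.
#' @param read_truth Read `<path>.truth.tsv` if it exists.
#' @return A `trace_recording`.
#' @export
read_trace <- function(path, read_truth = TRUE) {
  meta <- read_header(path)
  if (is.null(meta$units) || !identical(meta$units$current, "pA")) {
    stop("trace header lacks current units (pA) in ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  acq <- acquisition_spec(duration = meta$duration, seed = meta$seed,
                          sample_rate = meta$sample_rate,
                          filter_cutoff = meta$filter_cutoff,
                          noise_sd = meta$noise_sd, voltage = meta$voltage,
                          oversample = meta$oversample)
  truth <- NULL
  tpath <- paste0(path, ".truth.tsv")
  if (read_truth && file.exists(tpath)) {
    tt <- utils::read.table(tpath, header = TRUE, sep = "\t",
                            comment.char = "#")
    truth <- data.frame(t_start = tt[[1]], t_end = tt[[2]],
                        level = tt[[3]])
  }
  structure(list(current = tab$current_pA, acquisition = acq,
                 truth = truth,
                 level_currents = as.numeric(meta$level_currents),
                 provenance = list(hash = meta$hash, seed = meta$seed,
                                   mode = meta$mode)),
            class = "trace_recording")
}

#' Write idealized segments to a TSV file
#'
#' @param ideal An `idealized_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(ideal, path) {
  stopifnot(inherits(ideal, "idealized_trace"))
  amps <- ideal$levels$amplitudes
  segs <- ideal$segments
  meta <- list(format = "kirsub_segments",
               units = list(time = "s", current = "pA"),
               sample_rate = ideal$sample_rate,
               amplitudes = amps, sds = ideal$levels$sds,
               weights = ideal$levels$weights)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(meta), con)
  writeLines("t_start_s\tt_end_s\tlevel_id\tmean_pA", con)
  utils::write.table(data.frame(segs$t_start, segs$t_end, segs$level,
                                amps[segs$level + 1L]),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read idealized segments written by [write_segments()]
#'
#' @param path Segments TSV path.
#' @return An `idealized_trace`.
#' @export
read_segments <- function(path) {
  meta <- read_header(path)
  if (is.null(meta$units$time)) {
    stop("segments header lacks time units in ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  names(tab) <- c("t_start", "t_end", "level", "mean_pA")
  if (nrow(tab) > 1L &&
      any(tab$t_start[-1] < tab$t_end[-nrow(tab)] - 1e-12)) {
    stop("overlapping segment intervals in ", path, call. = FALSE)
  }
  fs <- meta$sample_rate
  segs <- data.frame(start = tab$t_start * fs, end = tab$t_end * fs,
                     level = tab$level, t_start = tab$t_start,
                     t_end = tab$t_end)
  lv <- level_set(as.numeric(meta$amplitudes), as.numeric(meta$sds),
                  as.numeric(meta$weights))
  structure(list(segments = segs, levels = lv, sample_rate = fs,
                 source = list(path = path)),
            class = "idealized_trace")
}

#' Write a pore trajectory to a directory of TSV tables
#'
#' Writes `ions.tsv`, `waters.tsv` (if present), `landmarks.tsv`,
#' `chain_distances.tsv` (if present) and `meta.json`.
#'
#' @param traj A [pore_trajectory()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_traj_tables <- function(traj, dir) {
  stopifnot(inherits(traj, "pore_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(traj$ions, "ions.tsv")
  if (!is.null(traj$waters)) wt(traj$waters, "waters.tsv")
  wt(traj$landmarks, "landmarks.tsv")
  if (!is.null(traj$chain_min_distances)) {
    wt(traj$chain_min_distances, "chain_distances.tsv")
  }
  meta <- list(format = "kirsub_traj", units = list(length = "Angstrom",
                                                    time = "ps"),
               box_length_z = traj$box_length_z)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  if (!is.null(traj$event_log)) wt(traj$event_log, "event_log.tsv")
  invisible(dir)
}

#' Read a pore trajectory from a directory written by [write_traj_tables()]
#'
#' @param dir Directory path.
#' @return A [pore_trajectory()].
#' @export
read_traj_tables <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (is.null(meta$box_length_z)) {
    stop("meta.json lacks box_length_z", call. = FALSE)
  }
  rt <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) utils::read.table(p, header = TRUE, sep = "\t")
    else NULL
  }
  ev <- rt("event_log.tsv")
  pore_trajectory(rt("ions.tsv"), rt("landmarks.tsv"),
                  waters = rt("waters.tsv"),
                  chain_min_distances = rt("chain_distances.tsv"),
                  box_length_z = meta$box_length_z,
                  event_log = ev)
}

#' Write an analysis report as JSON
#'
#' @param report Any list of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a protonation-model configuration from JSON
#'
#' Format: `{"site_classes":[{"n":4,"KH":2e-7,"g_weight":0.25}],
#' "KOC":0.05,"k_on":1e10,"k_close":3.7}`.
#'
#' @param path JSON file path.
#' @return A [protonation_model()].
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(cfg$site_classes)) {
    stop("model config lacks 'site_classes' in ", path, call. = FALSE)
  }
  sc <- cfg$site_classes
  classes <- lapply(seq_len(nrow(sc)), function(i) {
    site_class(sc$n[i], sc$KH[i], sc$g_weight[i])
  })
  protonation_model(classes,
                    K_OC = if (!is.null(cfg$KOC)) cfg$KOC else 0,
                    k_on = if (!is.null(cfg$k_on)) cfg$k_on else 1e10,
                    k_close = if (!is.null(cfg$k_close)) cfg$k_close else 0)
}

#' Write a protonation-model configuration to JSON
#'
#' @param model A [protonation_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "protonation_model"))
  cfg <- list(
    site_classes = data.frame(
      n = vapply(model$site_classes, `[[`, integer(1), "n_sites"),
      KH = vapply(model$site_classes, `[[`, numeric(1), "K_H"),
      g_weight = vapply(model$site_classes, `[[`, numeric(1), "g_weight")),
    KOC = model$K_OC, k_on = model$k_on, k_close = model$k_close)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
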