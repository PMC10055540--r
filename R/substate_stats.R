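#' Time-weighted level occupancies of an idealized trace
#'
#' @param ideal An `idealized_trace`.
#' @param conducting_only If `TRUE`, drop the closed level (0) and
#'   renormalize over conducting levels.
#' @return Named numeric vector of occupancy probabilities (names `"C"`,
#'   `"O1"`, ...), summing to 1.
#' @export
occupancies <- function(ideal, conducting_only = FALSE) {
  stopifnot(inherits(ideal, "idealized_trace"))
  segs <- ideal$segments
  if (nrow(segs) == 0L) stop("idealized trace has no segments", call. = FALSE)
  dur <- segs$t_end - segs$t_start
  lv <- segs$level
  if (conducting_only) {
    keep <- lv > 0
    dur <- dur[keep]; lv <- lv[keep]
    if (length(dur) == 0L) stop("no conducting segments", call. = FALSE)
  }
  levels_all <- sort(unique(lv))
  occ <- vapply(levels_all, function(l) sum(dur[lv == l]), numeric(1))
  occ <- occ / sum(occ)
  names(occ) <- ifelse(levels_all == 0, "C", paste0("O", levels_all))
  occ
}

#' Transition tally with adjacency classification
#'
#' Counts every boundary between consecutive segments and classifies
#' conducting-to-conducting transitions as adjacent (`|delta level| == 1`)
#' or non-adjacent; transitions to or from the closed level are tallied
#' separately ("C-coupled").
#'
#' @param ideal An `idealized_trace` with at least 2 segments.
#' @return List of class `transition_tally` with `counts` (matrix indexed by
#'   level label), and `adjacency_summary` (named counts: `adjacent`,
#'   `non_adjacent`, `closed_coupled`, `total`).
#' @export
transition_tally <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  lv <- ideal$segments$level
  if (length(lv) < 2L) stop("need at least 2 segments", call. = FALSE)
  from <- lv[-length(lv)]
  to <- lv[-1]
  labs <- sort(unique(lv))
  lab_names <- ifelse(labs == 0, "C", paste0("O", labs))
  counts <- matrix(0L, length(labs), length(labs),
                   dimnames = list(from = lab_names, to = lab_names))
  for (i in seq_along(from)) {
    a <- match(from[i], labs); b <- match(to[i], labs)
    counts[a, b] <- counts[a, b] + 1L
  }
  closed <- from == 0 | to == 0
  adj <- !closed & abs(from - to) == 1
  nonadj <- !closed & abs(from - to) > 1
  structure(list(counts = counts,
                 adjacency_summary = c(adjacent = sum(adj),
                                       non_adjacent = sum(nonadj),
                                       closed_coupled = sum(closed),
                                       total = length(from))),
            class = "transition_tally")
}

#' @export
print.transition_tally <- function(x, ...) {
  cat("transition_tally:\n")
  print(x$counts)
  print(x$adjacency_summary)
  invisible(x)
}

#' Intra-burst closure analysis
#'
#' Closed segments shorter than `burst_cutoff` are intra-burst closures;
#' closed segments at least as long terminate bursts and are excluded. With
#' `same_level_only`, only closures flanked by the same conducting level
#' (O_i -> C -> O_i) are retained for the dwell statistics. The closure
#' frequency is the number of retained events per second of conducting
#' (burst) time.
#'
#' @param ideal An `idealized_trace`.
#' @param burst_cutoff Burst closure cutoff, ms (default 100).
#' @param same_level_only Keep only O_i -> C -> O_i events (default `TRUE`).
#' @return List of class `closure_stats`: `frequency` (s^-1), `mean_dwell`
#'   (ms), `se_dwell` (ms), `n_events`, `selection_rule`. With no retained
#'   closures, `frequency` is 0 and the dwell fields are `NA` (flagged).
#' @export
closure_analysis <- function(ideal, burst_cutoff = 100,
                             same_level_only = TRUE) {
  stopifnot(inherits(ideal, "idealized_trace"))
  if (!is.numeric(burst_cutoff) || burst_cutoff <= 0) {
    stop("'burst_cutoff' must be > 0 (ms)", call. = FALSE)
  }
  segs <- ideal$segments
  dur_s <- segs$t_end - segs$t_start
  is_closed <- segs$level == 0
  dwell_ms <- dur_s * 1000
  intra <- is_closed & dwell_ms < burst_cutoff
  long_closed <- is_closed & !intra
  # burst time: conducting time excluding long closures (which are excluded
  # along with their flanks from nothing else -- conducting time stands)
  burst_time <- sum(dur_s[!is_closed])
  idx <- which(intra)
  if (same_level_only) {
    ok <- vapply(idx, function(i) {
      i > 1L && i < nrow(segs) &&
        segs$level[i - 1L] > 0 && segs$level[i + 1L] > 0 &&
        segs$level[i - 1L] == segs$level[i + 1L]
    }, logical(1))
    idx <- idx[ok]
  } else {
    idx <- idx[idx > 1L & idx < nrow(segs)]
  }
  n <- length(idx)
  dw <- dwell_ms[idx]
  structure(list(frequency = if (burst_time > 0) n / burst_time else 0,
                 mean_dwell = if (n > 0) mean(dw) else NA_real_,
                 se_dwell = if (n > 1) stats::sd(dw) / sqrt(n) else NA_real_,
                 n_events = n,
                 n_long_closures = sum(long_closed),
                 burst_time = burst_time,
                 selection_rule = if (same_level_only) "O_i->C->O_i"
                                  else "any flanks"),
            class = "closure_stats")
}

#' @export
print.closure_stats <- function(x, ...) {
  cat(sprintf("closure_stats (%s): %d events, frequency %.3g s^-1, dwell %.3g +/- %.2g ms\n",
              x$selection_rule, x$n_events, x$frequency, x$mean_dwell,
              x$se_dwell))
  invisible(x)
}

#' Compare two closed-dwell samples (unpaired t-test)
#'
#' Convenience wrapper to test whether mean intra-burst closed dwells differ
#' between two recordings (e.g. wild type vs mutant).
#'
#' @param dwells_a,dwells_b Numeric vectors of closed dwell times, ms.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_dwells <- function(dwells_a, dwells_b) {
  stats::t.test(dwells_a, dwells_b, paired = FALSE)
}

#' Per-level current-voltage fits
#'
#' Least-squares line through `(V, amplitude)` for each conducting level
#' across recordings at different voltages; slope in pS.
#'
#' @param ideals List of `idealized_trace` objects at different voltages.
#' @param voltages Numeric vector of membrane potentials, mV (one per
#'   element of `ideals`); defaults to the acquisition voltage stored with
#'   each trace source if present.
#' @param through_origin Force the regression through the origin
#'   (default `TRUE`; sub-state conductances scale linearly with voltage).
#' @return Data frame with one row per conducting level: `level`,
#'   `slope_pS`, `r_squared`, `n_points`.
#' @export
iv_per_level <- function(ideals, voltages, through_origin = TRUE) {
  if (length(ideals) < 2L) {
    stop("need idealized traces at >= 2 voltages", call. = FALSE)
  }
  if (length(voltages) != length(ideals)) {
    stop("'voltages' must match 'ideals' in length", call. = FALSE)
  }
  n_lev <- max(vapply(ideals, function(id) {
    length(id$levels$amplitudes) - 1L
  }, integer(1)))
  rows <- lapply(seq_len(n_lev), function(l) {
    amp <- vapply(seq_along(ideals), function(i) {
      a <- ideals[[i]]$levels$amplitudes
      if (length(a) - 1L >= l) a[l + 1L] - a[1L] else NA_real_
    }, numeric(1))
    # inward currents at negative potentials are recorded as magnitudes
    v <- abs(voltages) / 1000  # volts
    ok <- !is.na(amp)
    if (sum(ok) < 2L) {
      return(data.frame(level = l, slope_pS = NA_real_,
                        r_squared = NA_real_, n_points = sum(ok)))
    }
    fit <- if (through_origin) stats::lm(amp ~ 0 + v, subset = ok)
           else stats::lm(amp ~ v, subset = ok)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- if (through_origin) sum(amp[ok]^2) else
      sum((amp[ok] - mean(amp[ok]))^2)
    data.frame(level = l,
               slope_pS = unname(stats::coef(fit)[["v"]]),
               r_squared = 1 - ss_res / ss_tot,
               n_points = sum(ok))
  })
  do.call(rbind, rows)
}

#' Normalize conducting amplitudes to the fully open level
#'
#' @param levels A [level_set()] (or numeric vector of conducting
#'   amplitudes).
#' @return Numeric vector of relative amplitudes with maximum 1.
#' @export
normalize_amplitudes <- function(levels) {
  amps <- if (inherits(levels, "level_set")) {
    levels$amplitudes[-1] - levels$amplitudes[1]
  } else as.numeric(levels)
  if (length(amps) == 0L || max(amps) <= 0) {
    stop("no positive conducting amplitude to normalize by", call. = FALSE)
  }
  amps / max(amps)
}
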