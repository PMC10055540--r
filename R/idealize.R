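#' Fitted current-level set
#'
#' @param amplitudes Level amplitudes in pA, ascending; the first entry is
#'   the closed (zero-conductance) level.
#' @param sds Per-level emission SDs, pA (recycled if length 1).
#' @param weights Mixture proportions, summing to 1.
#' @return An object of class `level_set` with an additional
#'   `relative_amplitudes` field: conducting amplitudes relative to the
#'   largest, after subtracting the closed baseline.
#' @export
level_set <- function(amplitudes, sds, weights = NULL) {
  if (length(amplitudes) < 1L || any(diff(amplitudes) <= 0)) {
    stop("'amplitudes' must be strictly increasing", call. = FALSE)
  }
  sds <- rep_len(sds, length(amplitudes))
  if (is.null(weights)) weights <- rep(1 / length(amplitudes),
                                       length(amplitudes))
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("'weights' must be non-negative and sum to 1", call. = FALSE)
  }
  base <- amplitudes[1]
  conduct <- amplitudes[-1]
  rel <- if (length(conduct)) {
    (conduct - base) / (max(conduct) - base)
  } else numeric(0)
  structure(list(amplitudes = amplitudes, sds = sds, weights = weights,
                 relative_amplitudes = rel),
            class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat("level_set:", length(x$amplitudes) - 1, "conducting level(s) + closed\n")
  cat("  amplitudes (pA):", paste(sprintf("%.3f", x$amplitudes),
                                  collapse = ", "), "\n")
  if (length(x$relative_amplitudes)) {
    cat("  relative:", paste(sprintf("%.3f", x$relative_amplitudes),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' All-point amplitude histogram of a trace
#'
#' @param trace A `trace_recording` (or numeric vector of current, pA).
#' @param bin_width Bin width, pA (> 0).
#' @return List of class `allpoint_histogram` with `breaks`, `mids`,
#'   `counts`; counts sum to the number of samples.
#' @export
allpoint_histogram <- function(trace, bin_width) {
  x <- if (inherits(trace, "trace_recording")) trace$current else trace
  if (is.null(x) || length(x) == 0L) {
    stop("trace has no samples", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("'bin_width' must be > 0", call. = FALSE)
  }
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts),
            class = "allpoint_histogram")
}

## local maxima of a histogram after moving-average smoothing; returns a
## data.frame of peak positions and (smoothed) heights, tallest first
histogram_peaks <- function(h, smooth_bins = 5L) {
  y <- stats::filter(h$counts, rep(1 / smooth_bins, smooth_bins),
                     sides = 2)
  y[is.na(y)] <- 0
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3) {
    i <- which.max(y)
    return(data.frame(mid = h$mids[i], height = y[i]))
  }
  is_peak <- vapply(2:(n - 1), function(i) {
    y[i] > 0 && y[i] >= y[i - 1] && y[i] >= y[i + 1] &&
      (y[i] > y[i - 1] || y[i] > y[i + 1])
  }, logical(1))
  keep <- c(FALSE, is_peak, FALSE)
  out <- data.frame(mid = h$mids[keep], height = y[keep])
  out[order(-out$height), ]
}

## One EM run: 1-D Gaussian mixture, equal variances, component 1 mean fixed
## at `baseline`. Returns loglik, means, sigma, weights.
em_fixed_baseline <- function(x, k_free, baseline, init_means, max_iter = 100,
                              tol = 1e-7) {
  K <- k_free + 1L
  mu <- c(baseline, sort(init_means))
  sigma <- max(stats::sd(x) / K, 1e-6)
  w <- rep(1 / K, K)
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(j) {
      w[j] * stats::dnorm(x, mu[j], sigma)
    }, numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(list(loglik = -Inf))
    w <- nk / n
    for (j in 2:K) mu[j] <- sum(resp[, j] * x) / nk[j]
    sigma2 <- sum(resp * (x - matrix(mu, n, K, byrow = TRUE))^2) / n
    sigma <- sqrt(max(sigma2, 1e-12))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(loglik = ll, means = mu, sigma = sigma, weights = w)
}

#' Fit current levels to a trace by constrained Gaussian-mixture EM
#'
#' Fits, for each candidate number of conducting levels `k = 1..max_levels`,
#' a one-dimensional Gaussian mixture with `k` free components plus one
#' closed component pinned at the baseline (the lowest mode of the all-point
#' histogram), variances tied equal across components. The number of levels
#' is chosen by the Bayesian information criterion; ties break to the
#' smaller model, then the lowest restart index. EM restarts use
#' quantile-spaced initial means with deterministic jitter sub-seeded from
#' the trace seed.
#'
#' @param trace A `trace_recording`.
#' @param max_levels Maximum number of conducting levels to consider.
#' @param n_restarts EM restarts per candidate `k`.
#' @param max_points Cap on the number of samples used for the mixture fit;
#'   longer traces are thinned deterministically (every m-th sample). Path
#'   assignment ([assign_path()]) always uses the full trace.
#' @param min_weight Minimum mixture weight for a conducting component to
#'   count as a level; candidate fits containing a weaker component are
#'   rejected (such components absorb transition-ramp samples, not levels).
#' @return A [level_set()].
#' @export
fit_levels <- function(trace, max_levels = 6L, n_restarts = 5L,
                       max_points = 5e4, min_weight = 0.005) {
  stopifnot(inherits(trace, "trace_recording"))
  x_full <- trace$current
  if (is.null(x_full) || length(x_full) < 2L) {
    stop("trace has no rendered current", call. = FALSE)
  }
  # degenerate (noise-free) traces: the distinct values are the levels
  ux <- sort(unique(round(x_full, 10)))
  if (length(ux) <= max_levels + 1L) {
    w <- as.numeric(table(factor(round(x_full, 10), levels = ux)))
    w <- w / sum(w)
    if (ux[1] > 0) {  # no closed sojourn observed; prepend a zero baseline
      ux <- c(0, ux); w <- c(0, w); w <- w / sum(w)
    }
    return(level_set(ux, sds = 1e-6, weights = w))
  }
  step <- max(1L, ceiling(length(x_full) / max_points))
  x <- x_full[seq(1L, length(x_full), by = step)]

  h <- allpoint_histogram(x, bin_width = diff(range(x)) / 200)
  peaks <- histogram_peaks(h)
  # discard insignificant bumps in the noise tails before reading off the
  # closed (lowest) mode and level candidates
  peaks <- peaks[peaks$height >= 0.01 * max(peaks$height), , drop = FALSE]
  baseline_mode <- min(peaks$mid)
  bw <- diff(h$breaks[1:2])
  near <- abs(x - baseline_mode) <= 2 * bw
  baseline <- if (any(near)) stats::median(x[near]) else baseline_mode
  # conducting-level candidates from the amplitude histogram, tallest first
  pk_cand <- peaks$mid[abs(peaks$mid - baseline) > 4 * bw]

  seed0 <- if (!is.null(trace$provenance$seed)) trace$provenance$seed else 0L
  best <- NULL
  best_bic <- Inf
  for (k in seq_len(max_levels)) {
    qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    pk_init <- if (length(pk_cand)) {
      ini <- utils::head(pk_cand, k)
      if (length(ini) < k) ini <- c(ini, utils::tail(qs, k - length(ini)))
      sort(ini)
    }
    span <- diff(range(x))
    for (r in seq_len(n_restarts)) {
      set.seed(derive_seed(seed0, paste0("fit_levels_k", k, "_r", r)))
      init <- if (r == 1L) qs
              else if (r == 2L && !is.null(pk_init)) pk_init
              else qs + stats::rnorm(k, 0, 0.05 * span)
      fit <- em_fixed_baseline(x, k, baseline, init)
      if (!is.finite(fit$loglik)) next
      # a conducting component must carry real occupancy to count as a
      # level; vanishing-weight components fit transition-ramp samples
      if (any(fit$weights[-1] < min_weight)) next
      p <- 2 * k + 1  # k free means, common sigma, k free weights
      bic <- -2 * fit$loglik + p * log(length(x))
      if (bic < best_bic - 1e-9) {
        best_bic <- bic
        best <- fit
        best$k <- k
      }
    }
  }
  if (is.null(best)) {
    stop("level fitting failed to converge in all restarts; ",
         "inspect the trace amplitude histogram", call. = FALSE)
  }
  merged <- merge_close_components(best$means, best$weights, best$sigma,
                                   baseline)
  level_set(merged$means, sds = best$sigma, weights = merged$weights)
}

## Components whose means are indistinguishable (gap < mult * sigma) are
## duplicates of one level: merge them (weight-summed, weighted-mean
## position; the pinned baseline keeps its position).
merge_close_components <- function(means, weights, sigma, baseline,
                                   mult = 0.5) {
  ord <- order(means)
  mu <- means[ord]; w <- weights[ord]
  pinned <- which.min(abs(mu - baseline))
  repeat {
    if (length(mu) == 1L) break
    gaps <- diff(mu)
    if (all(gaps >= mult * sigma)) break
    i <- which.min(gaps)
    new_mu <- if (pinned %in% c(i, i + 1L)) baseline else
      (mu[i] * w[i] + mu[i + 1L] * w[i + 1L]) / (w[i] + w[i + 1L])
    mu <- c(mu[seq_len(i - 1L)], new_mu, mu[-seq_len(i + 1L)])
    w <- c(w[seq_len(i - 1L)], w[i] + w[i + 1L], w[-seq_len(i + 1L)])
    if (pinned > i + 1L) pinned <- pinned - 1L
    else if (pinned == i + 1L) pinned <- i
  }
  list(means = mu, weights = w)
}

#' Assign every sample of a trace to a level (idealization)
#'
#' Computes the most probable state path under a hidden-Markov observation
#' model: Gaussian emissions at the fitted level amplitudes with a common SD,
#' uniform off-diagonal transition probability `p_switch` per sample.
#' Segments shorter than `min_dwell_samples` are merged into the flanking
#' segment with the closer amplitude (apparent one-or-two-sample levels are
#' unresolved transitions at these acquisition settings).
#'
#' @param trace A `trace_recording`.
#' @param levels A [level_set()] (fitted or supplied).
#' @param p_switch Per-sample switching probability (default 1e-3).
#' @param min_dwell_samples Minimum retained segment length in samples.
#' @return An object of class `idealized_trace`: `segments` is a data frame
#'   with half-open sample intervals `start`, `end` (0-based), times
#'   `t_start`, `t_end` (s), and `level` (0 = closed; conducting levels
#'   numbered from 1 in ascending amplitude).
#' @export
assign_path <- function(trace, levels, p_switch = 1e-3,
                        min_dwell_samples = 2L) {
  stopifnot(inherits(trace, "trace_recording"), inherits(levels, "level_set"))
  x <- trace$current
  if (is.null(x)) stop("trace has no rendered current", call. = FALSE)
  mu <- levels$amplitudes
  sd_em <- max(mean(levels$sds), 1e-9)
  if (length(mu) > 1 && any(diff(mu) < sd_em)) {
    warning("some levels overlap within one SD; idealization may be unstable")
  }
  w <- pmax(levels$weights, 1e-12)
  path <- cpp_viterbi_gaussian(x, mu, sd_em, p_switch, log(w / sum(w)))
  segs <- path_to_segments(path, mu, min_dwell_samples)
  fs <- trace$acquisition$sample_rate
  segs$t_start <- segs$start / fs
  segs$t_end <- segs$end / fs
  structure(list(segments = segs, levels = levels,
                 sample_rate = fs,
                 source = trace$provenance),
            class = "idealized_trace")
}

## run-length segments from a per-sample state path (1-based states ->
## level = state - 1), with short-segment merging
path_to_segments <- function(path, mu, min_dwell_samples) {
  r <- rle(path)
  vals <- r$values
  lens <- r$lengths
  # merge short segments into the flanking run with closer amplitude
  repeat {
    short <- which(lens < min_dwell_samples)
    if (length(short) == 0L || length(vals) == 1L) break
    i <- short[which.min(lens[short])]
    left <- if (i > 1L) abs(mu[vals[i - 1L]] - mu[vals[i]]) else Inf
    right <- if (i < length(vals)) abs(mu[vals[i + 1L]] - mu[vals[i]]) else Inf
    j <- if (left <= right) i - 1L else i + 1L
    vals[i] <- vals[j]
    # re-run-length-encode
    keep <- c(TRUE, diff(vals) != 0)
    grp <- cumsum(keep)
    lens <- as.numeric(tapply(lens, grp, sum))
    vals <- vals[keep]
  }
  ends <- cumsum(lens)
  starts <- c(0, ends[-length(ends)])
  data.frame(start = starts, end = ends, level = vals - 1L)
}

#' Idealized trace from a generator ground-truth path
#'
#' Converts the exact simulated state path of a `trace_recording` into an
#' `idealized_trace` with continuous-time segments, for computing reference
#' statistics free of idealization error.
#'
#' @param trace A `trace_recording` with a `truth` path.
#' @return An `idealized_trace` (sample indices are the times scaled by the
#'   sampling rate; segment times are exact event times).
#' @export
truth_to_ideal <- function(trace) {
  stopifnot(inherits(trace, "trace_recording"))
  if (is.null(trace$truth)) stop("trace carries no truth path", call. = FALSE)
  segs <- trace$truth
  fs <- trace$acquisition$sample_rate
  amps <- c(0, trace$level_currents)
  # distinct truth levels may share an amplitude (e.g. a zero-conductance
  # conducting state); nudge so the level_set stays strictly ordered
  if (any(diff(amps) <= 0)) amps <- amps + (seq_along(amps) - 1) * 1e-9
  dur <- segs$t_end - segs$t_start
  w <- as.numeric(tapply(dur, factor(segs$level, levels = 0:(length(amps) - 1L)),
                         sum))
  w[is.na(w)] <- 0
  out <- data.frame(start = segs$t_start * fs, end = segs$t_end * fs,
                    level = segs$level,
                    t_start = segs$t_start, t_end = segs$t_end)
  structure(list(segments = out,
                 levels = level_set(amps, sds = 1e-6, weights = w / sum(w)),
                 sample_rate = fs,
                 source = trace$provenance),
            class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("idealized_trace: %d segments, %d level(s) + closed, %.6g s\n",
              nrow(x$segments), length(x$levels$amplitudes) - 1L,
              max(x$segments$t_end)))
  invisible(x)
}
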