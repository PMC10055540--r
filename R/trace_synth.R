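#' Acquisition settings for synthetic single-channel recordings
#'
#' Mirrors a patch-clamp acquisition chain: additive Gaussian instrument
#' noise, a 4-pole low-pass Bessel filter, and decimation to the digitizer
#' rate. Defaults emulate acquisition at 3 kHz with a 1 kHz low-pass filter
#' at -120 mV membrane potential.
#'
#' @param duration Recording length, seconds (> 0).
#' @param seed Integer RNG seed.
#' @param sample_rate Digitizer rate, Hz (must exceed `2 * filter_cutoff`).
#' @param filter_cutoff -3 dB frequency of the low-pass filter, Hz.
#' @param noise_sd SD of the white instrument noise before filtering, pA
#'   (default 0.72 pA = 10% of the 7.2 pA full amplitude of a 60 pS channel
#'   at -120 mV).
#' @param voltage Membrane potential, mV.
#' @param oversample Internal simulation grid factor (>= 10 recommended);
#'   the ideal trace is rendered at `oversample * sample_rate` before
#'   filtering so sub-sample flicker is smoothed as in real acquisition.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(duration, seed = 1L, sample_rate = 3000,
                             filter_cutoff = 1000, noise_sd = 0.72,
                             voltage = -120, oversample = 10L) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("'duration' must be a positive number of seconds", call. = FALSE)
  }
  if (sample_rate <= 2 * filter_cutoff) {
    stop("'sample_rate' must exceed 2 * filter_cutoff", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (oversample < 2) stop("'oversample' must be >= 2", call. = FALSE)
  structure(list(duration = duration, seed = as.integer(seed),
                 sample_rate = sample_rate, filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, voltage = voltage,
                 oversample = as.integer(oversample)),
            class = "acquisition_spec")
}

#' Empirical sub-state level specification
#'
#' Describes conducting levels directly by their relative amplitudes and
#' target occupancies, for the semi-Markov trace generator
#' [simulate_empirical()].
#'
#' @param relative_amplitudes Strictly increasing amplitudes in `(0, 1]`,
#'   maximum exactly 1 (the fully open level).
#' @param occupancies Target stationary probabilities of the conducting
#'   levels; must sum to 1 within 1e-9.
#' @param full_conductance Full single-channel conductance, pS.
#' @param closure_rate Intra-burst flicker closure rate, per second of
#'   conducting time.
#' @param closed_dwell_mean Mean flicker closed dwell, ms.
#' @param exchange_rate Total adjacent level-exchange intensity, s^-1; sets
#'   the sub-state dwell time scale (default 100 s^-1, i.e. dwells of the
#'   order of 10 ms).
#' @return An object of class `empirical_level_spec`.
#' @export
empirical_level_spec <- function(relative_amplitudes, occupancies,
                                 full_conductance = 60, closure_rate = 3.7,
                                 closed_dwell_mean = 6.4,
                                 exchange_rate = 100) {
  if (length(relative_amplitudes) < 1L ||
      any(diff(relative_amplitudes) <= 0) ||
      abs(max(relative_amplitudes) - 1) > 1e-12 ||
      any(relative_amplitudes <= 0)) {
    stop("'relative_amplitudes' must be strictly increasing in (0, 1] with max 1",
         call. = FALSE)
  }
  if (length(occupancies) != length(relative_amplitudes)) {
    stop("'occupancies' must match 'relative_amplitudes' in length",
         call. = FALSE)
  }
  if (abs(sum(occupancies) - 1) > 1e-9 || any(occupancies < 0)) {
    stop("'occupancies' must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  if (closure_rate < 0 || closed_dwell_mean < 0 || exchange_rate < 0) {
    stop("rate/dwell parameters must be >= 0", call. = FALSE)
  }
  structure(list(relative_amplitudes = relative_amplitudes,
                 occupancies = occupancies,
                 full_conductance = full_conductance,
                 closure_rate = closure_rate,
                 closed_dwell_mean = closed_dwell_mean,
                 exchange_rate = exchange_rate),
            class = "empirical_level_spec")
}

## FNV-1a hash of the serialized object, as 8 hex digits; used for
## provenance stamps on generated data.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' Stable integer hashing so each pipeline stage gets its own stream while
#' remaining fully determined by the root seed.
#'
#' @param seed Root integer seed.
#' @param label Character stage label.
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Design a digital 4-pole low-pass Bessel filter
#'
#' Poles of the 4th-order Bessel polynomial are computed, frequency-scaled so
#' the analog prototype is -3 dB at the cutoff, and mapped to the z-domain by
#' the bilinear transform with prewarping at the cutoff (so the digital filter
#' is -3 dB at `cutoff` exactly). DC gain is normalized to 1.
#'
#' @param cutoff -3 dB frequency, Hz.
#' @param fs Sampling rate, Hz (`cutoff < fs / 2`).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
bessel_lowpass <- function(cutoff, fs) {
  if (cutoff >= fs / 2) {
    stop("filter cutoff must be below the Nyquist frequency of the grid",
         call. = FALSE)
  }
  # delay-normalized 4th-order Bessel polynomial s^4+10s^3+45s^2+105s+105
  p_raw <- polyroot(c(105, 105, 45, 10, 1))
  gain_raw <- abs(prod(-p_raw))
  # locate the -3 dB frequency of the prototype, then normalize
  mag2 <- function(w) (gain_raw^2 / abs(prod(1i * w - p_raw))^2) - 0.5
  w3 <- stats::uniroot(mag2, c(0.1, 10), tol = 1e-12)$root
  p0 <- p_raw / w3
  # prewarped analog cutoff
  wa <- 2 * fs * tan(pi * cutoff / fs)
  p <- p0 * wa
  k <- Re(prod(-p))
  # bilinear transform: s = 2*fs*(z-1)/(z+1)
  g <- 2 * fs
  b <- k * c(1, 4, 6, 4, 1)  # k * (z+1)^4
  a <- 1
  for (pi_ in p) a <- convolve_poly(a, c(g - pi_, -(g + pi_)))
  a <- Re(a)
  b <- b / a[1]
  a <- a / a[1]
  b <- b * sum(a) / sum(b)  # exact unity DC gain
  list(b = b, a = a)
}

convolve_poly <- function(x, y) {
  n <- length(x) + length(y) - 1L
  out <- complex(n)
  for (i in seq_along(x)) {
    idx <- i:(i + length(y) - 1L)
    out[idx] <- out[idx] + x[i] * y
  }
  out
}

#' Render an ideal piecewise-constant current path as an acquired trace
#'
#' The ideal path is discretized on a fine internal grid
#' (`oversample * sample_rate`), white Gaussian noise of SD `noise_sd` is
#' added, the result is low-pass filtered with a causal 4-pole Bessel filter
#' at `filter_cutoff`, and decimated to `sample_rate`.
#'
#' @param path Data frame with columns `t_start`, `t_end` (seconds) and
#'   `current` (pA), tiling `[0, duration]`.
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of sampled current, length
#'   `round(duration * sample_rate)`.
#' @export
render <- function(path, acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  fs_int <- acq$oversample * acq$sample_rate
  n_int <- round(acq$duration * fs_int)
  n_out <- round(acq$duration * acq$sample_rate)
  t_int <- (seq_len(n_int) - 1) / fs_int
  seg <- findInterval(t_int, path$t_start)
  seg[seg < 1L] <- 1L
  x <- path$current[seg]
  if (acq$noise_sd > 0) x <- x + stats::rnorm(n_int, 0, acq$noise_sd)
  coefs <- bessel_lowpass(acq$filter_cutoff, fs_int)
  # pad with the initial value so the causal filter starts near steady state
  # instead of ramping up from zero
  n_pad <- ceiling(5 * fs_int / acq$filter_cutoff)
  x <- as.numeric(signal::filter(coefs$b, coefs$a,
                                 c(rep(x[1], n_pad), x)))[-seq_len(n_pad)]
  x[seq(1L, by = acq$oversample, length.out = n_out)]
}

make_trace <- function(current, acq, truth, level_currents, config,
                       mode) {
  structure(list(current = current, acquisition = acq, truth = truth,
                 level_currents = level_currents,
                 provenance = list(hash = config_hash(list(config, acq)),
                                   seed = acq$seed, mode = mode)),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("trace_recording: %.6g s at %g Hz (%d samples), noise_sd %.3g pA\n",
              x$acquisition$duration, x$acquisition$sample_rate,
              length(x$current), x$acquisition$noise_sd))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth path: %d segments over levels {%s}\n",
                nrow(x$truth),
                paste(sort(unique(x$truth$level)), collapse = ", ")))
  }
  invisible(x)
}

## convert event times/levels into a segment table tiling [0, duration]
events_to_segments <- function(times, levels, duration) {
  keep <- c(TRUE, diff(levels) != 0)  # merge repeats defensively
  times <- times[keep]; levels <- levels[keep]
  data.frame(t_start = times,
             t_end = c(times[-1], duration),
             level = levels)
}

truth_currents <- function(truth, level_currents) {
  cur <- numeric(nrow(truth))
  open <- truth$level > 0
  cur[open] <- level_currents[truth$level[open]]
  data.frame(t_start = truth$t_start, t_end = truth$t_end, current = cur)
}

#' Simulate a single-channel recording in empirical mode
#'
#' Semi-Markov birth-death walk over the conducting levels of `spec`, with
#' adjacent-only transitions whose embedded chain satisfies detailed balance
#' against the target occupancies, exponential dwells, and flicker closures
#' inserted as a Poisson process (rate `closure_rate` per second of
#' conducting time, exponential closed dwells) that always return to the
#' pre-closure level. The exact state path is recorded before rendering.
#'
#' @param spec An [empirical_level_spec()].
#' @param acq An [acquisition_spec()].
#' @param render_trace If `FALSE`, skip noise/filter rendering (truth path
#'   only; `current` is `NULL`). Useful for long dwell-statistics runs.
#' @return A `trace_recording` with fields `current` (pA), `acquisition`,
#'   `truth` (data frame `t_start`, `t_end`, `level`; level 0 = closed,
#'   conducting levels numbered from 1 in ascending amplitude) and
#'   `level_currents` (pA per conducting level).
#' @export
simulate_empirical <- function(spec, acq, render_trace = TRUE) {
  stopifnot(inherits(spec, "empirical_level_spec"),
            inherits(acq, "acquisition_spec"))
  occ <- spec$occupancies
  kept <- which(occ > 0)
  if (length(kept) < length(occ)) {
    warning("levels with zero occupancy are excluded from the simulation")
  }
  full_amp <- spec$full_conductance * abs(acq$voltage) / 1000  # pA
  level_currents <- spec$relative_amplitudes * full_amp
  set.seed(acq$seed)
  # start from the most likely level (deterministic, burn-in free enough for
  # the long traces this generator is used for)
  start <- which.max(occ[kept])
  max_events <- as.integer(min(2e8, 20 * acq$duration *
    (spec$exchange_rate + spec$closure_rate) + 1000))
  sim <- cpp_sim_empirical(occ[kept], spec$exchange_rate, spec$closure_rate,
                           spec$closed_dwell_mean / 1000, acq$duration,
                           start, max_events)
  lev <- sim$level
  lev[lev > 0L] <- kept[lev[lev > 0L]]
  truth <- events_to_segments(sim$time, lev, acq$duration)
  current <- NULL
  if (render_trace) {
    current <- render(truth_currents(truth, level_currents), acq)
  }
  make_trace(current, acq, truth, level_currents, spec, "empirical")
}

#' Simulate a single-channel recording from the protonation model
#'
#' Exact-event (Gillespie) continuous-time Markov simulation of per-site
#' protonation/deprotonation plus the flicker gate, using the rates of
#' [kinetic_rates()]; the ideal current is
#' `full amplitude x level conductance x open indicator`, then rendered
#' through the acquisition chain. The exact state path is recorded before
#' noise.
#'
#' @param model A [protonation_model()].
#' @param pH pH of the simulated bath.
#' @param acq An [acquisition_spec()].
#' @param full_amplitude Full-open current amplitude, pA (default from a
#'   60 pS conductance at the acquisition voltage).
#' @param render_trace If `FALSE`, return the truth path only.
#' @return A `trace_recording`; truth levels are 0 (flicker closed) or the
#'   model's conducting level indices (1 = most protonated / lowest
#'   conductance).
#' @export
simulate_mechanistic <- function(model, pH, acq,
                                 full_amplitude = 60 * abs(acq$voltage) / 1000,
                                 render_trace = TRUE) {
  stopifnot(inherits(model, "protonation_model"),
            inherits(acq, "acquisition_spec"))
  rates <- kinetic_rates(model, pH)  # validates kinetics
  ns <- vapply(model$site_classes, `[[`, integer(1), "n_sites")
  h <- proton_concentration(pH)
  r_on <- rep(model$k_on * h, length(ns))
  r_off <- model$k_on * vapply(model$site_classes, `[[`, numeric(1), "K_H")
  k_open <- if (model$k_close > 0) model$k_close / model$K_OC else 0
  if (all(ns * (r_on + r_off) == 0) && model$k_close == 0) {
    warning("all rates are zero; returning a constant full-open trace")
  }
  set.seed(acq$seed)
  max_events <- as.integer(min(2e8, 20 * acq$duration *
    (sum(ns * pmax(r_on, r_off)) + model$k_close + k_open) + 1000))
  sim <- cpp_gillespie_protonation(ns, r_on, r_off, model$k_close, k_open,
                                   acq$duration, max_events)
  lt <- level_table(model)
  level_of_combo <- lt$group_of_combo  # combo index (0-based) + 1 -> level
  lev <- ifelse(sim$gate == 1L, level_of_combo[sim$combo + 1L], 0L)
  truth <- events_to_segments(sim$time, lev, acq$duration)
  level_currents <- full_amplitude * lt$levels$conductance
  current <- NULL
  if (render_trace) {
    current <- render(truth_currents(truth, level_currents), acq)
  }
  make_trace(current, acq, truth, level_currents,
             list(model = model, pH = pH), "mechanistic")
}

#' Packaged fixture configurations
#'
#' Named generator configurations emulating the study conditions of the
#' forced-open Kir2 recordings: four sub-conductance levels with relative
#' amplitudes 0.45/0.74/0.92/1.00 and a ~60 pS full conductance for
#' Kir2.2\[G178D\], flicker closures at 3.7 s^-1 with 6.4 ms mean dwells
#' (5.9 s^-1 / 7.1 ms for wild type), and pH-dependent level occupancies.
#' At pH 7.4 the occupancies are the measured values renormalized over
#' conducting levels; at other pH they follow the fitted two-parameter
#' protonation model (K_H = 2e-7 M, K_OC = 0.05, top two model levels
#' merged).
#'
#' @param name One of `"kir22_g178d_ph62"`, `"kir22_g178d_ph68"`,
#'   `"kir22_g178d_ph74"`, `"kir22_g178d_ph80"`, `"kir22_wt_ph74"`,
#'   `"kir21_g177e_ph74"`, `"dimer_gE"`, `"dimer_ngnE"`.
#' @return A list with elements `spec` (an [empirical_level_spec()]), `pH`,
#'   and `label`.
#' @export
fixture_spec <- function(name) {
  g178d_amps <- c(0.45, 0.74, 0.92, 1.00)
  model <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
  model_occ <- function(ph) {
    d <- merge_top_levels(stationary_distribution(model, ph), 2)
    p <- unname(d$level_probs)
    p / sum(p)
  }
  cfg <- switch(name,
    kir22_g178d_ph74 = list(
      spec = empirical_level_spec(g178d_amps,
                                  c(0.02, 0.07, 0.26, 0.59) / 0.94,
                                  full_conductance = 60,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 7.4),
    kir22_g178d_ph62 = list(
      spec = empirical_level_spec(g178d_amps, model_occ(6.2),
                                  full_conductance = 60,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 6.2),
    kir22_g178d_ph68 = list(
      spec = empirical_level_spec(g178d_amps, model_occ(6.8),
                                  full_conductance = 60,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 6.8),
    kir22_g178d_ph80 = list(
      spec = empirical_level_spec(g178d_amps, model_occ(8.0),
                                  full_conductance = 60,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 8.0),
    kir22_wt_ph74 = list(
      spec = empirical_level_spec(1.0, 1.0, full_conductance = 46,
                                  closure_rate = 5.9,
                                  closed_dwell_mean = 7.1),
      pH = 7.4),
    kir21_g177e_ph74 = list(
      spec = empirical_level_spec(g178d_amps, model_occ(7.4),
                                  full_conductance = 50,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 7.4),
    dimer_gE = list(
      # two introduced glutamates plus the four native rectification
      # controller aspartates; four resolvable levels (synthetic amplitudes)
      spec = empirical_level_spec(c(0.5, 0.75, 0.9, 1.0), model_occ(7.4),
                                  full_conductance = 48,
                                  closure_rate = 3.7,
                                  closed_dwell_mean = 6.4),
      pH = 7.4),
    dimer_ngnE = list(
      # only two titratable sites -> three conducting levels (synthetic
      # amplitudes); occupancies from a two-site model
      spec = {
        m2 <- protonation_model(site_class(2, 2e-7, 0.5), K_OC = 0.05)
        d <- stationary_distribution(m2, 7.4)
        p <- unname(d$level_probs); p <- p / sum(p)
        empirical_level_spec(c(0.5, 0.8, 1.0), p, full_conductance = 47,
                             closure_rate = 3.7, closed_dwell_mean = 6.4)
      },
      pH = 7.4),
    stop("unknown fixture: ", name)
  )
  cfg$label <- name
  cfg
}
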