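#' Kir2.2\[G178D\]-like generator spec at a given pH
#'
#' At pH 7.4 the occupancies are the measured values (renormalized over
#' conducting levels); elsewhere they follow the fitted two-parameter
#' protonation model (K_H = 2e-7 M, K_OC = 0.05, top two levels merged).
#' Amplitudes are pH-independent.
#'
#' @param pH Bath pH.
#' @return An [empirical_level_spec()].
#' @export
g178d_spec_at_ph <- function(pH) {
  if (abs(pH - 7.4) < 1e-9) return(fixture_spec("kir22_g178d_ph74")$spec)
  model <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
  d <- merge_top_levels(stationary_distribution(model, pH), 2)
  p <- unname(d$level_probs)
  empirical_level_spec(c(0.45, 0.74, 0.92, 1.00), p / sum(p),
                       full_conductance = 60, closure_rate = 3.7,
                       closed_dwell_mean = 6.4)
}

## map conducting level ids of each idealization onto canonical levels by
## clustering the pooled relative amplitudes (which are pH-independent);
## amplitudes within `tol` of each other are one level
align_levels <- function(level_sets, tol = 0.04, max_canonical = Inf) {
  amps <- sort(unique(unlist(lapply(level_sets, function(l) {
    l$relative_amplitudes
  }))))
  grp <- cumsum(c(1, as.integer(diff(amps) > tol)))
  centers <- as.numeric(tapply(amps, grp, mean))
  # cap the canonical level count by merging the closest centers
  while (length(centers) > max_canonical) {
    i <- which.min(diff(centers))
    centers <- c(centers[seq_len(i - 1L)],
                 mean(centers[i:(i + 1L)]),
                 centers[-seq_len(i + 1L)])
  }
  lapply(level_sets, function(l) {
    vapply(l$relative_amplitudes, function(a) {
      which.min(abs(centers - a))
    }, integer(1))
  })
}

#' Run the full analysis chain on synthetic recordings
#'
#' Simulates one recording per pH, idealizes each (level fitting + Viterbi
#' path), computes occupancies with levels aligned across pH by their
#' pH-independent relative amplitudes, assembles a titration dataset and
#' fits the two-parameter protonation model. Fully deterministic for a given
#' root seed (per-stage sub-seeds are derived by stable hashing).
#'
#' @param pH_values pH set (default the buffer series 6.2, 6.5, 6.8, 7.1,
#'   7.4, 7.7, 8.0, 8.6).
#' @param duration Seconds of recording simulated per pH.
#' @param seed Root integer seed.
#' @param spec_for_ph Function pH -> [empirical_level_spec()] (default
#'   [g178d_spec_at_ph()]).
#' @param model_template [protonation_model()] used for the titration fit.
#' @param max_levels Maximum conducting levels for [fit_levels()].
#' @param out_dir Optional directory; when given, traces, segments and a
#'   JSON report bundle are written there.
#' @return List of class `pipeline_bundle`: `reports` (per-pH occupancies),
#'   `level_sets`, `dataset`, `fit` (a `titration_fit`, or `NULL` with a
#'   flag when only one conducting level is resolved), `residuals`,
#'   `provenance`.
#' @export
run_pipeline <- function(pH_values = c(6.2, 6.5, 6.8, 7.1, 7.4, 7.7, 8.0, 8.6),
                         duration = 30, seed = 1L,
                         spec_for_ph = g178d_spec_at_ph,
                         model_template =
                           protonation_model(site_class(4, 2e-7, 0.25),
                                             K_OC = 0.05),
                         max_levels = 6L, out_dir = NULL) {
  if (length(pH_values) < 2L) stop("need >= 2 pH values", call. = FALSE)
  specs <- lapply(pH_values, spec_for_ph)
  ideals <- vector("list", length(pH_values))
  level_sets <- vector("list", length(pH_values))
  for (i in seq_along(pH_values)) {
    ph <- pH_values[i]
    acq <- acquisition_spec(duration,
                            seed = derive_seed(seed,
                                               paste0("simulate_ph", ph)))
    trace <- simulate_empirical(specs[[i]], acq)
    levels <- fit_levels(trace, max_levels = max_levels)
    ideals[[i]] <- assign_path(trace, levels)
    level_sets[[i]] <- levels
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trace(trace, file.path(out_dir, sprintf("trace_ph%g.tsv", ph)))
      write_segments(ideals[[i]],
                     file.path(out_dir, sprintf("segments_ph%g.tsv", ph)))
    }
  }
  maps <- align_levels(level_sets,
                       max_canonical =
                         count_conducting_levels(model_template))
  reports <- lapply(seq_along(pH_values), function(i) {
    occ_raw <- occupancies(ideals[[i]])
    nm <- names(occ_raw)
    canon <- vapply(nm, function(n) {
      if (n == "C") "C" else paste0("O", maps[[i]][as.integer(sub("O", "", n))])
    }, character(1))
    occ <- tapply(occ_raw, canon, sum)  # merged if two map to one canonical
    list(pH = pH_values[i], occupancies = occ, obs_time = duration)
  })
  dataset <- build_dataset(reports)
  n_cond <- length(setdiff(unique(dataset$level), "C"))
  fit <- NULL
  residuals <- NULL
  flags <- character(0)
  if (n_cond == 1L) {
    flags <- c(flags,
               "single conducting level resolved; titration of K_H skipped")
  } else {
    fit <- fit_model(dataset, model_template,
                     merge_top = max(1L,
                                     count_conducting_levels(model_template) -
                                       n_cond + 1L))
    residuals <- predict_vs_observed(fit, dataset)
  }
  bundle <- structure(list(reports = reports, level_sets = level_sets,
                           dataset = dataset, fit = fit,
                           residuals = residuals,
                           flags = flags,
                           provenance = list(seed = seed,
                                             duration = duration,
                                             pH_values = pH_values,
                                             hash = config_hash(
                                               list(pH_values, duration,
                                                    seed)))),
                      class = "pipeline_bundle")
  if (!is.null(out_dir)) {
    rep_out <- list(
      provenance = bundle$provenance,
      flags = flags,
      occupancies = lapply(reports, function(r) {
        list(pH = r$pH, occupancies = as.list(r$occupancies))
      }),
      fit = if (!is.null(fit)) list(K_H_hat = fit$K_H_hat,
                                    K_OC_hat = fit$K_OC_hat,
                                    apparent_pKa = fit$apparent_pKa,
                                    rss = fit$objective,
                                    rmse = residuals$rmse)
    )
    write_report(rep_out, file.path(out_dir, "bundle.json"))
  }
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("pipeline_bundle: %d pH points, %g s each (seed %d)\n",
              length(x$provenance$pH_values), x$provenance$duration,
              x$provenance$seed))
  if (!is.null(x$fit)) print(x$fit)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
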