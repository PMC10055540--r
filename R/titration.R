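#' Assemble a titration dataset from per-pH occupancy reports
#'
#' @param reports List of per-pH reports; each a list with elements `pH`
#'   (single number), `occupancies` (named vector as returned by
#'   [occupancies()], names `"C"`, `"O1"`, ... — `"C"` optional) and
#'   optionally `obs_time` (seconds of observation).
#' @return Object of class `titration_dataset`: a data frame with columns
#'   `pH`, `level`, `occupancy`, `obs_time`, plus attribute `filled`
#'   (flagged pH/level pairs that were absent and set to 0).
#' @export
build_dataset <- function(reports) {
  if (length(reports) < 2L) stop("need reports at >= 2 pH values",
                                 call. = FALSE)
  phs <- vapply(reports, function(r) r$pH, numeric(1))
  if (anyDuplicated(phs)) stop("duplicate pH values in reports",
                               call. = FALSE)
  all_levels <- unique(unlist(lapply(reports, function(r) {
    names(r$occupancies)
  })))
  if (is.null(all_levels) || any(!grepl("^(C|O[0-9]+)$", all_levels))) {
    stop("occupancy names must be 'C' or 'O<k>'", call. = FALSE)
  }
  o_levels <- sort(as.integer(sub("^O", "", setdiff(all_levels, "C"))))
  lev_order <- c(if ("C" %in% all_levels) "C", paste0("O", o_levels))
  filled <- character(0)
  rows <- lapply(reports, function(r) {
    occ <- r$occupancies[lev_order]
    missing <- is.na(occ)
    if (any(missing)) {
      filled <<- c(filled, paste0("pH", r$pH, ":", lev_order[missing]))
      occ[missing] <- 0
    }
    data.frame(pH = r$pH, level = lev_order, occupancy = unname(occ),
               obs_time = if (!is.null(r$obs_time)) r$obs_time else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- vapply(split(out$occupancy, out$pH), function(p) {
    abs(sum(p) - 1) > 1e-6
  }, logical(1))
  if (any(bad)) {
    stop("occupancies do not sum to 1 at pH ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  structure(out, filled = filled, class = c("titration_dataset",
                                            "data.frame"))
}

## predicted occupancy vector (C first, then conducting ascending) for given
## parameters, aligned to n_obs_levels observed conducting levels
predict_occ <- function(model, pH, merge_top, has_closed) {
  d <- stationary_distribution(model, pH)
  if (merge_top > 1L) d <- merge_top_levels(d, merge_top)
  if (has_closed) c(d$closed_prob, unname(d$level_probs))
  else unname(d$level_probs) / sum(d$level_probs)
}

#' Fit the protonation model to per-pH occupancy data
#'
#' Minimizes the sum of squared differences between observed and predicted
#' occupancies over all pH values and levels (closed included when present
#' in the data), with predictions from [stationary_distribution()] followed
#' by [merge_top_levels()]. Optimization is bounded quasi-Newton (L-BFGS-B)
#' in `(log10 K_H, log10 K_OC)` with a 3x3 grid of multistarts over
#' pKa 5-9 and K_OC 1e-3-1.
#'
#' @param data A `titration_dataset` from [build_dataset()].
#' @param model_template A [protonation_model()] fixing the site structure
#'   (`n_sites`, `g_weight` per class); its `K_H` and `K_OC` values seed
#'   nothing — they are free parameters.
#' @param merge_top How many top model levels to merge into the observed top
#'   level (default 2: a five-level tetramer model against four observed
#'   levels).
#' @param weight_by_time Weight residuals by per-row observation time
#'   (optional; default unweighted).
#' @return Object of class `titration_fit` with `K_H_hat` (per class, molar),
#'   `K_OC_hat`, `apparent_pKa`, `objective` (residual sum of squares),
#'   `predicted` (long data frame), `convergence` (per-start table) and
#'   `flags`.
#' @export
fit_model <- function(data, model_template, merge_top = 2L,
                      weight_by_time = FALSE) {
  stopifnot(inherits(data, "titration_dataset"),
            inherits(model_template, "protonation_model"))
  has_closed <- "C" %in% data$level
  n_obs_cond <- length(setdiff(unique(data$level), "C"))
  n_classes <- length(model_template$site_classes)
  n_model_lev <- count_conducting_levels(model_template) - merge_top + 1L
  phs <- sort(unique(data$pH))

  flags <- character(0)
  if (n_classes > 1L && length(phs) < 6L && n_obs_cond > 1L) {
    stop("fitting more than one K_H requires >= 6 pH points", call. = FALSE)
  }
  if (n_obs_cond == 1L) {
    flags <- c(flags, "K_H unidentifiable from a single conducting level")
  } else if (n_model_lev != n_obs_cond) {
    stop(sprintf(paste0("model predicts %d conducting levels after merging",
                        " but data has %d; adjust 'merge_top' or the site",
                        " structure"), n_model_lev, n_obs_cond),
         call. = FALSE)
  }

  # observed matrix: rows pH, cols level in (C, O1..)
  lev_order <- c(if (has_closed) "C", paste0("O", seq_len(n_obs_cond)))
  obs <- matrix(NA_real_, length(phs), length(lev_order),
                dimnames = list(phs, lev_order))
  wts <- rep(1, length(phs))
  for (i in seq_along(phs)) {
    sub <- data[data$pH == phs[i], ]
    obs[i, ] <- sub$occupancy[match(lev_order, sub$level)]
    if (weight_by_time && !all(is.na(sub$obs_time))) {
      wts[i] <- mean(sub$obs_time, na.rm = TRUE)
    }
  }
  if (weight_by_time) wts <- wts / mean(wts)

  make_model <- function(par) {
    khs <- 10^par[seq_len(n_classes)]
    koc <- 10^par[n_classes + 1L]
    scs <- lapply(seq_len(n_classes), function(j) {
      sc <- model_template$site_classes[[j]]
      site_class(sc$n_sites, khs[j], sc$g_weight)
    })
    protonation_model(scs, K_OC = koc, k_on = model_template$k_on,
                      k_close = model_template$k_close)
  }
  objective <- function(par) {
    m <- make_model(par)
    sse <- 0
    for (i in seq_along(phs)) {
      pred <- predict_occ(m, phs[i], merge_top, has_closed)
      if (n_obs_cond == 1L) {
        # single conducting level: compare closed vs total conducting
        pred <- c(pred[1], sum(pred[-1]))[seq_along(lev_order)]
      }
      sse <- sse + wts[i] * sum((obs[i, ] - pred)^2)
    }
    sse
  }

  starts <- expand.grid(pKa = c(5, 7, 9), lkoc = c(-3, -1.5, 0))
  lower <- c(rep(-12, n_classes), -6)
  upper <- c(rep(-2, n_classes), 2)
  conv <- list()
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(rep(-starts$pKa[s], n_classes), starts$lkoc[s])
    res <- stats::optim(par0, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    conv[[s]] <- data.frame(start = s, pKa0 = starts$pKa[s],
                            log10_KOC0 = starts$lkoc[s],
                            objective = res$value,
                            converged = res$convergence == 0)
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  if (is.null(best)) stop("titration fit failed in all starts", call. = FALSE)
  K_H_hat <- 10^best$par[seq_len(n_classes)]
  K_OC_hat <- 10^best$par[n_classes + 1L]
  if (n_obs_cond == 1L) K_H_hat <- rep(NA_real_, n_classes)

  m_best <- make_model(best$par)
  pred_rows <- lapply(phs, function(ph) {
    pred <- predict_occ(m_best, ph, merge_top, has_closed)
    if (n_obs_cond == 1L) pred <- c(pred[1], sum(pred[-1]))[seq_along(lev_order)]
    data.frame(pH = ph, level = lev_order, predicted = pred)
  })
  structure(list(K_H_hat = K_H_hat, K_OC_hat = K_OC_hat,
                 apparent_pKa = if (all(is.na(K_H_hat))) NA_real_
                                else apparent_pKa(K_H_hat),
                 objective = best$value,
                 predicted = do.call(rbind, pred_rows),
                 convergence = do.call(rbind, conv),
                 merge_top = merge_top,
                 flags = flags),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("titration_fit:\n")
  cat("  K_H =", paste(sprintf("%.4g", x$K_H_hat), collapse = ", "),
      "M (apparent pKa",
      paste(sprintf("%.3f", x$apparent_pKa), collapse = ", "), ")\n")
  cat(sprintf("  K_OC = %.4g, RSS = %.4g\n", x$K_OC_hat, x$objective))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Observed vs predicted occupancies for a titration fit
#'
#' @param fit A `titration_fit`.
#' @param data The `titration_dataset` it was fitted to.
#' @return List with `table` (pH, level, observed, predicted, residual) and
#'   `rmse`.
#' @export
predict_vs_observed <- function(fit, data) {
  stopifnot(inherits(fit, "titration_fit"),
            inherits(data, "titration_dataset"))
  tab <- merge(as.data.frame(data)[, c("pH", "level", "occupancy")],
               fit$predicted, by = c("pH", "level"))
  names(tab)[names(tab) == "occupancy"] <- "observed"
  tab$residual <- tab$observed - tab$predicted
  tab <- tab[order(tab$pH, tab$level), ]
  rownames(tab) <- NULL
  list(table = tab, rmse = sqrt(mean(tab$residual^2)))
}
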