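#' Titratable site class
#'
#' A class of identical, independently titratable side chains in the channel
#' pore (e.g. the four introduced aspartates at the helix bundle crossing).
#' Each protonated site of the class removes `g_weight` from the relative
#' channel conductance.
#'
#' @param n_sites Integer count of sites of this class per channel (>= 0).
#' @param K_H Acid dissociation constant of the site, molar (> 0).
#' @param g_weight Conductance decrement per protonated site, as a fraction of
#'   the full single-channel amplitude (in `[0, 1]`).
#' @return An object of class `site_class`.
#' @examples
#' site_class(4, 2e-7, 0.25)
#' @export
site_class <- function(n_sites, K_H, g_weight = 1 / n_sites) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 0 ||
      n_sites != round(n_sites)) {
    stop("'n_sites' must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(K_H) || length(K_H) != 1L || !is.finite(K_H) || K_H <= 0) {
    stop("'K_H' must be a single positive number (molar)", call. = FALSE)
  }
  if (!is.numeric(g_weight) || length(g_weight) != 1L || !is.finite(g_weight) ||
      g_weight < 0 || g_weight > 1) {
    stop("'g_weight' must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_sites = as.integer(n_sites), K_H = K_H,
                 g_weight = g_weight),
            class = "site_class")
}

#' Independent-subunit protonation model
#'
#' Gating model for pH-dependent sub-conductance states: titratable sites
#' protonate independently (no cooperativity), each protonation stepping the
#' channel conductance down by the site's `g_weight`; in addition a single
#' fast "flicker" gate closes the channel entirely with equilibrium constant
#' `K_OC`, identically from every conducting level. At equilibrium the model
#' is controlled by the dissociation constant(s) `K_H` and `K_OC` alone;
#' `k_on` and `k_close` only set the time scale for kinetic simulation.
#'
#' @param site_classes A `site_class` or list of `site_class` objects.
#' @param K_OC Intra-burst closed/open equilibrium constant (dimensionless
#'   and non-negative). The stationary closed probability is
#'   `K_OC / (1 + K_OC)`.
#' @param k_on Protonation association rate constant, M^-1 s^-1 (default
#'   diffusion-limited 1e10).
#' @param k_close Closing rate of the fast gate, s^-1 (kinetics only).
#' @return An object of class `protonation_model`.
#' @examples
#' m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
#' stationary_distribution(m, 7.4)
#' @export
protonation_model <- function(site_classes, K_OC = 0, k_on = 1e10,
                              k_close = 0) {
  if (inherits(site_classes, "site_class")) site_classes <- list(site_classes)
  if (!is.list(site_classes) ||
      !all(vapply(site_classes, inherits, logical(1), "site_class"))) {
    stop("'site_classes' must be site_class objects", call. = FALSE)
  }
  if (!is.numeric(K_OC) || length(K_OC) != 1L || !is.finite(K_OC) || K_OC < 0) {
    stop("'K_OC' must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(k_on) || length(k_on) != 1L || k_on <= 0) {
    stop("'k_on' must be > 0", call. = FALSE)
  }
  if (!is.numeric(k_close) || length(k_close) != 1L || k_close < 0) {
    stop("'k_close' must be >= 0", call. = FALSE)
  }
  structure(list(site_classes = site_classes, K_OC = K_OC, k_on = k_on,
                 k_close = k_close),
            class = "protonation_model")
}

#' @export
print.protonation_model <- function(x, ...) {
  cat("Independent-subunit protonation model\n")
  for (sc in x$site_classes) {
    cat(sprintf("  site class: n = %d, K_H = %.3g M (pKa %.2f), g_weight = %.3g\n",
                sc$n_sites, sc$K_H, apparent_pKa(sc$K_H), sc$g_weight))
  }
  cat(sprintf("  K_OC = %.3g (closed prob %.4f), k_on = %.3g M^-1 s^-1, k_close = %.3g s^-1\n",
              x$K_OC, x$K_OC / (1 + x$K_OC), x$k_on, x$k_close))
  invisible(x)
}

#' Proton concentration from pH
#'
#' @param pH Numeric pH value(s).
#' @return Proton concentration in molar, `10^-pH`.
#' @examples
#' proton_concentration(7.4)
#' @export
proton_concentration <- function(pH) {
  if (!is.numeric(pH) || length(pH) == 0L || any(!is.finite(pH))) {
    stop("'pH' must be finite numeric", call. = FALSE)
  }
  10^(-pH)
}

#' Single-site protonation probability
#'
#' Equilibrium probability that one titratable site is protonated,
#' `[H+] / ([H+] + K_H)` (Henderson-Hasselbalch occupancy of the
#' protonated form).
#'
#' @param pH Numeric pH value(s).
#' @param K_H Acid dissociation constant, molar (> 0).
#' @return Protonation probability in `[0, 1]`, decreasing in pH.
#' @examples
#' site_protonation_prob(7.4, 2e-7)
#' @export
site_protonation_prob <- function(pH, K_H) {
  if (!is.numeric(K_H) || length(K_H) != 1L || !is.finite(K_H) || K_H <= 0) {
    stop("'K_H' must be a single positive number", call. = FALSE)
  }
  h <- proton_concentration(pH)
  h / (h + K_H)
}

#' Apparent pKa of a site
#'
#' @param K_H Acid dissociation constant, molar (> 0).
#' @return `-log10(K_H)`.
#' @examples
#' apparent_pKa(2e-7)
#' @export
apparent_pKa <- function(K_H) {
  if (!is.numeric(K_H) || length(K_H) == 0L || any(!is.finite(K_H)) ||
      any(K_H <= 0)) {
    stop("'K_H' must be positive", call. = FALSE)
  }
  -log10(K_H)
}

#' Fold-change of protonation rates under a pKa shift
#'
#' At fixed diffusion-limited association rate `k_on`, the dissociation rate
#' is `k_off = k_on * K_H`, so an upshift of the pKa slows both the effective
#' on-rate (at the half-titration pH) and the off-rate by the same factor.
#'
#' @param pKa_from,pKa_to Numeric pKa values.
#' @return `10^(pKa_to - pKa_from)`, the fold-slowing of the rates.
#' @examples
#' rate_shift_factor(3, 7)  # 1e4
#' @export
rate_shift_factor <- function(pKa_from, pKa_to) {
  if (any(!is.finite(pKa_from)) || any(!is.finite(pKa_to))) {
    stop("pKa values must be finite", call. = FALSE)
  }
  10^(pKa_to - pKa_from)
}

## Enumerate the distinct conductance levels of a model. Returns a data.frame
## with one row per (merged) level, ascending conductance, and the per-class
## protonation-count combinations feeding each level.
level_table <- function(model, tol = 1e-9) {
  ns <- vapply(model$site_classes, `[[`, integer(1), "n_sites")
  gs <- vapply(model$site_classes, `[[`, numeric(1), "g_weight")
  combos <- expand.grid(lapply(ns, function(n) 0:n), KEEP.OUT.ATTRS = FALSE)
  cond <- 1 - as.matrix(combos) %*% gs
  cond <- pmax(as.numeric(cond), 0)
  ord <- order(cond)
  cond_sorted <- cond[ord]
  # cluster conductances whose consecutive gaps are within tolerance
  grp <- cumsum(c(1, as.integer(diff(cond_sorted) > tol)))
  data.frame(
    level = seq_len(max(grp)),
    conductance = as.numeric(tapply(cond_sorted, grp, max)),
    row.names = NULL
  ) -> lv
  list(levels = lv, combos = combos, conductance = cond,
       group_of_combo = grp[order(ord)])
}

#' Number of distinct conducting levels of a model
#'
#' Counts the distinct relative-conductance values over all protonation
#' configurations (conductances equal within `tol` are merged). For a single
#' class of `k` sites this is `k + 1`; e.g. two titratable sites give the
#' three well-resolved sub-states seen when only two acidic residues remain
#' in the pore.
#'
#' @param model A [protonation_model()].
#' @param tol Merge tolerance on relative conductance.
#' @return Integer number of conducting levels.
#' @examples
#' count_conducting_levels(protonation_model(site_class(2, 2e-7, 0.5)))
#' @export
count_conducting_levels <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "protonation_model"))
  nrow(level_table(model, tol)$levels)
}

#' Stationary distribution over sub-conductance levels
#'
#' Computes the equilibrium probability of each conducting level and of the
#' aggregated fast-closed states. Per-class protonation counts are independent
#' binomials with success probability [site_protonation_prob()]; a level is one
#' distinct value of total relative conductance `1 - sum(k_c * g_weight_c)`
#' (clipped at 0, values equal within `tol` merged); every level carries a
#' paired flicker-closed state so the total closed probability is
#' `K_OC / (1 + K_OC)` independently of pH.
#'
#' @param model A [protonation_model()] with at least one site class.
#' @param pH pH value (single finite number).
#' @param tol Level-merge tolerance on relative conductance.
#' @return An object of class `state_distribution`: a list with
#'   `level_probs` (named `O1`, `O2`, ... ascending conductance; `O1` is the
#'   most-protonated, lowest-conductance state), `level_conductances`
#'   (strictly increasing, in `[0, 1]`) and `closed_prob`.
#' @examples
#' m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
#' stationary_distribution(m, 7.4)
#' @export
stationary_distribution <- function(model, pH, tol = 1e-9) {
  stopifnot(inherits(model, "protonation_model"))
  if (length(model$site_classes) == 0L) {
    stop("model needs at least one site class", call. = FALSE)
  }
  if (length(pH) != 1L) stop("'pH' must be a single value", call. = FALSE)
  lt <- level_table(model, tol)
  fs <- vapply(model$site_classes, function(sc) {
    site_protonation_prob(pH, sc$K_H)
  }, numeric(1))
  ns <- vapply(model$site_classes, `[[`, integer(1), "n_sites")
  # probability of each count combination = product of binomials
  p_combo <- rep(1, nrow(lt$combos))
  for (j in seq_along(ns)) {
    p_combo <- p_combo * stats::dbinom(lt$combos[[j]], ns[j], fs[j])
  }
  p_level <- as.numeric(tapply(p_combo, lt$group_of_combo, sum))
  open_frac <- 1 / (1 + model$K_OC)
  probs <- p_level * open_frac
  names(probs) <- paste0("O", seq_along(probs))
  structure(list(level_probs = probs,
                 level_conductances = lt$levels$conductance,
                 closed_prob = model$K_OC / (1 + model$K_OC)),
            class = "state_distribution")
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("Sub-state stationary distribution\n")
  cat(sprintf("  closed (C): %.4f\n", x$closed_prob))
  for (i in seq_along(x$level_probs)) {
    cat(sprintf("  %s (g = %.3f): %.4f\n", names(x$level_probs)[i],
                x$level_conductances[i], x$level_probs[i]))
  }
  invisible(x)
}

#' Merge the highest conducting levels of a distribution
#'
#' Collapses the top `n_merge` levels into a single level with summed
#' probability and the maximal conductance. Used to compare a five-level
#' tetramer model with experiments that resolve only four levels (the two
#' highest model levels merging into the observed top level).
#'
#' @param dist A `state_distribution`.
#' @param n_merge Number of top levels to merge (1 = identity).
#' @return A `state_distribution` with `length(level_probs) - n_merge + 1`
#'   levels; total probability conserved.
#' @examples
#' m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
#' merge_top_levels(stationary_distribution(m, 7.4), 2)
#' @export
merge_top_levels <- function(dist, n_merge) {
  stopifnot(inherits(dist, "state_distribution"))
  k <- length(dist$level_probs)
  if (!is.numeric(n_merge) || length(n_merge) != 1L || n_merge < 1 ||
      n_merge > k || n_merge != round(n_merge)) {
    stop("'n_merge' must be an integer in [1, number of levels]",
         call. = FALSE)
  }
  if (n_merge == 1L) return(dist)
  keep <- seq_len(k - n_merge)
  top <- (k - n_merge + 1L):k
  probs <- c(dist$level_probs[keep], sum(dist$level_probs[top]))
  names(probs) <- paste0("O", seq_along(probs))
  structure(list(level_probs = probs,
                 level_conductances = c(dist$level_conductances[keep],
                                        max(dist$level_conductances[top])),
                 closed_prob = dist$closed_prob),
            class = "state_distribution")
}

#' pH titration curves of the sub-state distribution
#'
#' Evaluates [stationary_distribution()] across a pH grid.
#'
#' @param model A [protonation_model()].
#' @param pH_grid Non-empty numeric vector of pH values.
#' @param merge_top Optionally merge the top levels of each distribution
#'   (see [merge_top_levels()]); default 1 (no merge).
#' @return A data.frame in long format with columns `pH`, `level` (`"C"` or
#'   `"O1"`, `"O2"`, ...), `conductance` (NA for `C`) and `prob`. Probabilities
#'   sum to 1 within each pH.
#' @examples
#' m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
#' head(titration_curves(m, c(6.2, 7.4, 8.6)))
#' @export
titration_curves <- function(model, pH_grid, merge_top = 1L) {
  stopifnot(inherits(model, "protonation_model"))
  if (!is.numeric(pH_grid) || length(pH_grid) == 0L ||
      any(!is.finite(pH_grid))) {
    stop("'pH_grid' must be a non-empty finite numeric vector", call. = FALSE)
  }
  rows <- lapply(pH_grid, function(ph) {
    d <- stationary_distribution(model, ph)
    if (merge_top > 1L) d <- merge_top_levels(d, merge_top)
    data.frame(pH = ph,
               level = c("C", names(d$level_probs)),
               conductance = c(NA_real_, d$level_conductances),
               prob = c(d$closed_prob, unname(d$level_probs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kinetic rate table of the protonation model
#'
#' Per-site protonation rate `k_on * [H+]`, per-site deprotonation rate
#' `k_on * K_H`, and flicker-gate closing/opening rates `k_close` and
#' `k_close / K_OC`. Detailed balance of these rates reproduces
#' [stationary_distribution()].
#'
#' @param model A [protonation_model()].
#' @param pH pH value.
#' @return A data.frame with columns `process`, `class` (site-class index, NA
#'   for the gate) and `rate` (s^-1; protonation rates are per unprotonated
#'   site, deprotonation per protonated site).
#' @examples
#' m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05, k_close = 3.7)
#' kinetic_rates(m, 7)
#' @export
kinetic_rates <- function(model, pH) {
  stopifnot(inherits(model, "protonation_model"))
  if (model$K_OC == 0 && model$k_close > 0) {
    stop("invalid kinetics: k_close > 0 requires K_OC > 0 (opening rate k_close/K_OC)",
         call. = FALSE)
  }
  h <- proton_concentration(pH)
  rows <- lapply(seq_along(model$site_classes), function(j) {
    sc <- model$site_classes[[j]]
    data.frame(process = c("protonation", "deprotonation"),
               class = j,
               rate = c(model$k_on * h, model$k_on * sc$K_H))
  })
  gate <- data.frame(process = c("close", "open"), class = NA_integer_,
                     rate = c(model$k_close,
                              if (model$k_close > 0) model$k_close / model$K_OC
                              else 0))
  out <- rbind(do.call(rbind, rows), gate)
  rownames(out) <- NULL
  out
}
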