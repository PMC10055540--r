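# Independent oracles used across tests.

# Brute-force stationary distribution: enumerate every per-site protonation
# configuration (2^n states per class) times the flicker gate, with
# equilibrium weights [H]/K_H per protonated site and K_OC for the closed
# gate. Returns conducting-level probabilities (ascending conductance),
# conductances, and the closed probability.
enumerate_stationary <- function(model, pH) {
  h <- 10^(-pH)
  ns <- vapply(model$site_classes, `[[`, integer(1), "n_sites")
  ks <- vapply(model$site_classes, `[[`, numeric(1), "K_H")
  gs <- vapply(model$site_classes, `[[`, numeric(1), "g_weight")
  n_tot <- sum(ns)
  class_of_site <- rep(seq_along(ns), ns)
  states <- expand.grid(rep(list(0:1), n_tot))
  w <- apply(states, 1, function(s) {
    prod(ifelse(s == 1, h / ks[class_of_site], 1))
  })
  cond <- apply(states, 1, function(s) {
    max(0, 1 - sum(s * gs[class_of_site]))
  })
  # flicker gate: open weight 1, closed weight K_OC
  z <- sum(w) * (1 + model$K_OC)
  closed_prob <- sum(w) * model$K_OC / z
  ord <- order(cond)
  cond_s <- cond[ord]; w_s <- w[ord] / z
  grp <- cumsum(c(1, as.integer(diff(cond_s) > 1e-9)))
  list(level_probs = as.numeric(tapply(w_s, grp, sum)),
       conductances = as.numeric(tapply(cond_s, grp, max)),
       closed_prob = closed_prob)
}

# Stationary distribution of the full protonation+gate CTMC from its
# generator null space (states: per-class counts x gate).
ctmc_stationary <- function(model, pH) {
  h <- 10^(-pH)
  ns <- vapply(model$site_classes, `[[`, integer(1), "n_sites")
  ks <- vapply(model$site_classes, `[[`, numeric(1), "K_H")
  counts <- expand.grid(lapply(ns, function(n) 0:n))
  n_c <- nrow(counts)
  states <- rbind(cbind(counts, gate = 1), cbind(counts, gate = 0))
  n_s <- nrow(states)
  Q <- matrix(0, n_s, n_s)
  idx <- function(cnt, gate) {
    i <- 1L
    for (j in seq_along(ns)) {
      stride <- if (j == 1) 1L else prod(ns[seq_len(j - 1)] + 1L)
      i <- i + cnt[[j]] * stride
    }
    i + (1 - gate) * n_c
  }
  k_open <- if (model$k_close > 0) model$k_close / model$K_OC else 0
  for (s in seq_len(n_s)) {
    cnt <- as.list(states[s, seq_along(ns)])
    gate <- states$gate[s]
    for (j in seq_along(ns)) {
      if (cnt[[j]] < ns[j]) {   # protonation
        to <- cnt; to[[j]] <- to[[j]] + 1
        Q[s, idx(to, gate)] <- Q[s, idx(to, gate)] +
          (ns[j] - cnt[[j]]) * model$k_on * h
      }
      if (cnt[[j]] > 0) {       # deprotonation
        to <- cnt; to[[j]] <- to[[j]] - 1
        Q[s, idx(to, gate)] <- Q[s, idx(to, gate)] +
          cnt[[j]] * model$k_on * ks[j]
      }
    }
    if (gate == 1 && model$k_close > 0) {
      Q[s, idx(cnt, 0)] <- Q[s, idx(cnt, 0)] + model$k_close
    }
    if (gate == 0 && k_open > 0) {
      Q[s, idx(cnt, 1)] <- Q[s, idx(cnt, 1)] + k_open
    }
  }
  diag(Q) <- -rowSums(Q)
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.min(abs(ev$values))]))
  pi_s <- v / sum(v)
  list(states = states, pi = pi_s)
}

# Frequency response of a digital filter at frequency f (Hz) for sample
# rate fs.
filter_gain <- function(coefs, f, fs) {
  z <- exp(2i * pi * f / fs)
  abs(sum(coefs$b * z^-(seq_along(coefs$b) - 1)) /
        sum(coefs$a * z^-(seq_along(coefs$a) - 1)))
}

# Sample-level truth path of a trace at its acquisition rate.
truth_path_samples <- function(trace) {
  fs <- trace$acquisition$sample_rate
  n <- length(trace$current)
  t_mid <- (seq_len(n) - 1) / fs
  trace$truth$level[findInterval(t_mid, trace$truth$t_start)]
}

g178d_fixture_trace <- function(duration, seed, render = TRUE) {
  fx <- fixture_spec("kir22_g178d_ph74")
  simulate_empirical(fx$spec, acquisition_spec(duration, seed = seed),
                     render_trace = render)
}
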