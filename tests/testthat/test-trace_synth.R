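test_that("acquisition chain has unity DC gain and -3 dB at the cutoff", {
  co <- bessel_lowpass(1000, 30000)
  expect_equal(filter_gain(co, 0, 30000), 1, tolerance = 1e-9)
  att_db <- 20 * log10(filter_gain(co, 1000, 30000))
  expect_lt(abs(att_db - (-3.0103)), 0.5)
  # a constant renders to itself (DC gain 1), up to noise-free equality
  acq <- acquisition_spec(0.2, seed = 1, noise_sd = 0)
  path <- data.frame(t_start = 0, t_end = 0.2, current = 4.2)
  y <- render(path, acq)
  expect_equal(mean(y), 4.2, tolerance = 1e-3)
  expect_error(bessel_lowpass(20000, 30000), "Nyquist")
})

test_that("filtered step response has the 4-pole Bessel rise time", {
  acq <- acquisition_spec(0.2, seed = 1, noise_sd = 0, sample_rate = 30000,
                          filter_cutoff = 1000, oversample = 10)
  path <- data.frame(t_start = c(0, 0.1), t_end = c(0.1, 0.2),
                     current = c(0, 1))
  y <- render(path, acq)
  t <- (seq_along(y) - 1) / acq$sample_rate
  i10 <- which(t >= 0.1 & y >= 0.1)[1]
  i90 <- which(t >= 0.1 & y >= 0.9)[1]
  rise <- t[i90] - t[i10]
  expect_lt(abs(rise - 0.34 / 1000), 0.2 * 0.34 / 1000)
})

test_that("a pure tone at the cutoff is attenuated by 3 dB", {
  fs_int <- 30000
  co <- bessel_lowpass(1000, fs_int)
  t <- (0:(fs_int / 5)) / fs_int
  x <- sin(2 * pi * 1000 * t)
  y <- as.numeric(signal::filter(co$b, co$a, x))
  # steady-state amplitude ratio
  amp <- max(abs(y[-(1:2000)]))
  expect_lt(abs(20 * log10(amp) - (-3.0103)), 0.5)
})

test_that("empirical simulation is deterministic and respects its spec", {
  fx <- fixture_spec("kir22_g178d_ph74")
  acq <- acquisition_spec(5, seed = 42)
  tr1 <- simulate_empirical(fx$spec, acq)
  tr2 <- simulate_empirical(fx$spec, acq)
  expect_identical(tr1$current, tr2$current)
  expect_identical(tr1$truth, tr2$truth)
  expect_equal(length(tr1$current), round(5 * acq$sample_rate))
  expect_true(all(tr1$truth$t_start >= 0 & tr1$truth$t_end <= 5))
  # only adjacent conducting transitions by construction
  tt <- transition_tally(truth_to_ideal(tr1))
  expect_equal(unname(tt$adjacency_summary["non_adjacent"]), 0)
  # noiseless, closure-free trace takes exactly the level amplitudes
  sp0 <- empirical_level_spec(c(0.5, 1), c(0.4, 0.6), closure_rate = 0)
  tr0 <- simulate_empirical(sp0, acquisition_spec(2, seed = 3, noise_sd = 0))
  amp <- 60 * 0.120
  near_level <- vapply(tr0$current, function(v) {
    min(abs(v - c(0.5, 1) * amp)) < 0.02 * amp
  }, logical(1))
  # all samples except the brief filter edges at transitions sit on levels
  expect_gt(mean(near_level), 0.97)
})

test_that("empirical mode reproduces occupancies, closure rate and dwells", {
  tr <- g178d_fixture_trace(120, seed = 7, render = FALSE)
  ti <- truth_to_ideal(tr)
  occ <- occupancies(ti, conducting_only = TRUE)
  target <- fixture_spec("kir22_g178d_ph74")$spec$occupancies
  # 3 SE bands from sojourn counting
  segs <- ti$segments
  n_soj <- sum(segs$level > 0)
  for (l in 1:4) {
    se <- sqrt(target[l] * (1 - target[l]) / n_soj) *
      sqrt(mean(segs$t_end - segs$t_start) * 200)  # dwell-correlation margin
    expect_lt(abs(occ[l] - target[l]), max(3 * se, 0.03))
  }
  cs <- closure_analysis(ti, burst_cutoff = 100, same_level_only = TRUE)
  expect_lt(abs(cs$frequency - 3.7), 3 * sqrt(3.7 * 120) / 120)
  expect_lt(abs(cs$mean_dwell - 6.4), 3 * 6.4 / sqrt(cs$n_events))
  # closures return to the pre-closure level by construction
  lv <- segs$level
  closed <- which(lv == 0)
  closed <- closed[closed > 1 & closed < length(lv)]
  expect_true(all(lv[closed - 1] == lv[closed + 1]))
})

test_that("zero-occupancy levels are excluded with a warning", {
  sp <- empirical_level_spec(c(0.5, 0.8, 1), c(0.5, 0, 0.5))
  expect_warning(tr <- simulate_empirical(sp, acquisition_spec(2, seed = 1),
                                          render_trace = FALSE),
                 "zero occupancy")
  expect_false(2 %in% tr$truth$level)
})

test_that("mechanistic truth-path occupancies match the closed form (chi-square)", {
  m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05,
                         k_on = 1e9, k_close = 3.7)
  tr <- simulate_mechanistic(m, 7.4, acquisition_spec(400, seed = 11),
                             render_trace = FALSE)
  segs <- tr$truth
  expect_gt(nrow(segs), 1e5)
  dur <- segs$t_end - segs$t_start
  d <- stationary_distribution(m, 7.4)
  probs <- c(d$closed_prob, unname(d$level_probs))
  obs_t <- vapply(0:5, function(l) sum(dur[segs$level == l]), numeric(1))
  # compare time fractions with a chi-square GOF on effective sojourn counts
  n_eff <- nrow(segs)
  expected <- probs * sum(obs_t)
  keep <- expected > 0
  stat <- sum((obs_t[keep] - expected[keep])^2 / expected[keep]) /
    mean(dur) / 3  # scale time to approximate counts, conservative factor
  p <- stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  # determinism
  tr2 <- simulate_mechanistic(m, 7.4, acquisition_spec(400, seed = 11),
                              render_trace = FALSE)
  expect_identical(tr$truth, tr2$truth)
})

test_that("mechanistic edge cases: no closures, degenerate rates", {
  # K_OC = 0, extreme pH: constant full-open current
  m0 <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0, k_close = 0)
  tr <- simulate_mechanistic(m0, 13, acquisition_spec(1, seed = 1,
                                                      noise_sd = 0))
  expect_true(all(tr$truth$level == max(tr$truth$level)))
  expect_lt(diff(range(tr$current[-(1:50)])), 1e-6)
  expect_false(0 %in% tr$truth$level)
})

test_that("fixture configurations encode the study conditions", {
  fx <- fixture_spec("kir22_g178d_ph74")
  expect_equal(fx$spec$relative_amplitudes, c(0.45, 0.74, 0.92, 1.00))
  expect_equal(fx$spec$occupancies, c(0.02, 0.07, 0.26, 0.59) / 0.94)
  expect_equal(fx$spec$closure_rate, 3.7)
  expect_equal(fx$spec$closed_dwell_mean, 6.4)
  expect_equal(fx$spec$full_conductance, 60)
  wt <- fixture_spec("kir22_wt_ph74")
  expect_length(wt$spec$relative_amplitudes, 1)
  expect_equal(wt$spec$closure_rate, 5.9)
  expect_equal(wt$spec$closed_dwell_mean, 7.1)
  expect_length(fixture_spec("dimer_ngnE")$spec$relative_amplitudes, 3)
  expect_error(fixture_spec("nope"), "unknown fixture")
})

test_that("spec constructors validate their invariants", {
  expect_error(empirical_level_spec(c(0.5, 0.4, 1), c(0.3, 0.3, 0.4)),
               "increasing")
  expect_error(empirical_level_spec(c(0.5, 1), c(0.3, 0.3, 0.4)),
               "length")
  expect_error(empirical_level_spec(c(0.5, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(acquisition_spec(-1), "duration")
  expect_error(acquisition_spec(1, sample_rate = 1500, filter_cutoff = 1000),
               "exceed")
})
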