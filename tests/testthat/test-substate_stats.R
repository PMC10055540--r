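make_ideal <- function(levels, durations, fs = 3000) {
  t_end <- cumsum(durations)
  t_start <- c(0, t_end[-length(t_end)])
  segs <- data.frame(start = t_start * fs, end = t_end * fs,
                     level = levels, t_start = t_start, t_end = t_end)
  amps <- seq(0, by = 2, length.out = max(levels) + 1L)
  structure(list(segments = segs,
                 levels = level_set(amps, sds = 0.1,
                                    weights = rep(1 / length(amps),
                                                  length(amps))),
                 sample_rate = fs, source = list()),
            class = "idealized_trace")
}

test_that("occupancies are time-weighted and normalized", {
  id <- make_ideal(c(1, 2, 1, 0), c(1, 2, 1, 4))
  occ <- occupancies(id)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["O2"]), 0.25)
  expect_equal(unname(occ["C"]), 0.5)
  occ_c <- occupancies(id, conducting_only = TRUE)
  expect_equal(unname(occ_c["O1"]), 0.5)
  expect_equal(sum(occ_c), 1)
  single <- make_ideal(2, 3)
  expect_equal(unname(occupancies(single)["O2"]), 1)
})

test_that("fixture occupancy recovery against the generator truth (600 s)", {
  tr <- g178d_fixture_trace(600, seed = 1, render = FALSE)
  occ <- occupancies(truth_to_ideal(tr), conducting_only = TRUE)
  target <- fixture_spec("kir22_g178d_ph74")$spec$occupancies
  expect_lt(abs(occ[4] - target[4]), 0.05)
  expect_equal(unname(occ), target, tolerance = 0.15)
})

test_that("transition tally classifies adjacency and counts every boundary", {
  id <- make_ideal(c(1, 2, 3), c(1, 1, 1))
  tt <- transition_tally(id)
  expect_equal(unname(tt$adjacency_summary["adjacent"]), 2)
  expect_equal(unname(tt$adjacency_summary["non_adjacent"]), 0)
  expect_equal(unname(tt$adjacency_summary["total"]), 2)
  id2 <- make_ideal(c(1, 3, 0, 2), c(1, 1, 1, 1))
  tt2 <- transition_tally(id2)
  expect_equal(unname(tt2$adjacency_summary["non_adjacent"]), 1)
  expect_equal(unname(tt2$adjacency_summary["closed_coupled"]), 2)
  expect_equal(sum(tt2$counts), nrow(id2$segments) - 1)
  expect_true(all(diag(tt2$counts) == 0))
  expect_error(transition_tally(make_ideal(1, 1)), "2 segments")
})

test_that("idealized fixture traces show few non-adjacent transitions", {
  nonadj <- 0; tot <- 0
  for (seed in 1:10) {
    tr <- g178d_fixture_trace(20, seed = seed)
    id <- assign_path(tr, fit_levels(tr))
    tt <- transition_tally(id)
    nonadj <- nonadj + tt$adjacency_summary["non_adjacent"]
    tot <- tot + tt$adjacency_summary["adjacent"] +
      tt$adjacency_summary["non_adjacent"]
  }
  expect_lt(nonadj / tot, 0.05)
})

test_that("closure analysis applies the cutoff and same-level rule", {
  # closures: 5 ms (same level), 200 ms (long), 5 ms (different flanks)
  id <- make_ideal(c(2, 0, 2, 0, 2, 0, 3),
                   c(1, 0.005, 1, 0.2, 1, 0.005, 1))
  cs <- closure_analysis(id, burst_cutoff = 100, same_level_only = TRUE)
  expect_equal(cs$n_events, 1)
  expect_equal(cs$mean_dwell, 5)
  expect_equal(cs$frequency, 1 / 4)  # one event per 4 s conducting time
  cs_all <- closure_analysis(id, burst_cutoff = 100, same_level_only = FALSE)
  expect_equal(cs_all$n_events, 2)
  # cutoff -> Inf counts every interior closed segment
  cs_inf <- closure_analysis(id, burst_cutoff = Inf, same_level_only = FALSE)
  expect_equal(cs_inf$n_events, 3)
  # no closures: frequency 0, dwell flagged NA
  cs0 <- closure_analysis(make_ideal(c(1, 2), c(1, 1)))
  expect_equal(cs0$frequency, 0)
  expect_true(is.na(cs0$mean_dwell))
  expect_error(closure_analysis(id, burst_cutoff = -1), "burst_cutoff")
})

test_that("closure statistics recover the generator parameters", {
  tr <- g178d_fixture_trace(300, seed = 9, render = FALSE)
  cs <- closure_analysis(truth_to_ideal(tr), burst_cutoff = 100,
                         same_level_only = TRUE)
  expect_lt(abs(cs$frequency - 3.7), 3 * sqrt(3.7 * 300) / 300)
  expect_lt(abs(cs$mean_dwell - 6.4), 3 * cs$se_dwell + 0.2)
  expect_equal(cs$se_dwell, 6.4 / sqrt(cs$n_events), tolerance = 0.15)
})

test_that("per-level IV fits recover configured conductances", {
  volts <- seq(-160, -60, by = 20)
  rel <- c(0.45, 0.74, 0.92, 1)
  ideals <- lapply(volts, function(v) {
    amps <- c(0, rel * 60 * abs(v) / 1000)
    structure(list(segments = data.frame(start = 0, end = 10, level = 0,
                                         t_start = 0, t_end = 10 / 3000),
                   levels = level_set(amps, 0.01,
                                      rep(1 / length(amps), length(amps))),
                   sample_rate = 3000, source = list()),
              class = "idealized_trace")
  })
  fits <- iv_per_level(ideals, volts)
  expect_equal(fits$slope_pS, rel * 60, tolerance = 1e-6)
  expect_true(all(fits$r_squared > 1 - 1e-9))
  # slope ratios equal configured amplitude ratios
  expect_equal(fits$slope_pS / max(fits$slope_pS), rel, tolerance = 1e-6)
  expect_error(iv_per_level(ideals[1], -120), "2 voltages")
})

test_that("amplitude normalization is scale-invariant", {
  expect_equal(normalize_amplitudes(c(2.7, 4.44, 5.52, 6.0)),
               c(0.45, 0.74, 0.92, 1.00))
  expect_equal(normalize_amplitudes(10 * c(2.7, 4.44, 5.52, 6.0)),
               c(0.45, 0.74, 0.92, 1.00))
  expect_equal(normalize_amplitudes(3.3), 1)
  lv <- level_set(c(0.1, 2.8, 6.1), 0.1, c(0.2, 0.3, 0.5))
  expect_equal(normalize_amplitudes(lv), c(2.7 / 6, 1))
  expect_error(normalize_amplitudes(c(0, 0)), "positive")
})

test_that("dwell comparison wraps an unpaired t-test", {
  set.seed(1)
  a <- rexp(200, 1 / 6.4)
  b <- rexp(200, 1 / 7.1)
  ht <- compare_dwells(a, b)
  expect_s3_class(ht, "htest")
  expect_match(ht$method, "Two Sample")
})
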