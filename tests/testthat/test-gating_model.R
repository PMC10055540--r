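test_that("proton concentration and site protonation follow the pH definitions", {
  expect_equal(proton_concentration(7), 1e-7)
  expect_equal(proton_concentration(0), 1)
  expect_equal(proton_concentration(7.4), 3.981072e-8, tolerance = 1e-6)
  expect_error(proton_concentration(NaN), "finite")

  expect_equal(site_protonation_prob(-log10(2e-7), 2e-7), 0.5)
  expect_equal(site_protonation_prob(12, 2e-7), 0, tolerance = 1e-4)
  expect_equal(site_protonation_prob(7.4, 2e-7), 0.166009, tolerance = 1e-5)
  expect_error(site_protonation_prob(7, -1), "positive")
  # monotone decreasing in pH
  p <- site_protonation_prob(seq(4, 10, by = 0.25), 2e-7)
  expect_true(all(diff(p) < 0))
})

test_that("apparent pKa and rate-shift arithmetic are exact", {
  expect_equal(apparent_pKa(1e-3), 3)
  expect_equal(apparent_pKa(2e-7), 6.699, tolerance = 1e-4)
  expect_equal(apparent_pKa(1), 0)
  expect_error(apparent_pKa(0), "positive")
  expect_equal(rate_shift_factor(3, 7), 1e4)
  expect_equal(rate_shift_factor(5.2, 5.2), 1)
  expect_equal(rate_shift_factor(7, 3), 1e-4)
})

test_that("stationary distribution matches hand-derived values for the tetramer model", {
  m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
  d <- stationary_distribution(m, 7.4)
  expect_equal(unname(d$level_probs["O5"]), 0.460740, tolerance = 1e-5)
  expect_equal(unname(d$level_probs["O4"]), 0.366848, tolerance = 1e-5)
  expect_equal(d$closed_prob, 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(sum(d$level_probs) + d$closed_prob, 1, tolerance = 1e-12)
  expect_true(all(diff(d$level_conductances) > 0))

  # no protons at extreme pH, no closures with K_OC = 0
  m0 <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0)
  d0 <- stationary_distribution(m0, 14)
  expect_equal(unname(d0$level_probs["O5"]), 1, tolerance = 1e-6)
  expect_equal(d0$closed_prob, 0)

  # half-titration: binomial(4, 1/2)
  dh <- stationary_distribution(m0, apparent_pKa(2e-7))
  expect_equal(unname(dh$level_probs["O3"]), 6 / 16, tolerance = 1e-12)
})

test_that("binomial level probabilities equal exhaustive enumeration", {
  cases <- list(
    protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05),
    protonation_model(site_class(6, 1e-6, 1 / 6), K_OC = 0.2),
    protonation_model(site_class(3, 5e-8, 0.4), K_OC = 0),
    protonation_model(list(site_class(2, 1e-7, 0.13),
                           site_class(4, 2e-7, 0.07)), K_OC = 0.05)
  )
  for (m in cases) {
    for (ph in c(5.5, 6.7, 7.4, 8.2)) {
      d <- stationary_distribution(m, ph)
      o <- enumerate_stationary(m, ph)
      expect_equal(unname(d$level_probs), o$level_probs, tolerance = 1e-12)
      expect_equal(d$level_conductances, o$conductances, tolerance = 1e-12)
      expect_equal(d$closed_prob, o$closed_prob, tolerance = 1e-12)
    }
  }
})

test_that("closed probability is pH-independent and monotonicity holds", {
  m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
  grid <- seq(5, 9, by = 0.2)
  tc <- titration_curves(m, grid)
  closed <- tc$prob[tc$level == "C"]
  expect_equal(closed, rep(0.05 / 1.05, length(grid)), tolerance = 1e-12)
  top <- tc$prob[tc$level == "O5"]
  bottom <- tc$prob[tc$level == "O1"]
  expect_true(all(diff(top) > 0))       # deprotonated level grows with pH
  expect_true(all(diff(bottom) < 0))    # protonated level shrinks
  # per-pH normalization
  sums <- tapply(tc$prob, tc$pH, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)), tolerance = 1e-12)
  expect_equal(nrow(titration_curves(m, c(6.2, 6.5, 6.8, 7.1, 7.4, 7.7,
                                          8.0, 8.6))),
               8 * 6)  # 8 pH values x (C + 5 levels)
  expect_error(titration_curves(m, numeric(0)), "non-empty")
})

test_that("merging top levels conserves probability", {
  m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05)
  d <- stationary_distribution(m, 7.4)
  expect_identical(merge_top_levels(d, 1), d)
  d2 <- merge_top_levels(d, 2)
  expect_equal(unname(d2$level_probs["O4"]), 0.460740 + 0.366848,
               tolerance = 1e-5)
  expect_equal(sum(d2$level_probs) + d2$closed_prob, 1, tolerance = 1e-12)
  d5 <- merge_top_levels(d, 5)
  expect_length(d5$level_probs, 1)
  expect_equal(unname(d5$level_probs), 1 - d$closed_prob, tolerance = 1e-12)
  expect_error(merge_top_levels(d, 6), "n_merge")
  expect_error(merge_top_levels(d, 0), "n_merge")
})

test_that("conducting-level count is sites + 1 per class and multiplies across classes", {
  for (k in 0:6) {
    m <- protonation_model(site_class(k, 2e-7,
                                      if (k > 0) 1 / (2 * k) else 0.5))
    expect_equal(count_conducting_levels(m), k + 1)
  }
  # two titratable sites -> the three well-resolved sub-states
  expect_equal(count_conducting_levels(
    protonation_model(site_class(2, 2e-7, 0.25))), 3)
  # incommensurate weights: all (k1, k2) sums distinct (no clipping)
  m2 <- protonation_model(list(site_class(2, 1e-7, 0.071),
                               site_class(4, 2e-7, 0.013)))
  expect_equal(count_conducting_levels(m2), 15)
})

test_that("kinetic rates obey detailed balance against the closed form", {
  m <- protonation_model(site_class(4, 2e-7, 0.25), K_OC = 0.05,
                         k_on = 1e10, k_close = 3.7)
  kr <- kinetic_rates(m, 7)
  expect_equal(kr$rate[kr$process == "protonation"], 1e3)
  expect_equal(kr$rate[kr$process == "deprotonation"], 2e3)
  expect_equal(kr$rate[kr$process == "open"], 3.7 / 0.05)
  expect_error(kinetic_rates(protonation_model(site_class(4, 2e-7, 0.25),
                                               K_OC = 0, k_close = 1), 7),
               "K_OC")

  # CTMC generator null space reproduces the analytic distribution
  for (ph in c(6.5, 7.4)) {
    cs <- ctmc_stationary(m, ph)
    d <- stationary_distribution(m, ph)
    open <- cs$states$gate == 1
    expect_equal(sum(cs$pi[!open]), d$closed_prob, tolerance = 1e-9)
    # per-count open probabilities must aggregate to the level probs
    lt <- kirsub:::level_table(m)
    lv_of_count <- lt$group_of_combo
    agg <- tapply(cs$pi[open], lv_of_count[seq_len(sum(open))], sum)
    expect_equal(as.numeric(agg), unname(d$level_probs), tolerance = 1e-9)
  }
})

test_that("constructor invariants are enforced", {
  expect_error(site_class(-1, 1e-7, 0.2), "n_sites")
  expect_error(site_class(4, 0, 0.2), "K_H")
  expect_error(site_class(4, 1e-7, 1.5), "g_weight")
  expect_error(protonation_model(site_class(4, 1e-7, 0.25), K_OC = -0.1),
               "K_OC")
  expect_error(stationary_distribution(
    protonation_model(list()), 7), "site class")
})
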