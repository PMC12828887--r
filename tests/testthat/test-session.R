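test_that("window sums cover the grid, reject bad windows, and match a loop oracle", {
  set.seed(1)
  bins <- seq(-300, 590, by = 10)
  counts <- array(rpois(3 * 5 * length(bins), 2),
                  dim = c(3, 5, length(bins)))
  full <- spike_count_window(counts, bins, -300, 600)
  expect_equal(full, rowSums(counts, dims = 2))
  expect_error(spike_count_window(counts, bins, 100, 100), "positive width")
  expect_error(spike_count_window(counts, bins, 105, 205), "align")
  expect_error(spike_count_window(counts, bins, 0, 700), "align")

  for (i in 1:100) {
    u <- sample(1:4, 1); tr <- sample(1:6, 1)
    cc <- array(rpois(u * tr * length(bins), 1), dim = c(u, tr, length(bins)))
    lo <- sample(seq(-300, 580, by = 10), 1)
    hi <- sample(seq(lo + 10, 600, by = 10), 1)
    got <- spike_count_window(cc, bins, lo, hi)
    ref <- matrix(0, u, tr)
    for (uu in 1:u) for (tt in 1:tr) for (b in seq_along(bins)) {
      if (bins[b] >= lo && bins[b] < hi) ref[uu, tt] <- ref[uu, tt] + cc[uu, tt, b]
    }
    expect_equal(got, ref)
  }
})

test_that("the visual screen passes responsive units, fails silent ones, and holds its type-I rate", {
  bins <- seq(-300, 590, by = 10)
  set.seed(2)
  n_tr <- 100L
  ## evoked unit: rate doubles after onset
  evoked <- t(sapply(seq_len(n_tr), function(i) {
    rpois(length(bins), ifelse(bins >= 0, 0.6, 0.3))
  }))
  res <- visual_responsiveness_screen(evoked, bins)
  expect_true(res$pass)

  flat <- matrix(0L, n_tr, length(bins))
  res0 <- visual_responsiveness_screen(flat, bins)
  expect_false(res0$pass)
  expect_equal(res0$flag, "zero_variance")

  ## null units: pass rate should approximate alpha = 0.1
  passes <- vapply(1:300, function(i) {
    null_u <- matrix(rpois(n_tr * length(bins), 0.3), n_tr)
    visual_responsiveness_screen(null_u, bins)$pass
  }, logical(1))
  expect_gt(mean(passes), 0.05)
  expect_lt(mean(passes), 0.16)
})

test_that("repetition modulation arithmetic and session inclusion criteria", {
  s <- make_flat_session(repeat_scale = 0.9, base_count = 10L)
  expect_equal(repetition_modulation_magnitude(s), 10, tolerance = 1e-12)
  s_eq <- make_flat_session(repeat_scale = 1)
  expect_equal(repetition_modulation_magnitude(s_eq), 0)

  ## too few trials
  cfg <- small_study_config()
  short <- simulate_session(cfg, 5L)
  inc_short <- session_inclusion(short, min_trials = 1200L)
  expect_false(inc_short$included)
  expect_false(inc_short$criteria[["min_trials"]])

  ## sub-threshold modulation: exactly 1% < the 2% criterion
  weak <- make_flat_session(repeat_scale = 0.99, base_count = 100L)
  inc_weak <- session_inclusion(weak, min_trials = 10L)
  expect_false(inc_weak$criteria[["modulation"]])

  ## everything met
  ok <- simulate_session(small_study_config(suppression_mean = 0.2), 13L)
  inc_ok <- session_inclusion(ok, min_trials = 100L)
  expect_true(inc_ok$included)
})

test_that("unit d-prime arithmetic, invariances, and degenerate flags", {
  expect_equal(unit_dprime(c(8, 10, 12), c(6, 8, 10)), 1.0)
  expect_equal(unit_dprime(c(3, 5, 9), c(3, 5, 9)), 0)
  set.seed(3)
  nov <- rpois(40, 8); rep_ <- rpois(40, 5)
  expect_equal(unit_dprime(3 * nov, 3 * rep_), unit_dprime(nov, rep_),
               tolerance = 1e-12)
  flagged <- unit_dprime(rep(4, 5), rep(4, 5))
  expect_true(is.na(flagged))
  expect_equal(attr(flagged, "flag"), "zero_sd")
  expect_error(unit_dprime(1, c(2, 3)), "at least 2")
})

test_that("pseudopopulations trim to the shortest session and sort lures by dissimilarity", {
  cfg5 <- small_study_config(n_lure_pairs = 20L, trials = 180L)
  cfg7 <- small_study_config(n_lure_pairs = 28L, trials = 180L)
  s5 <- simulate_session(cfg5, 41L, session_id = 1L)
  s7 <- simulate_session(cfg7, 43L, session_id = 2L)
  pop <- build_pseudopopulation(list(s5, s7), seed = 4L)
  expect_equal(dim(pop$blocks$lure)[2], 20L)          # min rule
  expect_false(is.unsorted(pop$lure_d))               # ranked alignment
  expect_length(pop$unit_ids, 80L)                    # units pooled
  for (blk in pop$blocks) {
    expect_equal(dim(blk)[1], 80L)
    expect_equal(dim(blk)[3], length(pop$time_bins_ms))
  }
})

test_that("alignment permutes trials without editing any spike count", {
  cfg <- small_study_config(n_lure_pairs = 15L, trials = 160L)
  s <- simulate_session(cfg, 47L)
  pop <- build_pseudopopulation(list(s), seed = 6L)
  ## single session, no ablation: each unit's lure-block multiset must equal
  ## the multiset of its lure-trial counts in the raw session
  lure_trials <- s$trials$trial_id[s$trials$condition == "lure"]
  w_pop <- spike_count_window(pop$blocks$lure, pop$time_bins_ms, 300, 500)
  w_raw <- spike_count_window(s$counts[, lure_trials, , drop = FALSE],
                              s$time_bins_ms, 300, 500)
  for (u in seq_len(nrow(w_pop))) {
    expect_equal(sort(w_pop[u, ]), sort(w_raw[u, ]))
  }
})

test_that("ablation is reproducible under a fixed seed", {
  cfg <- small_study_config(n_lure_pairs = 30L)
  st <- simulate_study(cfg)
  p1 <- build_pseudopopulation(st$sessions, seed = 11L)
  p2 <- build_pseudopopulation(st$sessions, seed = 11L)
  expect_identical(p1$blocks, p2$blocks)
  expect_identical(p1$lure_d, p2$lure_d)
})
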