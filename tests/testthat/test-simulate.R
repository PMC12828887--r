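test_that("a fixed seed reproduces a session exactly; different seeds differ", {
  cfg <- small_study_config()
  a <- simulate_session(cfg, 123L)
  b <- simulate_session(cfg, 123L)
  expect_identical(a$counts, b$counts)
  expect_identical(a$trials, b$trials)
  c_ <- simulate_session(cfg, 124L)
  expect_false(identical(a$counts, c_$counts))
})

test_that("with zero suppression, novel and repeat responses are indistinguishable", {
  cfg <- small_study_config(suppression_mean = 0, suppression_sd = 0,
                            frac_enhancement_units = 0)
  s <- simulate_session(cfg, 7L)
  w <- spike_count_window(s$counts, s$time_bins_ms, 300, 500)
  nov <- as.numeric(w[, s$trials$condition == "novel_exact"])
  rep_ <- as.numeric(w[, s$trials$condition == "repeat_exact"])
  expect_gt(t.test(nov, rep_)$p.value, 0.01)
})

test_that("suppression makes behavioral PCR fall with dissimilarity", {
  cfg <- small_study_config(suppression_mean = 0.1, lapse_rate = 0, seed = 3L)
  s <- simulate_session(cfg, 11L)
  tr <- s$trials
  pcr_repeat <- mean(tr$choice[tr$condition == "repeat_exact"] == "repeated")
  lure <- tr[tr$condition == "lure", ]
  pcr_far <- mean(lure$choice[lure$d > median(lure$d)] == "repeated")
  expect_lt(pcr_far, pcr_repeat)
})

test_that("first-presentation responses do not depend on the pair's dissimilarity", {
  cfg <- sim_config(n_sessions = 1L, units_per_session = 60L, trials = 800L,
                    n_exact_pairs = 100L, n_lure_pairs = 300L, seed = 5L)
  s <- simulate_session(cfg, 21L)
  w <- spike_count_window(s$counts, s$time_bins_ms, 300, 500)
  tot <- colSums(w)
  first <- s$trials$condition == "novel_lure"
  expect_gt(cor.test(tot[first], s$trials$d[first])$p.value, 0.01)
})

test_that("without enhancement units every unit's expected repeat response is suppressed", {
  cfg <- small_study_config(frac_enhancement_units = 0)
  st <- simulate_study(cfg)
  for (s in st$sessions) {
    expect_true(all(s$units$suppression >= 0))
  }
  ## empirically, the pooled repeat mean sits below the pooled novel mean
  s <- st$sessions[[1]]
  w <- spike_count_window(s$counts, s$time_bins_ms, 300, 500)
  expect_lt(mean(w[, s$trials$condition == "repeat_exact"]),
            mean(w[, s$trials$condition == "novel_exact"]))
})

test_that("population mean d-prime grows with the suppression level", {
  mean_dprime <- function(sup) {
    cfg <- sim_config(n_sessions = 1L, units_per_session = 220L,
                      trials = 400L, n_exact_pairs = 150L,
                      n_lure_pairs = 50L, suppression_mean = sup,
                      suppression_sd = 0.05, frac_enhancement_units = 0,
                      seed = 2L)
    s <- simulate_session(cfg, 31L)
    w <- spike_count_window(s$counts, s$time_bins_ms, 300, 500)
    nov <- w[, s$trials$condition == "novel_exact"]
    rep_ <- w[, s$trials$condition == "repeat_exact"]
    mean(unit_dprimes(nov, rep_), na.rm = TRUE)
  }
  d <- vapply(c(0.05, 0.15, 0.35), mean_dprime, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("a study keeps image ids disjoint across sessions and records ground truth", {
  cfg <- small_study_config()
  st <- simulate_study(cfg)
  expect_length(st$sessions, 2L)
  ids <- lapply(st$sessions, function(s) s$trials$image_id)
  expect_length(intersect(ids[[1]], ids[[2]]), 0L)
  expect_equal(st$ground_truth$sharpening, 0, tolerance = 1e-12)
  expect_equal(nrow(st$ground_truth$units),
               cfg$n_sessions * cfg$units_per_session)
})

test_that("the gaussian noise option produces non-negative integer counts", {
  cfg <- small_study_config(noise = "gaussian")
  s <- simulate_session(cfg, 17L)
  expect_true(all(s$counts >= 0))
  expect_true(all(s$counts == round(s$counts)))
})

test_that("config validation rejects impossible compositions", {
  expect_error(sim_config(trials = 100L, n_exact_pairs = 60L,
                          n_lure_pairs = 20L), "at least 2")
  expect_error(sim_config(lapse_rate = 1.5), "fractions")
  expect_error(sim_config(lure_d_range = c(0, 1)), "lure_d_range")
})

test_that("session composition reproduces the task's reward asymmetry", {
  comp <- session_composition()
  expect_equal(comp$n_trials, 1500L)
  expect_equal(round(100 * comp$novel_rewarded_fraction), 57)
  expect_equal(round(100 * comp$lure_fraction), 13)
})
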