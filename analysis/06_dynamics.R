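#!/usr/bin/env Rscript
# Sharpening dynamics: 21 sliding 200-ms windows (centers -100..500 ms),
# latency of the 0.1 threshold crossing per iteration, and a Welch t test
# comparing latencies between two simulated regions with different
# suppression ramps (a fast- and a slow-ramping population).

source(file.path("analysis", "00_config.R"))

make_pop <- function(ramp_t50, seed) {
  cfg <- sim_config(n_sessions = 6L, units_per_session = 24L,
                    transfer = transfer_profile("power", 3),
                    ramp_t50_ms = ramp_t50, seed = seed)
  st <- simulate_study(cfg)
  kept <- Filter(function(s) session_inclusion(s)$included, st$sessions)
  build_pseudopopulation(kept, target_nbacks = 23:26, seed = seed)
}

cat("Simulating a fast-ramping (t50 = 180 ms) and a slow-ramping (t50 = 260 ms) population...\n")
pops <- list(fast = make_pop(180, seed = 51L),
             slow = make_pop(260, seed = 52L))

lat <- list()
for (nm in names(pops)) {
  tc <- sliding_window_sharpening(pops[[nm]], n_iterations = 60L,
                                  seed = 61L)
  write.csv(data.frame(center_ms = tc$centers_ms, mean = tc$mean,
                       se = tc$se, accuracy = tc$accuracy),
            file.path(RESULTS_DIR, sprintf("dynamics_%s.csv", nm)),
            row.names = FALSE)
  lat[[nm]] <- sharpening_latency(tc, threshold = 0.1)
  cat(sprintf(
    "%s ramp: peak accuracy %.3f; sharpening first crosses 0.1 at %.0f ms (mean over %d iterations;\n  %d pre-onset crossings excluded, %d never crossed)\n",
    nm, tc$peak_accuracy, mean(lat[[nm]]), length(lat[[nm]]),
    attr(lat[[nm]], "n_excluded_preonset"),
    attr(lat[[nm]], "n_never_crossed")))
}

cmp <- compare_latencies(lat$fast, lat$slow)
cat(sprintf("\nLatency comparison (Welch): t(%.2f) = %.2f, p = %.3g (fast %.1f ms vs slow %.1f ms)\n",
            cmp$df, cmp$t, cmp$p, cmp$mean_a, cmp$mean_b))
write.csv(data.frame(t = cmp$t, df = cmp$df, p = cmp$p,
                     mean_fast_ms = cmp$mean_a, mean_slow_ms = cmp$mean_b),
          file.path(RESULTS_DIR, "latency_comparison.csv"), row.names = FALSE)
cat("A slower suppression ramp delays the sharpening latency, which the\n")
cat("threshold-crossing analysis detects.\n")
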