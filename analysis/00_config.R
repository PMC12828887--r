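# Shared configuration for the analysis scripts. Every script re-simulates
# the study deterministically from this config (simulation takes seconds;
# storing full spike-count arrays as text is wasteful), so results agree
# across scripts.

library(mnemosharp)

RESULTS_DIR <- file.path("results", "analysis")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# Monkey-1-style study: 1,500-trial sessions (450 exact pairs, 160 lure
# pairs, N-backs 23-26), 24 units per session. The transfer function is the
# sharpened regime the experiment is designed to detect.
study_config <- function(transfer = transfer_profile("power", 3),
                         seed = 2026L) {
  sim_config(n_sessions = 6L, units_per_session = 24L,
             transfer = transfer, seed = seed)
}

get_study <- local({
  cache <- new.env()
  function(transfer = transfer_profile("power", 3), seed = 2026L) {
    key <- paste(transfer$family, transfer$gamma, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_study(study_config(transfer, seed))
    }
    cache[[key]]
  }
})
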