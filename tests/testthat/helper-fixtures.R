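# Shared fixtures for the test suite. Everything is generated in code at
# test time; sizes are kept small so individual files run in seconds.

# A small but decodable study: 80 units, 60 exact / 40 lure pairs.
small_study_config <- function(...) {
  args <- utils::modifyList(
    list(n_sessions = 2L, units_per_session = 40L, trials = 200L,
         n_exact_pairs = 60L, n_lure_pairs = 40L),
    list(...))
  do.call(sim_config, args)
}

# The parameter-recovery study condition: 200 units across 5 sessions,
# 150 exact and 100 lure pairs per session.
recovery_config <- function(transfer = transfer_profile("linear"), ...) {
  args <- utils::modifyList(
    list(n_sessions = 5L, units_per_session = 40L, trials = 500L,
         n_exact_pairs = 150L, n_lure_pairs = 100L, transfer = transfer),
    list(...))
  do.call(sim_config, args)
}

# Hand-built session with exact control over the counts array, for
# screening/arithmetic tests. `novel_mult`/`repeat_mult` scale a constant
# per-bin count in the 300-500 ms window.
make_flat_session <- function(n_units = 2L, n_pairs = 20L,
                              base_count = 4L,
                              repeat_scale = 0.9,
                              n_extra_trials = 0L,
                              time_bins_ms = seq(-300, 590, by = 10)) {
  n_trials <- 2L * n_pairs + n_extra_trials
  counts <- array(0L, dim = c(n_units, n_trials, length(time_bins_ms)))
  win <- which(time_bins_ms >= 300 & time_bins_ms < 500)
  counts[, seq_len(n_pairs), win] <- base_count
  counts[, n_pairs + seq_len(n_pairs), win] <-
    as.integer(round(base_count * repeat_scale))
  if (n_extra_trials > 0) {
    counts[, 2L * n_pairs + seq_len(n_extra_trials), win] <- base_count
  }
  trials <- data.frame(
    condition = c(rep("novel_exact", n_pairs), rep("repeat_exact", n_pairs),
                  rep("filler", n_extra_trials)),
    pair_id = c(paste0("e", seq_len(n_pairs)), paste0("e", seq_len(n_pairs)),
                rep(NA_character_, n_extra_trials)),
    image_id = seq_len(n_trials),
    d = c(rep(0, 2L * n_pairs), rep(NA_real_, n_extra_trials)),
    m = 0, n_back = 8L,
    trial_id = seq_len(n_trials),
    valid = TRUE,
    choice = "novel", correct = NA)
  structure(list(session_id = 1L, region = "ITC", trials = trials,
                 counts = counts, time_bins_ms = time_bins_ms,
                 units = data.frame(unit_id = seq_len(n_units))),
            class = "session_recording")
}

# Brute-force oracle for the leave-one-out correlation classifier.
loo_oracle <- function(features, labels) {
  labels <- as.character(labels)
  n <- nrow(features)
  correct <- logical(n)
  for (i in seq_len(n)) {
    train_f <- features[-i, , drop = FALSE]
    train_l <- labels[-i]
    best <- NA_character_
    best_r <- -Inf
    for (lab in sort(unique(labels))) {
      proto <- colMeans(train_f[train_l == lab, , drop = FALSE])
      r <- stats::cor(features[i, ], proto)
      if (!is.na(r) && r > best_r) { best_r <- r; best <- lab }
    }
    correct[i] <- identical(best, labels[i])
  }
  mean(correct)
}
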