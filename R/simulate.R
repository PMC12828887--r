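#' Simulate one recording session
#'
#' Generates a trial table and a unit x trial x time-bin spike-count array
#' for a single session of the modified mnemonic similarity task. The trial
#' table contains novel/exact-repeat pairs (dissimilarity 0), novel/lure
#' pairs (dissimilarity drawn uniformly from `config$lure_d_range`) at
#' N-backs drawn from `config$target_nback_set`, and filler trials (standing
#' in for vigilance trials and lure repeats; excluded from analysis).
#'
#' Spike counts in each bin are Poisson (or matched-moment Gaussian) draws
#' with rate `baseline_i + gain_i * v(t) * (1 - s_i * r(t) * m(d))` for the
#' second presentation of a pair and without the suppression term for first
#' presentations and fillers; `v(t)` is a visual-response envelope rising
#' ~80 ms after onset and decaying after stimulus offset (500 ms), `r(t)` a
#' logistic suppression ramp reaching ~1 by
#' `ramp_t50_ms + ramp_width_ms` ms.
#'
#' Behavioral choices are a logistic read-out of the z-scored population
#' total spike count in the 300--500 ms decision window, mixed with a lapse:
#' `P(choose repeat) = (1 - lapse) * plogis(-behav_slope * z) + lapse / 2`.
#'
#' @param config A [sim_config()].
#' @param session_seed Integer seed for this session (see [simulate_study()]
#'   for the derivation from the master seed).
#' @param session_id Identifier stored on the result.
#' @param image_id_offset First image id minus one; lets studies keep image
#'   ids disjoint across sessions.
#' @return An object of class `session_recording`: a list with `trials`
#'   (data.frame), `counts` (unit x trial x bin integer array),
#'   `time_bins_ms` (left bin edges), `units` (per-unit ground-truth
#'   parameters), `region`, `session_id`.
#' @export
simulate_session <- function(config, session_seed, session_id = 1L,
                             image_id_offset = 0L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(session_seed) %% .Machine$integer.max)

  U <- config$units_per_session
  Tn <- config$trials
  bins <- seq(config$window_ms[1], config$window_ms[2] - config$bin_ms,
              by = config$bin_ms)
  B <- length(bins)
  dt <- config$bin_ms / 1000

  ## -- unit ground truth ----------------------------------------------------
  baseline <- stats::rlnorm(U, config$baseline_meanlog, config$baseline_sdlog)
  gain <- stats::rlnorm(U, config$gain_meanlog, config$gain_sdlog)
  s <- stats::rnorm(U, config$suppression_mean, config$suppression_sd)
  s <- pmin(pmax(s, 0), 0.95)
  n_enh <- round(config$frac_enhancement_units * U)
  if (n_enh > 0) {
    enh <- sample.int(U, n_enh)
    s[enh] <- -s[enh]
  }
  units <- data.frame(
    unit_id = seq_len(U), baseline = baseline, gain = gain, suppression = s)

  ## -- trial table ----------------------------------------------------------
  nE <- config$n_exact_pairs
  nL <- config$n_lure_pairs
  n_fill <- Tn - 2L * (nE + nL)
  lure_d <- stats::runif(nL, config$lure_d_range[1], config$lure_d_range[2])
  m_lure <- memory_transfer(lure_d, config$transfer)

  pick_nback <- function(n) {
    config$target_nback_set[sample.int(length(config$target_nback_set), n,
                                       replace = TRUE)]
  }
  exact_first <- data.frame(
    condition = "novel_exact", pair_id = paste0("e", seq_len(nE)),
    image_id = image_id_offset + seq_len(nE),
    d = 0, m = 0, n_back = pick_nback(nE))
  exact_second <- data.frame(
    condition = "repeat_exact", pair_id = exact_first$pair_id,
    image_id = exact_first$image_id,
    d = 0, m = 1, n_back = exact_first$n_back)
  lure_first <- data.frame(
    condition = "novel_lure", pair_id = paste0("l", seq_len(nL)),
    image_id = image_id_offset + nE + seq_len(nL),
    d = lure_d, m = 0, n_back = pick_nback(nL))
  lure_second <- data.frame(
    condition = "lure", pair_id = lure_first$pair_id,
    image_id = image_id_offset + nE + nL + seq_len(nL),
    d = lure_d, m = m_lure, n_back = lure_first$n_back)
  trials <- rbind(exact_first, exact_second, lure_first, lure_second)
  if (n_fill > 0) {
    trials <- rbind(trials, data.frame(
      condition = "filler", pair_id = NA_character_,
      image_id = image_id_offset + 2L * nL + nE + seq_len(n_fill),
      d = NA_real_, m = 0,
      n_back = sample(c(1L, 2L, 4L), n_fill, replace = TRUE)))
  }
  ## interleave presentation order (no true temporal lags are simulated)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials$trial_id <- seq_len(nrow(trials))
  trials$valid <- TRUE
  rownames(trials) <- NULL

  ## -- spike counts ---------------------------------------------------------
  v <- visual_envelope(bins + config$bin_ms / 2)
  r <- suppression_ramp(bins + config$bin_ms / 2,
                        config$ramp_t50_ms, config$ramp_width_ms)
  ## suppression factor per unit x trial: s_i * m(trial); m = 0 on firsts
  S <- outer(s, trials$m)                         # U x T
  counts <- array(0L, dim = c(U, Tn, B))
  for (b in seq_len(B)) {
    lam <- dt * (baseline + gain * v[b] * pmax(1 - r[b] * S, 0))
    counts[, , b] <- draw_counts(lam, config$noise)
  }

  ## -- behavioral choices ---------------------------------------------------
  dec_bins <- which(bins >= 300 & bins < 500)
  evid <- colSums(rowSums(counts[, , dec_bins, drop = FALSE], dims = 2))
  z <- as.numeric(scale(evid))
  p_rep <- (1 - config$lapse_rate) * stats::plogis(-config$behav_slope * z) +
    config$lapse_rate / 2
  trials$choice <- ifelse(stats::runif(Tn) < p_rep, "repeated", "novel")
  rewarded <- ifelse(trials$condition == "repeat_exact", "repeated",
                     ifelse(trials$condition == "filler", NA, "novel"))
  trials$correct <- trials$choice == rewarded

  structure(list(
    session_id = session_id,
    region = config$region,
    trials = trials,
    counts = counts,
    time_bins_ms = bins,
    units = units
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> id=%s region=%s: %d units x %d trials x %d bins\n",
              x$session_id, x$region, dim(x$counts)[1], dim(x$counts)[2],
              dim(x$counts)[3]))
  invisible(x)
}

draw_counts <- function(lam, noise) {
  n <- length(lam)
  if (noise == "poisson") {
    matrix(stats::rpois(n, lam), nrow = nrow(lam))
  } else {
    matrix(as.integer(round(pmax(stats::rnorm(n, lam, sqrt(lam)), 0))),
           nrow = nrow(lam))
  }
}

#' Visual response envelope
#'
#' Smooth gate that is 0 before ~50 ms after stimulus onset, ~1 during the
#' viewing window, and decays after stimulus offset at 500 ms.
#'
#' @param t_ms Time(s) relative to stimulus onset, ms.
#' @return Values in `[0, 1]`.
#' @export
visual_envelope <- function(t_ms) {
  stats::plogis((t_ms - 80) / 15) * (1 - stats::plogis((t_ms - 560) / 30))
}

#' Repetition-suppression onset ramp
#'
#' Logistic growth of the suppression signal over the viewing window,
#' parameterised by the half-maximum time and the 10--90% rise width; the
#' defaults reach ~0.98 of asymptote by `t50 + width` ms.
#'
#' @param t_ms Time(s) relative to stimulus onset, ms.
#' @param t50_ms Half-maximum time (ms).
#' @param width_ms Rise width (ms).
#' @return Values in `(0, 1)`.
#' @export
suppression_ramp <- function(t_ms, t50_ms = 200, width_ms = 200) {
  stats::plogis(4 * (t_ms - t50_ms) / width_ms)
}

#' Simulate a multi-session study with known ground truth
#'
#' Derives one seed per session from `config$seed` (deterministically, via a
#' seeded draw of session seeds), keeps image ids disjoint across sessions,
#' and records the generative ground truth alongside the recordings.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_study`: list with `sessions` (list of
#'   [simulate_session()] results), `ground_truth` (per-session unit
#'   parameters, per-pair dissimilarities and transfer values, and the
#'   generative sharpening score), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  session_seeds <- sample.int(.Machine$integer.max - 1L, config$n_sessions)
  images_per_session <- config$n_exact_pairs + 2L * config$n_lure_pairs +
    max(config$trials - 2L * (config$n_exact_pairs + config$n_lure_pairs), 0L)
  sessions <- vector("list", config$n_sessions)
  for (i in seq_len(config$n_sessions)) {
    sessions[[i]] <- simulate_session(
      config, session_seeds[i], session_id = i,
      image_id_offset = (i - 1L) * images_per_session)
  }
  gt_units <- do.call(rbind, lapply(sessions, function(s) {
    cbind(session_id = s$session_id, s$units)
  }))
  gt_pairs <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    second <- tr[tr$condition %in% c("repeat_exact", "lure"), ]
    data.frame(session_id = s$session_id, pair_id = second$pair_id,
               condition = second$condition, d = second$d, m = second$m)
  }))
  structure(list(
    sessions = sessions,
    ground_truth = list(
      units = gt_units,
      pairs = gt_pairs,
      sharpening = generative_sharpening(config$transfer),
      session_seeds = session_seeds
    ),
    config = config
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d sessions, transfer=%s(%g), generative sharpening=%.3f\n",
              length(x$sessions), x$config$transfer$family,
              x$config$transfer$gamma, x$ground_truth$sharpening))
  invisible(x)
}

#' Asymptotic session composition
#'
#' Bookkeeping for the task's reward structure. A session is built from
#' exact novel/repeat pairs (2 trials each: rewarded novel then rewarded
#' repeated) and lure sets (3 trials each: a novel image, its lure --
#' rewarded novel because it has never been seen -- and a lure repeat,
#' rewarded repeated). With the standard composition of 450 exact pairs and
#' 200 lure sets per 1,500 trials, the fraction of trials whose rewarded
#' answer is "novel" converges to ~57% and lures make up ~13% of images.
#'
#' @param n_exact_pairs Exact novel/repeat pairs per session.
#' @param n_lure_sets Lure sets (novel image + lure + lure repeat).
#' @return List with `n_trials`, `novel_rewarded_fraction`, `lure_fraction`,
#'   `repeat_rewarded_fraction`.
#' @export
session_composition <- function(n_exact_pairs = 450L, n_lure_sets = 200L) {
  n_trials <- 2L * n_exact_pairs + 3L * n_lure_sets
  novel_rewarded <- n_exact_pairs + 2L * n_lure_sets   # novels + lures
  lures <- n_lure_sets
  list(
    n_trials = n_trials,
    novel_rewarded_fraction = novel_rewarded / n_trials,
    repeat_rewarded_fraction = 1 - novel_rewarded / n_trials,
    lure_fraction = lures / n_trials
  )
}
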