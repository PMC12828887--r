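#' Simulation configuration
#'
#' Bundles every parameter of the synthetic spiking-data generator. The
#' defaults emulate a Monkey-1-style recording session: 1,500 trials per
#' session of which 450 are exact novel/repeat pairs and 160 are novel/lure
#' pairs shown at N-backs drawn uniformly from \{23, 24, 25, 26\}, recorded on
#' a 24-channel probe (24 units/session), with spike counts in 10 ms bins on
#' a -300 to +600 ms peristimulus grid.
#'
#' The response model for unit `i` in time bin `t` is Poisson with rate
#' `baseline_i + gain_i * v(t) * (1 - s_i * r(t) * m(d))` (spikes/s) on
#' second presentations, where `v(t)` is the visual response envelope,
#' `r(t)` the suppression onset ramp, `s_i` the unit's suppression fraction
#' and `m(d)` the memory transfer at the pair's dissimilarity (`m(0) = 1`
#' for exact repeats). First presentations omit the suppression term.
#'
#' @param n_sessions Number of sessions in a simulated study.
#' @param units_per_session Units recorded per session.
#' @param trials Trials per session; must be at least
#'   `2 * (n_exact_pairs + n_lure_pairs)`. Remaining trials are fillers
#'   (standing in for vigilance trials and lure repeats, excluded from
#'   analysis).
#' @param n_exact_pairs Novel/exact-repeat image pairs per session.
#' @param n_lure_pairs Novel/lure image pairs per session.
#' @param target_nback_set Integer set the experimental N-backs are drawn
#'   from (uniformly).
#' @param window_ms Length-2 onset-relative range (ms) of the recording grid.
#' @param bin_ms Spike-count bin width (ms).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-unit
#'   baseline rates (spikes/s).
#' @param gain_meanlog,gain_sdlog Log-normal parameters of per-unit visually
#'   evoked gains (spikes/s).
#' @param suppression_mean,suppression_sd Mean/SD of the per-unit fraction of
#'   the evoked response removed on an exact repeat (truncated to
#'   `[0, 0.95]`).
#' @param frac_enhancement_units Fraction of units whose repetition effect is
#'   enhancement rather than suppression (their `s_i` has its sign flipped).
#' @param ramp_t50_ms,ramp_width_ms Logistic suppression-ramp parameters:
#'   half-maximum time and 10--90% rise width; the defaults reach ~1 by
#'   400 ms after onset.
#' @param transfer A [transfer_profile()]; ground-truth memory transfer.
#' @param lapse_rate Probability a behavioral choice is a coin flip.
#' @param behav_slope Logistic slope of the behavioral read-out on the
#'   z-scored population spike count.
#' @param lure_d_range Range the per-pair lure dissimilarities are drawn
#'   from (uniformly).
#' @param region Region label attached to simulated sessions.
#' @param noise One of `"poisson"` (default) or `"gaussian"`. The Gaussian
#'   option (matched mean and variance, rounded and floored at zero) exists
#'   for unit tests needing closed forms.
#' @param seed Master integer seed; all randomness in a study derives from
#'   it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 10L,
                       units_per_session = 24L,
                       trials = 1500L,
                       n_exact_pairs = 450L,
                       n_lure_pairs = 160L,
                       target_nback_set = c(23L, 24L, 25L, 26L),
                       window_ms = c(-300, 600),
                       bin_ms = 10,
                       baseline_meanlog = log(5),
                       baseline_sdlog = 0.5,
                       gain_meanlog = log(10),
                       gain_sdlog = 0.5,
                       suppression_mean = 0.15,
                       suppression_sd = 0.10,
                       frac_enhancement_units = 0.1,
                       ramp_t50_ms = 200,
                       ramp_width_ms = 200,
                       transfer = transfer_profile("linear"),
                       lapse_rate = 0.05,
                       behav_slope = 4,
                       lure_d_range = c(0.05, 0.95),
                       region = "ITC",
                       noise = c("poisson", "gaussian"),
                       seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(
    n_sessions = as.integer(n_sessions),
    units_per_session = as.integer(units_per_session),
    trials = as.integer(trials),
    n_exact_pairs = as.integer(n_exact_pairs),
    n_lure_pairs = as.integer(n_lure_pairs),
    target_nback_set = as.integer(target_nback_set),
    window_ms = as.numeric(window_ms),
    bin_ms = as.numeric(bin_ms),
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    gain_meanlog = gain_meanlog,
    gain_sdlog = gain_sdlog,
    suppression_mean = suppression_mean,
    suppression_sd = suppression_sd,
    frac_enhancement_units = frac_enhancement_units,
    ramp_t50_ms = ramp_t50_ms,
    ramp_width_ms = ramp_width_ms,
    transfer = transfer,
    lapse_rate = lapse_rate,
    behav_slope = behav_slope,
    lure_d_range = as.numeric(lure_d_range),
    region = region,
    noise = noise,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1
  if (!pos_count(cfg$n_sessions) || !pos_count(cfg$units_per_session) ||
      !pos_count(cfg$trials) || !pos_count(cfg$n_exact_pairs) ||
      !pos_count(cfg$n_lure_pairs)) {
    stop("session/unit/trial/pair counts must be positive integers",
         call. = FALSE)
  }
  if (cfg$trials < 2L * (cfg$n_exact_pairs + cfg$n_lure_pairs)) {
    stop("`trials` must be at least 2 * (n_exact_pairs + n_lure_pairs)",
         call. = FALSE)
  }
  frac_ok <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!frac_ok(cfg$frac_enhancement_units) || !frac_ok(cfg$lapse_rate)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!frac_ok(cfg$suppression_mean) || cfg$suppression_sd < 0) {
    stop("suppression_mean in [0, 1]; suppression_sd >= 0", call. = FALSE)
  }
  if (length(cfg$window_ms) != 2L || diff(cfg$window_ms) <= 0 ||
      cfg$bin_ms <= 0 ||
      (diff(cfg$window_ms) %% cfg$bin_ms) != 0) {
    stop("`window_ms` must span a positive multiple of `bin_ms`",
         call. = FALSE)
  }
  if (length(cfg$lure_d_range) != 2L ||
      cfg$lure_d_range[1] <= 0 || cfg$lure_d_range[2] > 1 ||
      diff(cfg$lure_d_range) <= 0) {
    stop("`lure_d_range` must be an increasing range within (0, 1]",
         call. = FALSE)
  }
  if (!inherits(cfg$transfer, "transfer_profile")) {
    stop("`transfer` must be a transfer_profile", call. = FALSE)
  }
  if (any(cfg$target_nback_set < 1L)) {
    stop("`target_nback_set` entries must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d sessions x %d units, %d trials ",
           "(%d exact + %d lure pairs), transfer=%s(%g), ",
           "suppression=%.2f+/-%.2f, seed=%d\n"),
    x$n_sessions, x$units_per_session, x$trials,
    x$n_exact_pairs, x$n_lure_pairs,
    x$transfer$family, x$transfer$gamma,
    x$suppression_mean, x$suppression_sd, x$seed))
  invisible(x)
}
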