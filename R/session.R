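#' Spike counts in a time window
#'
#' Sums a unit x trial x time-bin count array over a half-open window
#' `[start_ms, stop_ms)` relative to stimulus onset. The window must align
#' with bin edges and lie on the recorded grid.
#'
#' @param counts Unit x trial x bin array.
#' @param time_bins_ms Left edges of the bins (uniform grid).
#' @param start_ms,stop_ms Window bounds (ms), `start_ms < stop_ms`.
#' @return A unit x trial matrix of summed counts.
#' @export
spike_count_window <- function(counts, time_bins_ms, start_ms, stop_ms) {
  stopifnot(length(dim(counts)) == 3L,
            dim(counts)[3] == length(time_bins_ms))
  bin <- unique(round(diff(time_bins_ms), 9))
  if (length(bin) != 1L) stop("bin grid must be uniform", call. = FALSE)
  if (start_ms >= stop_ms) stop("window must have positive width", call. = FALSE)
  grid_start <- time_bins_ms[1]
  grid_stop <- time_bins_ms[length(time_bins_ms)] + bin
  aligned <- function(x) abs((x - grid_start) %% bin) < 1e-9 ||
    abs(bin - (x - grid_start) %% bin) < 1e-9
  if (!aligned(start_ms) || !aligned(stop_ms) ||
      start_ms < grid_start || stop_ms > grid_stop) {
    stop("window [", start_ms, ", ", stop_ms,
         ") must align with bin edges on the recorded grid", call. = FALSE)
  }
  idx <- which(time_bins_ms >= start_ms - 1e-9 & time_bins_ms < stop_ms - 1e-9)
  rowSums(counts[, , idx, drop = FALSE], dims = 2)
}

#' Visual responsiveness screen for one unit
#'
#' Compares per-trial mean firing rates before stimulus onset
#' (`[-300, 0)` ms) and after (`[50, 350)` ms) with a two-sample t test;
#' a unit passes when `p < alpha` (default 0.1).
#'
#' @param counts Unit-sliced trial x bin matrix, or a 3-d array with the
#'   unit in the first dimension when `unit` is given.
#' @param time_bins_ms Left edges of bins.
#' @param unit Unit index when `counts` is 3-d.
#' @param pre_ms,post_ms Comparison windows.
#' @param alpha Pass threshold on the p-value.
#' @return List with `pass`, `p`, and mean rates in each window (spikes/s).
#' @export
visual_responsiveness_screen <- function(counts, time_bins_ms, unit = NULL,
                                         pre_ms = c(-300, 0),
                                         post_ms = c(50, 350),
                                         alpha = 0.1) {
  if (length(dim(counts)) == 3L) {
    stopifnot(!is.null(unit))
    counts <- counts[unit, , , drop = TRUE]
  }
  counts <- array(counts, dim = c(1, dim(counts)))
  bin_s <- (time_bins_ms[2] - time_bins_ms[1]) / 1000
  pre <- spike_count_window(counts, time_bins_ms, pre_ms[1], pre_ms[2])[1, ] /
    (diff(pre_ms) / 1000)
  post <- spike_count_window(counts, time_bins_ms, post_ms[1], post_ms[2])[1, ] /
    (diff(post_ms) / 1000)
  if (stats::sd(pre) == 0 && stats::sd(post) == 0) {
    return(list(pass = FALSE, p = NA_real_, rate_pre = mean(pre),
                rate_post = mean(post), flag = "zero_variance"))
  }
  p <- stats::t.test(pre, post)$p.value
  list(pass = p < alpha, p = p, rate_pre = mean(pre), rate_post = mean(post),
       flag = NULL)
}

#' Repetition-modulation magnitude of a session
#'
#' Percent change between the session-pooled mean spike count to novel
#' exact-pair images and to their exact repeats, in the 300--500 ms window:
#' `100 * |mean_novel - mean_repeat| / mean_novel`.
#'
#' @param session A `session_recording`.
#' @param window_ms Counting window (default `c(300, 500)`).
#' @return Percent magnitude (scalar); `NA` when the novel mean is zero.
#' @export
repetition_modulation_magnitude <- function(session, window_ms = c(300, 500)) {
  w <- spike_count_window(session$counts, session$time_bins_ms,
                          window_ms[1], window_ms[2])
  tr <- session$trials
  nov <- mean(w[, tr$condition == "novel_exact", drop = FALSE])
  rep_ <- mean(w[, tr$condition == "repeat_exact", drop = FALSE])
  if (!is.finite(nov) || nov == 0) return(NA_real_)
  100 * abs(nov - rep_) / nov
}

#' Session inclusion screen
#'
#' Applies the recording-quality criteria: (1) a minimum number of completed
#' trials (default 1,200); (2) at least one unit passing the visual
#' responsiveness screen (t test, `p < 0.1`); (3) an optional firing-rate
#' drift screen (split-half rate ratio; off by default, replacing a
#' by-inspection stability criterion); (4) a minimum repetition suppression
#' or enhancement magnitude of 2% on exact repeats.
#'
#' @param session A `session_recording`.
#' @param min_trials Minimum completed trials.
#' @param min_modulation_pct Minimum RS/RE magnitude, percent.
#' @param screen_alpha Alpha for the visual screen.
#' @param drift_ratio Maximum allowed split-half rate ratio (larger half /
#'   smaller half); `NULL` (default) disables the drift screen.
#' @return List with `included` (logical) and `criteria`, a named logical
#'   vector (`min_trials`, `visual`, `drift`, `modulation`), plus the
#'   measured `modulation_pct`.
#' @export
session_inclusion <- function(session, min_trials = 1200L,
                              min_modulation_pct = 2,
                              screen_alpha = 0.1,
                              drift_ratio = NULL) {
  tr_ok <- sum(session$trials$valid) >= min_trials
  n_units <- dim(session$counts)[1]
  vis_ok <- FALSE
  for (u in seq_len(n_units)) {
    scr <- visual_responsiveness_screen(session$counts, session$time_bins_ms,
                                        unit = u, alpha = screen_alpha)
    if (isTRUE(scr$pass)) { vis_ok <- TRUE; break }
  }
  drift_ok <- TRUE
  if (!is.null(drift_ratio)) {
    half <- floor(dim(session$counts)[2] / 2)
    r1 <- mean(session$counts[, seq_len(half), , drop = FALSE])
    r2 <- mean(session$counts[, (half + 1):dim(session$counts)[2], ,
                              drop = FALSE])
    drift_ok <- max(r1, r2) / max(min(r1, r2), .Machine$double.eps) <=
      drift_ratio
  }
  mod <- repetition_modulation_magnitude(session)
  mod_ok <- is.finite(mod) && mod >= min_modulation_pct
  crit <- c(min_trials = tr_ok, visual = vis_ok, drift = drift_ok,
            modulation = mod_ok)
  list(included = all(crit), criteria = crit, modulation_pct = mod)
}

#' Unit d-prime for repetition suppression
#'
#' `(mean(novel) - mean(repeat)) / ((sd(novel) + sd(repeat)) / 2)`.
#' Positive values indicate repetition suppression, negative values
#' repetition enhancement.
#'
#' @param novel_counts,repeat_counts Per-trial spike counts of one unit
#'   (>= 2 each).
#' @return Scalar d-prime; `NA` (flagged) when both SDs are zero.
#' @export
unit_dprime <- function(novel_counts, repeat_counts) {
  if (length(novel_counts) < 2L || length(repeat_counts) < 2L) {
    stop("need at least 2 trials per set", call. = FALSE)
  }
  s <- (stats::sd(novel_counts) + stats::sd(repeat_counts)) / 2
  if (s == 0) return(structure(NA_real_, flag = "zero_sd"))
  (mean(novel_counts) - mean(repeat_counts)) / s
}

#' d-prime for every unit of a session or pseudopopulation
#'
#' @param novel,repeat_ Unit x trial count matrices (e.g., from
#'   [spike_count_window()]).
#' @return Numeric vector of d-primes (NA where undefined).
#' @export
unit_dprimes <- function(novel, repeat_) {
  stopifnot(nrow(novel) == nrow(repeat_))
  vapply(seq_len(nrow(novel)), function(u) {
    as.numeric(unit_dprime(novel[u, ], repeat_[u, ]))
  }, numeric(1))
}
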