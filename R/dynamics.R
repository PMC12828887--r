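#' Sliding-window sharpening timecourse
#'
#' Runs the cross-validated decoder in a sequence of (by default 21)
#' 200-ms-wide windows whose centers step from -100 to +500 ms relative to
#' stimulus onset, and computes the per-iteration sharpening value in each
#' window. The performance weight of every window uses a common anchor: the
#' maximum over windows of the mean novel/repeat accuracy (the highest
#' observed classifier performance during the viewing period).
#'
#' @param pop A [build_pseudopopulation()] result whose recording grid
#'   covers every window.
#' @param kind Decoder kind.
#' @param window_ms Window width in ms (default 200).
#' @param centers_ms Window centers (default `seq(-100, 500, by = 30)`,
#'   21 windows).
#' @param n_iterations Cross-validation iterations per window.
#' @param seed Integer seed (one independent stream per window, derived
#'   deterministically).
#' @return An object of class `sharpening_timecourse`: list with
#'   `centers_ms`, `values` (iterations x windows matrix of weighted
#'   sharpening values), `mean`, `se`, `accuracy` (per-window mean),
#'   `peak_accuracy`.
#' @export
sliding_window_sharpening <- function(pop,
                                      kind = c("spike_count", "weighted"),
                                      window_ms = 200,
                                      centers_ms = seq(-100, 500, by = 30),
                                      n_iterations = 100L,
                                      seed = 1L) {
  kind <- match.arg(kind)
  grid_lo <- pop$time_bins_ms[1]
  grid_hi <- pop$time_bins_ms[length(pop$time_bins_ms)] +
    (pop$time_bins_ms[2] - pop$time_bins_ms[1])
  if (min(centers_ms) - window_ms / 2 < grid_lo ||
      max(centers_ms) + window_ms / 2 > grid_hi) {
    stop("window outside the recorded grid", call. = FALSE)
  }
  set.seed(as.integer(seed))
  window_seeds <- sample.int(.Machine$integer.max - 1L, length(centers_ms))

  cvs <- vector("list", length(centers_ms))
  for (wi in seq_along(centers_ms)) {
    cvs[[wi]] <- crossval_run(
      pop, kind = kind, n_iterations = n_iterations,
      window = c(centers_ms[wi] - window_ms / 2,
                 centers_ms[wi] + window_ms / 2),
      seed = window_seeds[wi])
  }
  acc <- vapply(cvs, function(cv) mean(cv$iterations$accuracy), numeric(1))
  peak <- max(acc)
  values <- matrix(NA_real_, nrow = n_iterations, ncol = length(centers_ms))
  for (wi in seq_along(cvs)) {
    sh <- if (peak > 0.5) {
      sharpening_from_crossval(cvs[[wi]], peak_accuracy = peak)$values
    } else {
      rep(0, n_iterations)
    }
    values[, wi] <- sh
  }
  structure(list(
    centers_ms = centers_ms,
    window_ms = window_ms,
    values = values,
    mean = colMeans(values),
    se = apply(values, 2, stats::sd) / sqrt(n_iterations),
    accuracy = acc,
    peak_accuracy = peak,
    kind = kind
  ), class = "sharpening_timecourse")
}

#' @export
print.sharpening_timecourse <- function(x, ...) {
  cat(sprintf(
    "<sharpening_timecourse> %d windows of %g ms (centers %g..%g), peak acc=%.3f, max sharpening=%.3f\n",
    length(x$centers_ms), x$window_ms, min(x$centers_ms), max(x$centers_ms),
    x$peak_accuracy, max(x$mean)))
  invisible(x)
}

#' Sharpening latency per iteration
#'
#' The first window center at which an iteration's sharpening value reaches
#' the threshold (default 0.1), with no interpolation. Iterations whose
#' first crossing falls before stimulus onset (center < 0 ms) are impossible
#' latencies triggered by noise and are excluded; iterations that never
#' cross are missing.
#'
#' @param timecourse A [sliding_window_sharpening()] result.
#' @param threshold Sharpening threshold (default 0.1).
#' @return Numeric vector of latencies (ms) for iterations with a valid
#'   crossing, with attributes `n_excluded_preonset` and `n_never_crossed`.
#' @export
sharpening_latency <- function(timecourse, threshold = 0.1) {
  stopifnot(inherits(timecourse, "sharpening_timecourse"))
  centers <- timecourse$centers_ms
  lat <- apply(timecourse$values, 1, function(v) {
    k <- which(v >= threshold)
    if (!length(k)) NA_real_ else centers[min(k)]
  })
  never <- sum(is.na(lat))
  pre <- sum(!is.na(lat) & lat < 0)
  out <- lat[!is.na(lat) & lat >= 0]
  attr(out, "n_excluded_preonset") <- pre
  attr(out, "n_never_crossed") <- never
  out
}

#' Compare latency distributions between regions
#'
#' Welch two-sample, two-sided t test on two latency distributions (e.g.
#' hippocampus versus inferotemporal cortex).
#'
#' @param latencies_a,latencies_b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df` (fractional, Welch), `p`, and the two group
#'   means.
#' @export
compare_latencies <- function(latencies_a, latencies_b) {
  if (length(latencies_a) < 2L || length(latencies_b) < 2L) {
    stop("need at least 2 latencies per group", call. = FALSE)
  }
  tt <- stats::t.test(latencies_a, latencies_b)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean_a = mean(latencies_a), mean_b = mean(latencies_b))
}
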