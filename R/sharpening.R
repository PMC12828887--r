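#' Percent-chose-repeat curve
#'
#' A PCR-versus-dissimilarity curve with its exact-repeat endpoint at
#' `d = 0`, its novel endpoint at `d = 1`, and interior lure points in
#' between. The endpoint PCRs serve as the anchors for rescaling: the
#' repeat-endpoint PCR is the hit rate, the novel-endpoint PCR the
#' false-alarm rate.
#'
#' @param d Strictly increasing dissimilarities; `d[1] == 0`,
#'   `d[length(d)] == 1`.
#' @param pcr PCR values in `[0, 1]`, one per `d`.
#' @param source `"behavior"` or `"classifier"` (annotation only).
#' @return An object of class `pcr_curve`.
#' @export
pcr_curve <- function(d, pcr, source = c("classifier", "behavior")) {
  source <- match.arg(source)
  stopifnot(length(d) == length(pcr), length(d) >= 2L)
  if (is.unsorted(d, strictly = TRUE)) {
    stop("`d` must be strictly increasing", call. = FALSE)
  }
  if (d[1] != 0 || d[length(d)] != 1) {
    stop("curve needs endpoints at d = 0 (repeat) and d = 1 (novel)",
         call. = FALSE)
  }
  if (any(!is.finite(pcr)) || any(pcr < 0 | pcr > 1)) {
    stop("`pcr` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    d = as.numeric(d), pcr = as.numeric(pcr), source = source,
    pcr_repeat = pcr[1], pcr_novel = pcr[length(pcr)],
    novel_accuracy = 1 - pcr[length(pcr)], repeat_accuracy = pcr[1]
  ), class = "pcr_curve")
}

#' @export
print.pcr_curve <- function(x, ...) {
  cat(sprintf("<pcr_curve> source=%s, %d points; anchors: repeat PCR=%.2f, novel PCR=%.2f\n",
              x$source, length(x$d), x$pcr_repeat, x$pcr_novel))
  invisible(x)
}

#' Weighted signed-area sharpening metric
#'
#' Quantifies how strongly a PCR curve deviates from the linear benchmark
#' joining its repeat and novel endpoints:
#' 1. All PCRs are anchor-rescaled ([rescale_predictions()]) so the curve
#'    `y(d)` runs from `y(0) = 0` to `y(1) = 1` (rescaled "novelness").
#' 2. The signed area `A = integral of (y(d) - d)` is computed by the
#'    trapezoidal rule over the curve's points (no smoothing), and doubled,
#'    so a maximally sharpened step curve scores +1 and a maximally
#'    broadened one -1.
#' 3. The raw score is weighted by
#'    `((acc - 0.5) / (peak_accuracy - 0.5))^2` clipped to `[0, 1]`, with
#'    `acc` the mean of the curve's novel and repeat accuracies: 1 at the
#'    highest observed classifier performance, 0 at chance.
#'
#' Positive values indicate sharpening (lures treated more novel than the
#' linear benchmark), negative values broadening, 0 no deviation. When the
#' anchors coincide (chance performance) the value is 0 with weight 0.
#'
#' @param curve A [pcr_curve()].
#' @param peak_accuracy Weighting anchor, > 0.5: for a single-window
#'   analysis the analysis's own mean accuracy; for sliding-window dynamics
#'   the maximum mean accuracy over windows.
#' @return An object of class `sharpening_result`: list with `value`
#'   (= `weight * raw`), `raw`, `weight`, `accuracy`, `degenerate`.
#' @export
sharpening_metric <- function(curve, peak_accuracy) {
  stopifnot(inherits(curve, "pcr_curve"))
  if (!is.numeric(peak_accuracy) || peak_accuracy <= 0.5) {
    stop("`peak_accuracy` must exceed chance (0.5)", call. = FALSE)
  }
  y <- rescale_predictions(curve$pcr, curve$pcr_novel, curve$pcr_repeat)
  acc <- (curve$novel_accuracy + curve$repeat_accuracy) / 2
  if (isTRUE(attr(y, "degenerate"))) {
    return(structure(list(value = 0, raw = 0, weight = 0, accuracy = acc,
                          degenerate = TRUE), class = "sharpening_result"))
  }
  ## the doubled signed area lies in [-1, 1] whenever lure performance is
  ## intermediate to the anchors; near-chance anchors can push the rescaled
  ## curve outside that range, so the raw score is clipped to the metric's
  ## defined range
  raw <- min(max(2 * trapz(curve$d, y - curve$d), -1), 1)
  weight <- min(max(((acc - 0.5) / (peak_accuracy - 0.5))^2, 0), 1)
  structure(list(value = weight * raw, raw = raw, weight = weight,
                 accuracy = acc, degenerate = FALSE),
            class = "sharpening_result")
}

#' @export
print.sharpening_result <- function(x, ...) {
  cat(sprintf("<sharpening_result> value=%.3f (raw=%.3f, weight=%.2f, acc=%.3f)\n",
              x$value, x$raw, x$weight, x$accuracy))
  invisible(x)
}

#' Per-iteration sharpening of a cross-validation run
#'
#' Builds, for every iteration of a [crossval_run()], the PCR curve through
#' the repeat endpoint, the three lure-bin points (at the bins' mean
#' dissimilarities) and the novel endpoint, and applies
#' [sharpening_metric()].
#'
#' @param cv A [crossval_run()] result.
#' @param peak_accuracy Weighting anchor; default: the run's mean accuracy
#'   across iterations (single-window convention). When the default anchor
#'   does not exceed chance the run is degenerate and all values are 0.
#' @return List with `values` (per iteration), `mean`, `se`, `raw_mean`,
#'   `peak_accuracy`.
#' @export
sharpening_from_crossval <- function(cv, peak_accuracy = NULL) {
  stopifnot(inherits(cv, "crossval_result"))
  it <- cv$iterations
  if (is.null(peak_accuracy)) peak_accuracy <- mean(it$accuracy)
  n_bins <- length(cv$bin_mean_d)
  pcr_cols <- paste0("pcr_bin", seq_len(n_bins))
  vals <- raws <- numeric(nrow(it))
  for (i in seq_len(nrow(it))) {
    if (peak_accuracy <= 0.5 || it$pcr_novel[i] == it$pcr_repeat[i]) {
      vals[i] <- 0; raws[i] <- 0
      next
    }
    ## interior points must be strictly inside (0, 1) on the d axis
    crv <- pcr_curve(c(0, cv$bin_mean_d, 1),
                     c(it$pcr_repeat[i],
                       as.numeric(it[i, pcr_cols]),
                       it$pcr_novel[i]))
    m <- sharpening_metric(crv, peak_accuracy)
    vals[i] <- m$value; raws[i] <- m$raw
  }
  list(values = vals, mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       raw_mean = mean(raws), peak_accuracy = peak_accuracy)
}

#' Session-averaged behavioral PCR curve
#'
#' Computes, per session, the percent-chose-repeat for exact repeats
#' (`d = 0` endpoint), novel exact images (`d = 1` endpoint) and ranked
#' lure-dissimilarity bins, then averages across sessions with 95%
#' confidence intervals (`mean +/- 1.96 * SEM`). Filler trials are
#' excluded.
#'
#' @param sessions List of `session_recording` objects (>= 1; CIs need
#'   >= 2).
#' @param n_bins Number of lure-dissimilarity bins.
#' @param target_nbacks Optional N-back filter.
#' @return List with `table` (condition, mean d, PCR, CI bounds) and
#'   `curve` (a [pcr_curve()] through the session means).
#' @export
behavioral_pcr_curve <- function(sessions, n_bins = 3L,
                                 target_nbacks = NULL) {
  stopifnot(length(sessions) >= 1L)
  per_session <- lapply(sessions, function(s) {
    tr <- s$trials
    keep <- tr$valid & tr$condition != "filler"
    if (!is.null(target_nbacks)) keep <- keep & tr$n_back %in% target_nbacks
    tr <- tr[keep, , drop = FALSE]
    lure <- tr[tr$condition == "lure", , drop = FALSE]
    lure <- lure[order(lure$d), , drop = FALSE]
    bins <- rep(seq_len(n_bins), lure_bin_sizes(nrow(lure), n_bins))
    pcr_of <- function(x) mean(x$choice == "repeated")
    c(repeat_exact = pcr_of(tr[tr$condition == "repeat_exact", ]),
      stats::setNames(
        vapply(seq_len(n_bins), function(b) pcr_of(lure[bins == b, ]),
               numeric(1)), paste0("lure_bin", seq_len(n_bins))),
      novel_exact = pcr_of(tr[tr$condition == "novel_exact", ]),
      stats::setNames(
        vapply(seq_len(n_bins), function(b) mean(lure$d[bins == b]),
               numeric(1)), paste0("d_bin", seq_len(n_bins))))
  })
  mat <- do.call(rbind, per_session)
  n_s <- nrow(mat)
  mu <- colMeans(mat)
  sem <- apply(mat, 2, stats::sd) / sqrt(n_s)
  ci <- if (n_s >= 2L) 1.96 * sem else rep(NA_real_, length(mu))
  pcr_names <- c("repeat_exact", paste0("lure_bin", seq_len(n_bins)),
                 "novel_exact")
  d_vals <- c(0, mu[paste0("d_bin", seq_len(n_bins))], 1)
  tab <- data.frame(
    condition = pcr_names,
    d = as.numeric(d_vals),
    pcr = as.numeric(mu[pcr_names]),
    ci_lo = as.numeric(mu[pcr_names] - ci[pcr_names]),
    ci_hi = as.numeric(mu[pcr_names] + ci[pcr_names]))
  list(table = tab,
       curve = pcr_curve(tab$d, tab$pcr, source = "behavior"),
       n_sessions = n_s)
}
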