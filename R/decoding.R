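#' Train a linear novel/repeat decoder
#'
#' Both decoders are linear discriminants `f(x) = w . x - b` with criterion
#' `b = 0.5 * w . (muN + muR)`, where `muN`, `muR` are the mean population
#' responses to novel and repeated training images. The spike-count decoder
#' uses the homogeneous weight vector `w = (1, ..., 1)` (it reads out total
#' population repetition suppression); the weighted decoder uses the
#' prototype-classifier weights `w = muN - muR`, a Fisher discriminant under
#' isotropic covariance, which can exploit mixtures of suppressed and
#' enhanced units.
#'
#' @param novel_block,repeat_block Unit x trial count matrices of matched
#'   (image-paired) novel and repeated training trials.
#' @param kind `"spike_count"` or `"weighted"`.
#' @return An object of class `linear_decoder`: list with `w`, `b`, `kind`.
#' @export
train_decoder <- function(novel_block, repeat_block,
                          kind = c("spike_count", "weighted")) {
  kind <- match.arg(kind)
  novel_block <- as.matrix(novel_block)
  repeat_block <- as.matrix(repeat_block)
  if (ncol(novel_block) == 0L || ncol(repeat_block) == 0L) {
    stop("empty training set", call. = FALSE)
  }
  if (nrow(novel_block) != nrow(repeat_block)) {
    stop("unit dimensions differ between blocks", call. = FALSE)
  }
  muN <- rowMeans(novel_block)
  muR <- rowMeans(repeat_block)
  w <- if (kind == "spike_count") rep(1, length(muN)) else muN - muR
  b <- 0.5 * sum(w * (muN + muR))
  structure(list(w = w, b = b, kind = kind), class = "linear_decoder")
}

#' @export
print.linear_decoder <- function(x, ...) {
  cat(sprintf("<linear_decoder> kind=%s, %d units, b=%.3f\n",
              x$kind, length(x$w), x$b))
  invisible(x)
}

#' Decoder decision function and classification
#'
#' `decision_function()` returns `f(x) = w . x - b` for one population
#' response vector or each column of a unit x trial matrix.
#' `classify_response()` labels a response `"novel"` when `f(x) >= 0` and
#' `"repeated"` when `f(x) < 0` (ties resolve to novel, so "repeated" means
#' strictly below the criterion).
#'
#' @param x Numeric vector (length = units) or unit x trial matrix.
#' @param decoder A [train_decoder()] result.
#' @return Numeric `f` values / character labels.
#' @export
decision_function <- function(x, decoder) {
  stopifnot(inherits(decoder, "linear_decoder"))
  if (is.matrix(x)) {
    if (nrow(x) != length(decoder$w)) stop("dimension mismatch", call. = FALSE)
    as.numeric(crossprod(decoder$w, x)) - decoder$b
  } else {
    if (length(x) != length(decoder$w)) stop("dimension mismatch", call. = FALSE)
    sum(decoder$w * x) - decoder$b
  }
}

#' @rdname decision_function
#' @export
classify_response <- function(x, decoder) {
  ifelse(decision_function(x, decoder) >= 0, "novel", "repeated")
}

#' Predicted percent-chose-repeat for a test block
#'
#' The fraction of test trials whose decoder value falls strictly below the
#' criterion, i.e. that would be reported "repeated".
#'
#' @param test_block Unit x trial count matrix.
#' @param decoder A [train_decoder()] result.
#' @return PCR in `[0, 1]`.
#' @export
predict_pcr <- function(test_block, decoder) {
  test_block <- as.matrix(test_block)
  if (ncol(test_block) < 1L) stop("need at least one test trial", call. = FALSE)
  mean(decision_function(test_block, decoder) < 0)
}

#' Anchor rescaling of classifier predictions
#'
#' `(C - C_R) / (C_N - C_R)`: maps the repeat anchor to 0 and the novel
#' anchor to 1, so rescaled novel/repeat accuracy is 100% and lure
#' predictions are scaled proportionally.
#'
#' @param C Value(s) to rescale (e.g. lure PCR).
#' @param C_N,C_R Novel and repeat anchor values (must differ).
#' @return Rescaled value(s); `NA` with a `degenerate` attribute when the
#'   anchors coincide (such iterations carry zero weight downstream).
#' @export
rescale_predictions <- function(C, C_N, C_R) {
  if (isTRUE(all.equal(C_N, C_R, tolerance = 0))) {
    return(structure(rep(NA_real_, length(C)), degenerate = TRUE))
  }
  (C - C_R) / (C_N - C_R)
}

#' Ranked-bin sizes for the lure pairs
#'
#' Splits `n` ranked lure pairs into `k` contiguous dissimilarity bins of
#' near-equal size; when `n` is not divisible by `k` the extra pairs go to
#' the lowest-dissimilarity bins first (e.g. 133 pairs -> 45/44/44).
#'
#' @param n Number of lure pairs.
#' @param k Number of bins (default 3).
#' @return Integer vector of bin sizes summing to `n`.
#' @export
lure_bin_sizes <- function(n, k = 3L) {
  base <- n %/% k
  sizes <- rep(base, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

## apply a per-unit column permutation: S[u, j] = M[u, perm[u, j]]
shuffle_rows <- function(M, perm) {
  U <- nrow(M)
  matrix(M[matrix(seq_len(U), U, ncol(M)) + (perm - 1L) * U], nrow = U)
}

rand_perms <- function(U, P, cols = seq_len(P)) {
  if (length(cols) == 1L) return(matrix(cols, U, 1L))
  t(vapply(seq_len(U), function(u) sample(cols), integer(length(cols))))
}

#' Cross-validated decoding of a pseudopopulation
#'
#' The iterative resampling procedure relating neural responses to
#' behavior. Per iteration: (i) each unit's responses are shuffled across
#' pairs within condition -- jointly for the novel/repeat members of each
#' exact pair, and jointly within each of the `n_bins` ranked-dissimilarity
#' lure bins (with the matched novel-lure responses) -- removing artificial
#' within-session correlations; (ii) a holdout of exact pairs equal to the
#' (largest) lure-bin size is reserved; (iii) a decoder is trained on the
#' remaining exact pairs; (iv) percent-chose-repeat is computed for the
#' held-out novel and repeat trials and for each lure bin; (v) lure PCRs are
#' rescaled with the iteration's novel/repeat PCRs as anchors
#' ([rescale_predictions()]).
#'
#' @param pop A [build_pseudopopulation()] result.
#' @param kind Decoder kind, `"spike_count"` (default) or `"weighted"`.
#' @param n_iterations Resampling iterations (default 100).
#' @param window Counting window in ms (default `c(300, 500)`).
#' @param seed Integer seed.
#' @param holdout_size Override for the number of held-out exact pairs
#'   (default: the largest lure-bin size).
#' @param n_bins Number of ranked lure bins (default 3).
#' @return An object of class `crossval_result`: list with `iterations`
#'   (data.frame: per-iteration PCRs, rescaled lure PCRs, accuracy),
#'   `bin_mean_d`, `bin_sizes`, and the run parameters.
#' @export
crossval_run <- function(pop, kind = c("spike_count", "weighted"),
                         n_iterations = 100L, window = c(300, 500),
                         seed = 1L, holdout_size = NULL, n_bins = 3L) {
  kind <- match.arg(kind)
  stopifnot(inherits(pop, "pseudopopulation"), n_iterations >= 1L)
  Xn <- spike_count_window(pop$blocks$novel_exact, pop$time_bins_ms,
                           window[1], window[2])
  Xr <- spike_count_window(pop$blocks$repeat_exact, pop$time_bins_ms,
                           window[1], window[2])
  Xnl <- spike_count_window(pop$blocks$novel_lure, pop$time_bins_ms,
                            window[1], window[2])
  Xl <- spike_count_window(pop$blocks$lure, pop$time_bins_ms,
                           window[1], window[2])
  U <- nrow(Xn); ne <- ncol(Xn); nl <- ncol(Xl)
  sizes <- lure_bin_sizes(nl, n_bins)
  bin_idx <- split(seq_len(nl), rep(seq_len(n_bins), sizes))
  h <- if (is.null(holdout_size)) max(sizes) else as.integer(holdout_size)
  if (h >= ne) {
    stop("lure bin (holdout) larger than available exact pairs",
         call. = FALSE)
  }
  bin_mean_d <- vapply(bin_idx, function(ix) mean(pop$lure_d[ix]), numeric(1))

  set.seed(as.integer(seed))
  res <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    pe <- rand_perms(U, ne)
    Xn_s <- shuffle_rows(Xn, pe)
    Xr_s <- shuffle_rows(Xr, pe)
    Xl_s <- Xl
    for (b in seq_len(n_bins)) {
      cols <- bin_idx[[b]]
      pl <- rand_perms(U, nl, cols)
      Xl_s[, cols] <- shuffle_rows(Xl[, cols, drop = FALSE],
                                   pl - cols[1] + 1L)
    }
    ho <- sample.int(ne, h)
    tr <- setdiff(seq_len(ne), ho)
    dec <- train_decoder(Xn_s[, tr, drop = FALSE], Xr_s[, tr, drop = FALSE],
                         kind)
    pcr_n <- predict_pcr(Xn_s[, ho, drop = FALSE], dec)
    pcr_r <- predict_pcr(Xr_s[, ho, drop = FALSE], dec)
    pcr_b <- vapply(bin_idx, function(ix) {
      predict_pcr(Xl_s[, ix, drop = FALSE], dec)
    }, numeric(1))
    resc <- rescale_predictions(pcr_b, pcr_n, pcr_r)
    res[[it]] <- c(iteration = it, pcr_novel = pcr_n, pcr_repeat = pcr_r,
                   stats::setNames(pcr_b, paste0("pcr_bin", seq_len(n_bins))),
                   stats::setNames(as.numeric(resc),
                                   paste0("rescaled_bin", seq_len(n_bins))),
                   accuracy = ((1 - pcr_n) + pcr_r) / 2,
                   degenerate = as.numeric(isTRUE(attr(resc, "degenerate"))))
  }
  structure(list(
    iterations = as.data.frame(do.call(rbind, res)),
    bin_mean_d = bin_mean_d,
    bin_sizes = sizes,
    kind = kind, window = window, seed = seed, holdout_size = h,
    n_units = U, n_exact = ne, n_lure = nl
  ), class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "<crossval_result> kind=%s, window=[%g,%g) ms, %d iterations: acc=%.3f, rescaled lure PCR = %s\n",
    x$kind, x$window[1], x$window[2], nrow(x$iterations),
    mean(x$iterations$accuracy),
    paste(sprintf("%.2f", colMeans(
      x$iterations[grep("^rescaled_bin", names(x$iterations))],
      na.rm = TRUE)), collapse = "/")))
  invisible(x)
}

#' Classifier performance as ranked units are added
#'
#' Cross-validated novel/repeat accuracy of the weighted decoder as units
#' are added in deciles of the population, ranked by their signed training
#' weight `muN - muR`: `"high"` adds the most-suppressed units first,
#' `"low"` the most-enhanced first, `"random"` in seeded random order.
#' Rankings are recomputed from the training split of every iteration; all
#' rankings share each iteration's shuffle and holdout, so the three curves
#' coincide exactly at 100% of units.
#'
#' @param pop A [build_pseudopopulation()] result (>= 10 units).
#' @param fractions Population fractions to evaluate (default deciles).
#' @param kind Decoder kind (default `"weighted"`).
#' @param n_iterations Resampling iterations.
#' @param window Counting window, ms.
#' @param seed Integer seed.
#' @return Data.frame with `fraction`, `ranking`, `n_units`, `accuracy`
#'   (mean over iterations) and `se`.
#' @export
ranked_unit_curve <- function(pop, fractions = seq(0.1, 1, by = 0.1),
                              kind = c("weighted", "spike_count"),
                              n_iterations = 50L, window = c(300, 500),
                              seed = 1L) {
  kind <- match.arg(kind)
  Xn <- spike_count_window(pop$blocks$novel_exact, pop$time_bins_ms,
                           window[1], window[2])
  Xr <- spike_count_window(pop$blocks$repeat_exact, pop$time_bins_ms,
                           window[1], window[2])
  U <- nrow(Xn); ne <- ncol(Xn)
  if (U < 10L) stop("need at least 10 units", call. = FALSE)
  nl <- ncol(spike_count_window(pop$blocks$lure, pop$time_bins_ms,
                                window[1], window[2]))
  h <- max(lure_bin_sizes(nl))
  if (h >= ne) stop("holdout larger than available exact pairs", call. = FALSE)

  set.seed(as.integer(seed))
  rankings <- c("high", "low", "random")
  acc <- array(NA_real_,
               dim = c(n_iterations, length(fractions), length(rankings)),
               dimnames = list(NULL, NULL, rankings))
  for (it in seq_len(n_iterations)) {
    pe <- rand_perms(U, ne)
    Xn_s <- shuffle_rows(Xn, pe)
    Xr_s <- shuffle_rows(Xr, pe)
    ho <- sample.int(ne, h)
    tr <- setdiff(seq_len(ne), ho)
    muN <- rowMeans(Xn_s[, tr, drop = FALSE])
    muR <- rowMeans(Xr_s[, tr, drop = FALSE])
    w_full <- muN - muR
    orders <- list(high = order(w_full, decreasing = TRUE),
                   low = order(w_full),
                   random = sample.int(U))
    for (fi in seq_along(fractions)) {
      n_keep <- max(1L, ceiling(fractions[fi] * U))
      for (r in rankings) {
        keep <- orders[[r]][seq_len(n_keep)]
        w <- if (kind == "weighted") w_full[keep] else rep(1, n_keep)
        b <- 0.5 * sum(w * (muN[keep] + muR[keep]))
        fN <- as.numeric(crossprod(w, Xn_s[keep, ho, drop = FALSE])) - b
        fR <- as.numeric(crossprod(w, Xr_s[keep, ho, drop = FALSE])) - b
        acc[it, fi, r] <- (mean(fN >= 0) + mean(fR < 0)) / 2
      }
    }
  }
  out <- expand.grid(fraction = fractions, ranking = rankings,
                     stringsAsFactors = FALSE)
  out$n_units <- pmax(1L, ceiling(out$fraction * U))
  out$accuracy <- mapply(function(f, r) {
    mean(acc[, match(f, fractions), r])
  }, out$fraction, out$ranking)
  out$se <- mapply(function(f, r) {
    stats::sd(acc[, match(f, fractions), r]) / sqrt(n_iterations)
  }, out$fraction, out$ranking)
  out
}
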