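#' Representational dissimilarity of two feature vectors
#'
#' Defined as 1 minus the Pearson correlation of the two vectors, the
#' standard representational-similarity-analysis distance. Identical (or
#' perfectly correlated) vectors score 0, anti-correlated vectors 2, and two
#' long independent random vectors score ~1.
#'
#' @param a,b Numeric feature vectors of equal length (>= 2), neither
#'   constant.
#' @return A scalar in `[0, 2]`.
#' @export
representational_dissimilarity <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop("`a` and `b` must be equal-length vectors of length >= 2",
         call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant feature vector", call. = FALSE)
  }
  1 - stats::cor(a, b)
}

#' Within-category dissimilarity matrix
#'
#' Full symmetric matrix of pairwise representational dissimilarities among
#' the images of one object category.
#'
#' @param features Numeric matrix (images x features) with image ids as row
#'   names, or a list of equal-length numeric vectors.
#' @param category Category label stored on the result.
#' @return An object of class `dissimilarity_matrix`: the matrix with zero
#'   diagonal, plus `category` and image ids as dimnames.
#' @export
category_dissimilarity_matrix <- function(features, category = "category") {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  if (nrow(features) < 2L) {
    stop("a category needs at least 2 images", call. = FALSE)
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("img", seq_len(nrow(features)))
  }
  if (any(apply(features, 1, stats::sd) == 0)) {
    stop("correlation undefined for a constant feature vector", call. = FALSE)
  }
  m <- 1 - stats::cor(t(features))
  diag(m) <- 0
  structure(m, category = category, class = c("dissimilarity_matrix", "matrix"))
}

#' Greedy lure-pair selection
#'
#' Repeatedly takes the currently lowest-dissimilarity unpaired pair from a
#' within-category dissimilarity matrix, removes both images, and records
#' the pair's dissimilarity, until no two images remain. Ties are broken
#' lexicographically by (image id, image id). With an odd image count the
#' last image is reported unpaired.
#'
#' @param mat A [category_dissimilarity_matrix()] (or plain symmetric
#'   matrix with image-id dimnames).
#' @return A data.frame (`image_a`, `image_b`, `d`) in selection order, with
#'   attributes `unpaired` (character vector) and `category`.
#' @export
select_lure_pairs <- function(mat) {
  m <- unclass(mat)
  ids <- rownames(m)
  stopifnot(!is.null(ids), nrow(m) == ncol(m))
  active <- ids[order(ids)]
  m <- m[active, active, drop = FALSE]
  out <- list()
  while (length(active) >= 2L) {
    sub <- m[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    ## which.max/min scan column-major: upper triangle in (row-within-column)
    ## order, i.e. ties resolve to the lexicographically smallest id pair
    ## because `active` stays sorted.
    k <- which.min(sub)
    ij <- arrayInd(k, dim(sub))
    a <- active[ij[1]]; b <- active[ij[2]]
    out[[length(out) + 1L]] <- data.frame(
      image_a = min(a, b), image_b = max(a, b), d = sub[k])
    active <- setdiff(active, c(a, b))
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(image_a = character(), image_b = character(), d = numeric())
  attr(pairs, "unpaired") <- active
  attr(pairs, "category") <- attr(mat, "category")
  pairs
}

#' Assign lure pairs to sessions, spread by dissimilarity
#'
#' Stratified round-robin: pairs are sorted by dissimilarity, cut into
#' equal-count strata (one per session pass), and dealt to sessions in
#' rotation so every session receives a comparable spread of
#' dissimilarities, subject to a per-session cap on how often one category
#' may appear.
#'
#' @param pairs A data.frame as returned by [select_lure_pairs()], with an
#'   additional `category` column when pooling several categories.
#' @param n_sessions Number of sessions to fill.
#' @param category_cap Maximum times a category may be used within one
#'   session (default 4).
#' @return The input with a `session` column (NA where the cap forced a
#'   pair to be skipped).
#' @export
assign_pairs_to_sessions <- function(pairs, n_sessions, category_cap = 4L) {
  stopifnot(n_sessions >= 1L)
  if (is.null(pairs$category)) pairs$category <- "category"
  ord <- order(pairs$d)
  pairs$session <- NA_integer_
  usage <- matrix(0L, nrow = n_sessions,
                  ncol = length(unique(pairs$category)),
                  dimnames = list(NULL, unique(pairs$category)))
  sess <- 0L
  for (i in ord) {
    placed <- FALSE
    for (try in seq_len(n_sessions)) {
      cand <- (sess + try - 1L) %% n_sessions + 1L
      if (usage[cand, pairs$category[i]] < category_cap) {
        pairs$session[i] <- cand
        usage[cand, pairs$category[i]] <- usage[cand, pairs$category[i]] + 1L
        sess <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  pairs
}

#' Low-level image-statistics vector
#'
#' The 18-value descriptor used to check that lure dissimilarity is not
#' predictable from trivial image properties: for each of the three color
#' channels (R, G, B order), the mean, variance, skewness, kurtosis, max and
#' min of the pixel values, in that order. Variance is the sample (n - 1)
#' variance; skewness and kurtosis are the standardized third and fourth
#' central moments (kurtosis not excess). A constant channel has undefined
#' skew/kurtosis; both are recorded as 0 and the result carries a
#' `degenerate_channels` attribute.
#'
#' @param pixels Numeric array `height x width x 3`.
#' @return Numeric vector of length 18, named
#'   `<channel>_<statistic>`.
#' @export
lowlevel_stats_vector <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  }
  if (prod(dim(pixels)[1:2]) < 2L) {
    stop("need at least 2 pixels per channel", call. = FALSE)
  }
  stats_one <- function(x) {
    n <- length(x)
    mu <- mean(x)
    v <- stats::var(x)               # sample variance
    m2 <- mean((x - mu)^2)           # population moments for skew/kurtosis
    if (m2 == 0) {
      sk <- 0; ku <- 0
    } else {
      sk <- mean((x - mu)^3) / m2^1.5
      ku <- mean((x - mu)^4) / m2^2
    }
    c(mean = mu, variance = v, skew = sk, kurtosis = ku,
      max = max(x), min = min(x))
  }
  ch_names <- c("R", "G", "B")
  res <- numeric(0)
  degenerate <- character(0)
  for (ch in 1:3) {
    x <- as.numeric(pixels[, , ch])
    if (stats::var(x) == 0) degenerate <- c(degenerate, ch_names[ch])
    s <- stats_one(x)
    names(s) <- paste0(ch_names[ch], "_", names(s))
    res <- c(res, s)
  }
  if (length(degenerate)) {
    warning("constant channel(s): skew/kurtosis recorded as 0 for ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    attr(res, "degenerate_channels") <- degenerate
  }
  res
}

#' Leave-one-out correlation classifier
#'
#' For each held-out item, training items of each label are averaged into a
#' prototype vector and the item is assigned the label whose prototype has
#' the highest Pearson correlation with it. Used as the confound check that
#' three dissimilarity bins cannot be told apart from low-level image
#' statistics (chance benchmark 1/3).
#'
#' @param features Numeric matrix, items x features.
#' @param labels Vector of bin labels, one per item; at least 3 distinct
#'   labels with >= 2 items each.
#' @return Mean leave-one-out accuracy in `[0, 1]`.
#' @export
loo_correlation_classifier <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  lev <- sort(unique(labels))
  if (length(lev) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (any(table(labels) < 2L)) {
    stop("each label needs at least 2 items", call. = FALSE)
  }
  ## per-label feature sums let each leave-one-out prototype be formed by
  ## subtracting the held-out row, avoiding an inner loop over labels
  sums <- rowsum(features, labels)
  ns <- as.integer(table(labels)[rownames(sums)])
  correct <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    protos <- sums
    li <- match(labels[i], rownames(sums))
    protos[li, ] <- protos[li, ] - features[i, ]
    protos <- protos / ifelse(seq_along(ns) == li, ns[li] - 1L, ns)
    rs <- suppressWarnings(stats::cor(features[i, ], t(protos)))
    correct[i] <- rownames(sums)[which.max(rs)] == labels[i]
  }
  mean(correct)
}

#' Chance benchmark of the bin classifier
#'
#' Average [loo_correlation_classifier()] accuracy over repeated random
#' label assignments that carry no information about the features; converges
#' to 1/k for k equal bins.
#'
#' @param features Items x features matrix.
#' @param n_bins Number of equal bins (items must divide evenly).
#' @param n_shuffles Number of random assignments to average over.
#' @param seed Integer seed.
#' @return Mean accuracy over shuffles.
#' @export
classifier_chance_benchmark <- function(features, n_bins = 3L,
                                        n_shuffles = 200L, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n %% n_bins == 0L)
  set.seed(seed)
  base_labels <- rep(paste0("bin", seq_len(n_bins)), each = n / n_bins)
  accs <- vapply(seq_len(n_shuffles), function(i) {
    loo_correlation_classifier(features, sample(base_labels))
  }, numeric(1))
  mean(accs)
}
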