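test_that("representational dissimilarity hits its boundary values", {
  set.seed(1)
  a <- rnorm(100)
  expect_equal(representational_dissimilarity(a, a), 0)
  expect_equal(representational_dissimilarity(a, -a + 3), 2)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(representational_dissimilarity(x, y) - 1), 0.05)
})

test_that("dissimilarity is symmetric and invariant to positive affine rescaling", {
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(representational_dissimilarity(a, b),
                 representational_dissimilarity(b, a))
    expect_equal(representational_dissimilarity(2.5 * a + 1, b),
                 representational_dissimilarity(a, b), tolerance = 1e-12)
  }
  expect_error(representational_dissimilarity(rep(1, 10), rnorm(10)),
               "constant")
  expect_error(representational_dissimilarity(rnorm(5), rnorm(6)),
               "equal-length")
})

test_that("category matrices agree with pairwise recomputation", {
  set.seed(3)
  f <- matrix(rnorm(6 * 12), nrow = 6,
              dimnames = list(paste0("img", 1:6), NULL))
  m <- category_dissimilarity_matrix(f, "cats")
  expect_equal(diag(unclass(m)), setNames(rep(0, 6), rownames(f)))
  expect_equal(unclass(m), t(unclass(m)))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], representational_dissimilarity(f[i, ], f[j, ]),
                 tolerance = 1e-12)
  }
  ident <- category_dissimilarity_matrix(rbind(a = f[1, ], b = f[1, ]))
  expect_equal(ident[1, 2], 0)
  expect_error(category_dissimilarity_matrix(f[1, , drop = FALSE]),
               "at least 2")
})

test_that("greedy pair selection takes the minimum first and pairs floor(n/2) images", {
  set.seed(4)
  f <- matrix(rnorm(4 * 10), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  f[2, ] <- f[1, ] + rnorm(10, sd = 0.05)    # a-b the unique closest pair
  m <- category_dissimilarity_matrix(f)
  p <- select_lure_pairs(m)
  expect_equal(nrow(p), 2L)
  expect_equal(c(p$image_a[1], p$image_b[1]), c("a", "b"))
  expect_true(all(diff(p$d) >= 0))           # non-decreasing selection order

  ## random instances: selection order is non-decreasing, each image used once
  for (i in 1:10) {
    n <- sample(4:9, 1)
    fm <- matrix(rnorm(n * 8), nrow = n,
                 dimnames = list(sprintf("i%02d", 1:n), NULL))
    pp <- select_lure_pairs(category_dissimilarity_matrix(fm))
    expect_equal(nrow(pp), n %/% 2L)
    used <- c(pp$image_a, pp$image_b)
    expect_equal(anyDuplicated(used), 0L)
    expect_true(all(diff(pp$d) >= -1e-12))
    expect_length(attr(pp, "unpaired"), n %% 2L)
  }
})

test_that("equal dissimilarities break ties lexicographically by image id", {
  m <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  p <- select_lure_pairs(m)
  expect_equal(p$image_a, c("a", "c"))
  expect_equal(p$image_b, c("b", "d"))
})

test_that("session assignment spreads pairs while honoring the category cap", {
  set.seed(5)
  pairs <- data.frame(image_a = paste0("a", 1:20), image_b = paste0("b", 1:20),
                      d = runif(20),
                      category = rep(c("cat", "dog"), each = 10))
  asg <- assign_pairs_to_sessions(pairs, n_sessions = 2L, category_cap = 4L)
  tab <- table(asg$session, asg$category)
  expect_true(all(tab <= 4L))
  expect_equal(sum(is.na(asg$session)), 20L - sum(tab))
})

test_that("the 18-value low-level statistics vector is laid out channel-major", {
  img <- array(0, dim = c(4, 4, 3))
  expect_warning(v <- lowlevel_stats_vector(img), "constant channel")
  expect_length(v, 18L)
  expect_equal(names(v)[1:6],
               c("R_mean", "R_variance", "R_skew", "R_kurtosis", "R_max", "R_min"))
  expect_equal(unname(v[c("R_mean", "R_max", "R_min", "R_variance")]),
               rep(0, 4))

  half <- array(rep(c(0, 1), each = 8), dim = c(4, 4, 3))
  v2 <- lowlevel_stats_vector(half)
  expect_equal(unname(v2["G_mean"]), 0.5)
  expect_equal(unname(v2["G_variance"]), 0.25, tolerance = 0.07) # sample var
  expect_equal(unname(v2["G_min"]), 0)
  expect_equal(unname(v2["G_max"]), 1)
  expect_equal(unname(v2["G_skew"]), 0)
  expect_equal(unname(v2["G_kurtosis"]), 1)  # two-point symmetric
})

test_that("constant channels flag skew/kurtosis as degenerate", {
  img <- array(rnorm(32 * 3), dim = c(8, 4, 3))
  img[, , 2] <- 7
  expect_warning(v <- lowlevel_stats_vector(img), "constant channel")
  expect_equal(attr(v, "degenerate_channels"), "G")
  expect_equal(unname(v[c("G_skew", "G_kurtosis")]), c(0, 0))
})

test_that("low-level statistics match an independent recomputation", {
  set.seed(6)
  for (i in 1:100) {
    img <- array(runif(2 * 3 * 3), dim = c(2, 3, 3))
    v <- lowlevel_stats_vector(img)
    for (ch in 1:3) {
      x <- as.numeric(img[, , ch])
      mu <- sum(x) / length(x)
      cm <- function(k) sum((x - mu)^k) / length(x)
      ref <- c(mu, sum((x - mu)^2) / (length(x) - 1),
               cm(3) / cm(2)^1.5, cm(4) / cm(2)^2, max(x), min(x))
      expect_equal(unname(v[(ch - 1) * 6 + 1:6]), ref, tolerance = 1e-12)
    }
  }
})

test_that("the leave-one-out correlation classifier separates clusters and matches its oracle", {
  set.seed(7)
  centers <- matrix(rnorm(3 * 10, sd = 4), nrow = 3)
  feats <- centers[rep(1:3, each = 6), ] + matrix(rnorm(18 * 10, sd = 0.1), 18)
  labels <- rep(c("lo", "mid", "hi"), each = 6)
  expect_equal(loo_correlation_classifier(feats, labels), 1.0)

  for (i in 1:30) {
    f <- matrix(rnorm(12 * 6), nrow = 12)
    l <- sample(rep(c("a", "b", "c"), each = 4))
    expect_equal(loo_correlation_classifier(f, l), loo_oracle(f, l))
  }
  expect_error(loo_correlation_classifier(feats, rep(c("a", "b"), 9)),
               "at least 3")
})

test_that("label-independent features classify at the 1/3 chance benchmark", {
  set.seed(8)
  feats <- matrix(rnorm(30 * 18), nrow = 30)
  acc <- classifier_chance_benchmark(feats, n_bins = 3L, n_shuffles = 120L,
                                     seed = 9L)
  expect_lt(abs(acc - 1 / 3), 0.04)
})
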