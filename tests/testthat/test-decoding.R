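test_that("decoder training reproduces the criterion arithmetic", {
  ## one unit, means 10 vs 6: homogeneous weights, b = 8
  nov <- matrix(c(9, 10, 11), nrow = 1)
  rep_ <- matrix(c(5, 6, 7), nrow = 1)
  d1 <- train_decoder(nov, rep_, "spike_count")
  expect_equal(d1$w, 1)
  expect_equal(d1$b, 8)

  ## two units, muN = (10, 5), muR = (6, 7): w = (4, -2), b = 20
  nov2 <- rbind(c(9, 11), c(4, 6))
  rep2 <- rbind(c(5, 7), c(6, 8))
  d2 <- train_decoder(nov2, rep2, "weighted")
  expect_equal(d2$w, c(4, -2))
  expect_equal(d2$b, 20)

  expect_error(train_decoder(nov[, 0, drop = FALSE], rep_), "empty")
})

test_that("the decision rule classifies by sign with ties going to novel", {
  dec <- structure(list(w = 1, b = 8, kind = "spike_count"),
                   class = "linear_decoder")
  expect_equal(decision_function(9, dec), 1)
  expect_equal(classify_response(9, dec), "novel")
  expect_equal(decision_function(7, dec), -1)
  expect_equal(classify_response(7, dec), "repeated")
  expect_equal(classify_response(8, dec), "novel")     # f = 0 -> novel
  expect_error(decision_function(c(1, 2), dec), "dimension")
})

test_that("the training mean classifies novel whenever the signal is positive", {
  set.seed(1)
  for (i in 1:20) {
    u <- sample(2:6, 1)
    nov <- matrix(rpois(u * 10, 8), u)
    rep_ <- matrix(rpois(u * 10, 5), u)
    dec <- train_decoder(nov, rep_, "weighted")
    muN <- rowMeans(nov); muR <- rowMeans(rep_)
    if (sum(dec$w * (muN - muR)) > 0) {
      expect_equal(classify_response(muN, dec), "novel")
    }
  }
})

test_that("predicted PCR equals explicit per-trial counting", {
  dec <- structure(list(w = c(1, 1), b = 10, kind = "spike_count"),
                   class = "linear_decoder")
  expect_equal(predict_pcr(rbind(c(1, 2), c(1, 2)), dec), 1)  # all below
  expect_equal(predict_pcr(rbind(c(9, 9), c(9, 9)), dec), 0)  # all above
  set.seed(2)
  for (i in 1:100) {
    u <- sample(1:5, 1); n <- sample(1:12, 1)
    X <- matrix(rpois(u * n, 4), u)
    w <- rnorm(u); b <- rnorm(1, 4 * u)
    d <- structure(list(w = w, b = b, kind = "weighted"),
                   class = "linear_decoder")
    ref <- 0
    for (j in seq_len(n)) if (sum(w * X[, j]) - b < 0) ref <- ref + 1
    expect_equal(predict_pcr(X, d), ref / n)
  }
})

test_that("PCR and its complement partition the trials (ties to novel)", {
  set.seed(3)
  X <- matrix(rpois(3 * 50, 5), 3)
  dec <- train_decoder(X + 2L, X, "spike_count")
  f <- decision_function(X, dec)
  expect_equal(predict_pcr(X, dec) + mean(f >= 0), 1)
})

test_that("anchor rescaling maps the anchors to 0 and 1", {
  expect_equal(rescale_predictions(0.9, C_N = 0.2, C_R = 0.9), 0)
  expect_equal(rescale_predictions(0.2, C_N = 0.2, C_R = 0.9), 1)
  expect_equal(rescale_predictions(0.55, C_N = 0.2, C_R = 0.9), 0.5)
  deg <- rescale_predictions(0.4, C_N = 0.5, C_R = 0.5)
  expect_true(is.na(deg))
  expect_true(attr(deg, "degenerate"))
})

test_that("ranked lure bins put remainders in the lowest-dissimilarity bins", {
  expect_equal(lure_bin_sizes(133), c(45L, 44L, 44L))
  expect_equal(lure_bin_sizes(80), c(27L, 27L, 26L))
  expect_equal(lure_bin_sizes(99), c(33L, 33L, 33L))
  for (n in 10:40) expect_equal(sum(lure_bin_sizes(n)), n)
})

test_that("within-condition shuffling preserves each unit's count multiset", {
  set.seed(4)
  for (i in 1:50) {
    U <- sample(2:6, 1); P <- sample(3:10, 1)
    M <- matrix(rpois(U * P, 5), U)
    perm <- t(sapply(seq_len(U), function(u) sample.int(P)))
    S <- mnemosharp:::shuffle_rows(M, perm)
    for (u in seq_len(U)) expect_equal(sort(S[u, ]), sort(M[u, ]))
  }
})

test_that("a zero-suppression population decodes at chance in every condition", {
  ## a single study's lure pairs carry frozen count noise that all CV
  ## iterations share, so the no-signal control averages replicate studies
  per_study <- sapply(1:5, function(k) {
    cfg <- small_study_config(suppression_mean = 0, suppression_sd = 0,
                              frac_enhancement_units = 0, seed = 5L + k)
    st <- simulate_study(cfg)
    pop <- build_pseudopopulation(st$sessions, seed = 6L + k)
    cv <- crossval_run(pop, n_iterations = 30L, seed = 7L + k)
    it <- cv$iterations
    c(mean(it$pcr_novel), mean(it$pcr_repeat),
      mean(it$pcr_bin1), mean(it$pcr_bin2), mean(it$pcr_bin3))
  })
  grand <- rowMeans(per_study)
  expect_true(all(abs(grand - 0.5) < 0.06))
})

test_that("cross-validation errors when the holdout exceeds the exact pairs", {
  cfg <- small_study_config(n_exact_pairs = 10L, n_lure_pairs = 40L,
                            trials = 100L)
  st <- simulate_study(cfg)
  pop <- build_pseudopopulation(st$sessions, seed = 8L)
  expect_error(crossval_run(pop, n_iterations = 2L), "holdout")
})

test_that("uniform suppression makes the weighted and spike-count decoders agree", {
  ## every unit carries the same expected suppression: muN - muR is a
  ## positive multiple of 1, so both decision functions are positive scalings
  set.seed(9)
  U <- 5L
  muN <- rep(20, U); muR <- rep(14, U)
  nov <- matrix(muN + rep(c(-1, 0, 1), each = U), U)
  rep_ <- matrix(muR + rep(c(-1, 0, 1), each = U), U)
  d_sc <- train_decoder(nov, rep_, "spike_count")
  d_w <- train_decoder(nov, rep_, "weighted")
  X <- matrix(rpois(U * 200, 17), U)
  expect_equal(classify_response(X, d_sc), classify_response(X, d_w))
})
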