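test_that("dense gradient descriptors behave on canonical inputs", {
  ## flat frame: zero gradients everywhere -> all descriptors dropped
  fs0 <- extractLocalFeatures(matrix(1, 16, 16))
  expect_equal(nrow(fs0$features), 0L)
  expect_equal(attr(fs0, "n_dropped"), 1L)
  ## descriptors are L2-normalized, D = 128
  set.seed(41)
  fr <- array(rnorm(2 * 24 * 24), c(2, 24, 24))
  fs <- extractLocalFeatures(fr, patch = 16, stride = 8)
  expect_equal(ncol(fs$features), 128L)
  expect_equal(rowSums(fs$features^2), rep(1, nrow(fs$features)),
               tolerance = 1e-10)
  ## grid arithmetic: floor((W - patch)/stride) + 1 positions per axis
  expect_equal(nrow(fs$features), 2 * 2 * 2)
  expect_error(extractLocalFeatures(matrix(0, 8, 8)), "16 x 16")
})

test_that("a 90-degree rotation permutes cells and orientation bins", {
  set.seed(42)
  sm <- matrix(rnorm(8 * 8), 8, 8)
  ## smooth upsample to avoid bin-boundary ties
  up <- kronecker(sm, matrix(1, 2, 2)) + matrix(rnorm(256, sd = 1e-3), 16)
  rot <- t(up)[, rev(seq_len(16))]          # 90-degree rotation
  d1 <- extractLocalFeatures(up)$features[1, ]
  d2 <- extractLocalFeatures(rot)$features[1, ]
  ## orientation bins shift by 2 (90 deg / 45 deg) and the 4x4 cell grid
  ## rotates; compare via the explicit permutation
  m1 <- array(d1, c(8, 4, 4))               # bins x cell-row x cell-col
  m2 <- array(d2, c(8, 4, 4))
  m1s <- m1[c(7:8, 1:6), , ]                # bin + 2 (mod 8)
  expected <- array(0, c(8, 4, 4))          # cell (i', j') <- (5 - j', i')
  for (i2 in 1:4) for (j2 in 1:4)
    expected[, i2, j2] <- m1s[, 5 - j2, i2]
  expect_equal(as.vector(expected), as.vector(m2), tolerance = 1e-6)
})

test_that("k-means codebook attains small-instance optima", {
  ## distinct repeated points with K = M: centers equal the points
  pts <- matrix(c(0, 0, 5, 5, 10, -3), 3, 2, byrow = TRUE)
  feats <- pts[rep(1:3, each = 7), ]
  cb <- trainCodebook(feats, 3, seed = 1)
  expect_equal(sort(codewords(cb)[, 1]), sort(pts[, 1]), tolerance = 1e-9)
  ## tiny instance: inertia is not beaten by any 2-partition
  set.seed(43)
  f6 <- matrix(rnorm(12), 6, 2)
  cb2 <- trainCodebook(f6, 2, seed = 9)
  inertia <- function(assign_) {
    sum(vapply(1:2, function(k) {
      m <- f6[assign_ == k, , drop = FALSE]
      if (nrow(m) == 0) 0 else sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
  }
  got <- inertia(apply(as.matrix(dist(rbind(codewords(cb2), f6)))[3:8, 1:2],
                       1, which.min))
  best <- min(vapply(1:31, function(mask) {
    a <- as.integer(intToBits(mask))[1:6] + 1L
    if (length(unique(a)) < 2) Inf else inertia(a)
  }, numeric(1)))
  expect_lte(got, best + 1e-9)
  expect_error(trainCodebook(f6, 10, seed = 1), "N >= M")
})

test_that("the five-layer neighbor graph respects its contract", {
  set.seed(44)
  cb <- trainCodebook(matrix(rnorm(400 * 8), 400, 8), 15, seed = 2)
  msm <- buildMSM(cb)
  expect_equal(sort(unique(msm@layer)), 1:5)
  expect_true(all(tabulate(msm@layer, 5) >= 1))
  for (i in seq_along(msm@layer)) {
    expect_lte(length(msm@one_hop[[i]]), 6L)
    expect_lte(length(msm@two_hop[[i]]), 2L)
    expect_false(i %in% msm@one_hop[[i]])
    expect_false(i %in% msm@two_hop[[i]])
    expect_length(intersect(msm@one_hop[[i]], msm@two_hop[[i]]), 0)
  }
  expect_warning(buildMSM(trainCodebook(matrix(rnorm(40), 20, 2), 4,
                                        seed = 3)), "all-pairs")
})

test_that("integer ambiguity fixing matches exhaustive search", {
  set.seed(45)
  cb <- trainCodebook(matrix(rnorm(300 * 6), 300, 6), 12, seed = 5)
  msm <- buildMSM(cb)
  for (k in 1:20) {
    r <- rnorm(6, sd = 1.5)
    sol <- resolveNeighbors(r, cb, msm)
    expect_gte(length(sol$words), 1L)       # nearest word always present
    if (!is.null(sol$covariance)) {
      Covi <- solve(sol$covariance)
      ## independent brute-force minimizer over the same box
      best <- c(NA, NA); bestq <- Inf
      for (a in -3:3) for (b in -3:3) {
        dd <- sol$float - c(a, b)
        q <- drop(t(dd) %*% Covi %*% dd)
        if (q < bestq) { bestq <- q; best <- c(a, b) }
      }
      expect_equal(sol$fixed, as.integer(best))
      expect_equal(sol$objective, bestq, tolerance = 1e-9)
      expect_gte(sol$objective, 0)
    }
  }
})

test_that("batch neighbor resolution equals the per-feature solver", {
  set.seed(48)
  cb <- trainCodebook(matrix(rnorm(300 * 6), 300, 6), 14, seed = 11)
  msm <- buildMSM(cb)
  feats <- matrix(rnorm(60 * 6, sd = 1.3), 60, 6)
  batch <- scnet:::resolveNeighborsBatch(feats, cb, msm, k_nn = 3)
  for (f in 1:60) {
    single <- head(resolveNeighbors(feats[f, ], cb, msm)$words, 3)
    expect_equal(batch[[f]], single)
  }
})

test_that("MN-VLAD reduces to standard VLAD at k_nn = 1", {
  set.seed(46)
  for (k in 1:25) {
    feats <- matrix(rnorm(30 * 8), 30, 8)
    cb <- trainCodebook(matrix(rnorm(200 * 8), 200, 8), 10,
                        seed = 100 + k)
    enc <- encodeMNVlad(feats, cb, k_nn = 1)
    expect_equal(enc$v_raw, referenceVlad(feats, codewords(cb)),
                 tolerance = 1e-10)
  }
})

test_that("VLAD residual accumulation matches brute force on a hand case", {
  words <- rbind(c(0, 0), c(10, 0))
  cb <- new("Codebook", words = words, seed = 1L, iterations = 1L)
  feats <- rbind(c(1, 1), c(2, -1), c(9, 2))
  enc <- encodeMNVlad(feats, cb, k_nn = 1)
  ## features 1, 2 -> word 1; feature 3 -> word 2 (hand-assigned)
  expect_equal(enc$v_raw,
               rbind(c(1 + 2, 1 - 1), c(9 - 10, 2)))
  ## normalized descriptor has unit length
  expect_equal(sum(enc$v^2), 1, tolerance = 1e-12)
})

test_that("VLAD descriptor invariances hold", {
  set.seed(47)
  feats <- matrix(rnorm(40 * 8), 40, 8)
  cb <- trainCodebook(matrix(rnorm(300 * 8), 300, 8), 10, seed = 7)
  msm <- buildMSM(cb)
  e1 <- encodeMNVlad(feats, cb, msm, k_nn = 3)
  ## permutation invariance in the feature order
  e2 <- encodeMNVlad(feats[sample(40), ], cb, msm, k_nn = 3)
  expect_equal(e1$v_raw, e2$v_raw, tolerance = 1e-9)
  ## adding a feature that sits exactly on a codeword changes nothing
  e3 <- encodeMNVlad(rbind(feats, codewords(cb)[4, ]), cb, msm, k_nn = 3)
  expect_equal(e1$v_raw, e3$v_raw, tolerance = 1e-9)
  ## empty input: flagged zero descriptor
  e0 <- encodeMNVlad(matrix(0, 0, 8), cb, msm)
  expect_true(e0$empty)
  expect_equal(sum(abs(e0$v)), 0)
})
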