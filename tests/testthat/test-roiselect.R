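test_that("panel normalization is a population z-score", {
  p <- normalizePanel(rbind(c(1, 2, 3), c(10, 20, 60)))
  expect_equal(rowMeans(p), c(0, 0), tolerance = 1e-12)
  expect_equal(sqrt(rowMeans(p^2)), c(1, 1), tolerance = 1e-12)
  expect_error(normalizePanel(rbind(c(1, 1, 1), c(1, 2, 3))),
               "degenerate")
  ## affine copies of one signal normalize identically
  set.seed(21)
  x <- rnorm(50)
  p <- normalizePanel(rbind(x, 3 * x + 7, 0.1 * x - 2))
  expect_equal(p[1, ], p[2, ], tolerance = 1e-10)
  expect_equal(p[1, ], p[3, ], tolerance = 1e-10)
})

test_that("equal-time correlation has the Pearson structure", {
  set.seed(22)
  x <- rnorm(500)
  p <- normalizePanel(rbind(x, x, -x))
  cr <- equalTimeCorrelation(p)
  expect_equal(diag(cr), rep(1, 3), tolerance = 1e-12)
  expect_equal(cr[1, 2], 1, tolerance = 1e-12)
  expect_equal(cr[1, 3], -1, tolerance = 1e-12)
  ## independent noise: off-diagonals small at T = 1e4
  pn <- normalizePanel(matrix(rnorm(4 * 1e4), 4))
  crn <- equalTimeCorrelation(pn)
  expect_lt(max(abs(crn[upper.tri(crn)])), 0.05)
  ## trace preservation: eigenvalue sum = N
  rep_ <- correlationReport(pn)
  expect_equal(sum(rep_$eigenvalues), 4, tolerance = 1e-9)
})

test_that("Marchenko-Pastur reference matches the closed form", {
  r <- rmtReference(10, 40)                 # U = 4
  expect_identical(c(r$lambda_minus, r$lambda_plus), c(0.25, 2.25))
  ## U -> infinity: both edges -> 1
  rbig <- rmtReference(10, 10 * 2^40)
  expect_equal(rbig$lambda_minus, 1, tolerance = 1e-5)
  expect_equal(rbig$lambda_plus, 1, tolerance = 1e-5)
  ## density integrates to 1 and vanishes outside the support
  q <- integrate(r$density, r$lambda_minus, r$lambda_plus,
                 rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-3)
  expect_equal(r$density(c(0.1, 3)), c(0, 0))
  expect_error(rmtReference(10, 10), "U > 1")
})

test_that("lambda_MSC flags planted correlation and not noise", {
  ## N identical rows: rank-one matrix with lambda_max = N
  x <- rnorm(300)
  p <- normalizePanel(matrix(rep(x, 6), 6, byrow = TRUE))
  rep_ <- correlationReport(p)
  expect_equal(rep_$eigenvalues[1], 6, tolerance = 1e-9)
  expect_equal(lambdaMsc(rep_)$ratio, 6 / rep_$lambda_plus,
               tolerance = 1e-9)
  expect_true(lambdaMsc(rep_)$correlated)
  ## planted common factor, loading 0.8: detected in every replicate
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    f <- rnorm(1000)
    panel <- 0.8 * matrix(rep(f, 10), 10, byrow = TRUE) +
      0.6 * matrix(rnorm(10 * 1000), 10)
    lambdaMsc(correlationReport(normalizePanel(panel)))$correlated
  }, logical(1))
  expect_true(all(hits))
})

test_that("feature vectors are windowed means and variances", {
  ser <- data.frame(frame_index = 0:5, M1 = rep(2, 6), M2 = 1:6,
                    M3 = rep(0, 6), M4 = rep(1, 6), S = c(1, 3, 1, 3, 1, 3))
  fv <- buildFV(ser, window = 2)
  expect_equal(dim(fv), c(3L, 10L))          # 5 channels x (mu, var)
  expect_equal(unname(fv[, "mu_M1"]), rep(2, 3))
  expect_equal(unname(fv[, "var_M1"]), rep(0, 3))
  expect_equal(unname(fv[, "mu_S"]), rep(2, 3))
  expect_equal(unname(fv[, "var_S"]), rep(1, 3))   # population variance
  ## brute-force check on a random window
  set.seed(23)
  ser2 <- data.frame(frame_index = 0:9, A = rnorm(10), B = rnorm(10))
  fv2 <- buildFV(ser2, window = 5)
  expect_equal(unname(fv2[2, "mu_A"]), mean(ser2$A[6:10]))
  expect_equal(unname(fv2[2, "var_B"]),
               mean((ser2$B[6:10] - mean(ser2$B[6:10]))^2))
  expect_error(buildFV(ser, window = 7), "longer")
  expect_error(buildFV(ser, window = 1), "at least 2")
})

test_that("coarse inner product is a normalized correlation", {
  set.seed(24)
  a <- matrix(rnorm(40 * 3), 40)
  expect_equal(coarseInnerProduct(a, a), 1, tolerance = 1e-12)
  expect_equal(coarseInnerProduct(a, -a), -1, tolerance = 1e-12)
  ## orthogonal sinusoids over whole periods: near zero at >= 64 samples
  t <- seq(0, 1, length.out = 128)
  s1 <- matrix(sin(2 * pi * 4 * t)); s2 <- matrix(cos(2 * pi * 4 * t))
  expect_lt(abs(coarseInnerProduct(s1, s2, level_j = 0,
                                   period_p = 128)), 0.05)
  expect_error(coarseInnerProduct(a, a, level_j = -10, period_p = 4),
               "sampling step")
})

test_that("delta maps the inner product onto [0, 1]", {
  set.seed(25)
  ref <- matrix(rnorm(30 * 2), 30)
  expect_equal(deltaStrength(ref, ref), 1, tolerance = 1e-12)
  expect_equal(deltaStrength(-ref, ref), 0, tolerance = 1e-12)
  expect_error(deltaStrength(ref), "reference")
  ## unrelated noise scores near one half
  ds <- vapply(1:20, function(s) {
    set.seed(600 + s)
    deltaStrength(matrix(rnorm(30 * 2), 30), ref)
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.5), 0.1)
})

test_that("composite ROI ranking obeys the weights and is stable", {
  set.seed(26)
  T_ <- 400
  f <- rnorm(T_)
  mk <- function(load) load * matrix(rep(f, 6), 6, byrow = TRUE) +
    sqrt(1 - load^2) * matrix(rnorm(6 * T_), 6)
  panels <- list(weak = mk(0.2), strong = mk(0.7), none = mk(0))
  fvs <- lapply(panels, function(p)
    lapply(seq_len(nrow(p)), function(i)
      buildFV(data.frame(frame_index = seq_len(T_) - 1, S = p[i, ]), 20)))
  ref <- fvs$strong[[1]]
  ## m = 1, n = 0: ranking must follow lambda_MSC alone
  sc <- selectRoi(panels, fvs, m = 1, n = 0, reference = ref)
  expect_equal(sc$roi[order(-sc$lambda_msc)], sc$roi)
  expect_equal(sc$epsilon, sc$lambda_msc_scaled)
  ## permutation invariance of candidate order
  perm <- c("none", "strong", "weak")
  sc2 <- selectRoi(panels[perm], fvs[perm], m = 1, n = 0, reference = ref)
  expect_equal(sc2, sc, ignore_attr = TRUE)
  ## epsilon is the stated convex combination
  sc3 <- selectRoi(panels, fvs, m = 0.5, n = 0.5, reference = ref)
  expect_equal(sc3$epsilon,
               0.5 * sc3$lambda_msc_scaled + 0.5 * sc3$delta,
               tolerance = 1e-12)
  expect_true(all(sc3$epsilon >= 0 & sc3$epsilon <= 1))
  expect_error(selectRoi(panels, fvs, m = 0.8, n = 0.8), "m \\+ n")
  expect_error(selectRoi(panels["weak"], fvs["weak"]), "2 candidate")
})
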