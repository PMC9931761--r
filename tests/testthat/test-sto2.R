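basis <- defaultChromophoreBasis()

test_that("absorbance follows the -log10 contract", {
  s <- SpectralFrameStack(array(200, c(2, 4, 3, 3)),
                          c(540, 556, 560, 576), 30)
  expect_equal(max(abs(computeAbsorbance(s, 200))), 0)
  expect_equal(unique(as.vector(computeAbsorbance(s, 2000))), 1)
  dark <- SpectralFrameStack(array(0, c(1, 4, 2, 2)),
                             c(540, 556, 560, 576), 30)
  A <- computeAbsorbance(dark, 100)
  expect_true(all(is.finite(A)))
  expect_equal(unique(as.vector(A)), -log10(1e-6))
  expect_error(computeAbsorbance(s, 0), "positive")
  expect_error(computeAbsorbance(s, c(1, 1, -1, 1)), "positive")
})

test_that("Beer-Lambert inversion is exact on forward-generated data", {
  ## zero absorbance -> zero concentrations and offset
  cm0 <- invertBeerLambert(array(0, c(2, 4, 3, 3)), basis)
  expect_equal(max(abs(cm0@c_hbo2)), 0)
  expect_equal(max(abs(cm0@g_prime)), 0)
  ## random positive concentrations recovered within 1e-9
  set.seed(7)
  sh <- c(4, 5, 6)
  c1 <- array(runif(prod(sh), 0.01, 0.3), sh)
  c2 <- array(runif(prod(sh), 0.01, 0.3), sh)
  c3 <- array(runif(prod(sh), 0.001, 0.05), sh)
  gp <- array(runif(prod(sh), -0.1, 0.2), sh)
  A <- forwardAbsorbance(basis, c1, c2, c3, gp)
  cm <- invertBeerLambert(A, basis)
  expect_lt(max(abs(cm@c_hbo2 - c1)), 1e-9)
  expect_lt(max(abs(cm@c_hb - c2)), 1e-9)
  expect_lt(max(abs(cm@c_melanin - c3)), 1e-9)
  expect_lt(max(abs(cm@g_prime - gp)), 1e-9)
  ## default basis covers exactly the four acquisition bands
  expect_equal(nrow(designMatrix(basis)), 4L)
  expect_equal(wavelengths(basis), c(540, 556, 560, 576))
})

test_that("a common per-band offset is absorbed entirely by G'", {
  ## the G' design column is all ones, so adding k to every band moves
  ## only the offset estimate
  set.seed(8)
  sh <- c(2, 3, 3)
  c1 <- array(runif(prod(sh)), sh); c2 <- array(runif(prod(sh)), sh)
  c3 <- array(runif(prod(sh)), sh); gp <- array(0, sh)
  A <- forwardAbsorbance(basis, c1, c2, c3, gp)
  cmA <- invertBeerLambert(A, basis)
  cmB <- invertBeerLambert(A + 0.37, basis)
  expect_equal(cmA@c_hbo2, cmB@c_hbo2, tolerance = 1e-10)
  expect_equal(cmA@c_hb, cmB@c_hb, tolerance = 1e-10)
  expect_equal(cmB@g_prime - cmA@g_prime, array(0.37, sh),
               tolerance = 1e-10)
})

test_that("StO2 is the clipped saturation ratio with NaN degenerates", {
  sh <- c(1, 2, 2)
  mk <- function(v) array(v, sh)
  cm <- new("ChromophoreMap", c_hbo2 = mk(0.2), c_hb = mk(0),
            c_melanin = mk(0), g_prime = mk(0))
  expect_equal(unique(as.vector(sto2Values(computeStO2(cm)))), 1)
  cm@c_hb <- mk(0.2)
  expect_equal(unique(as.vector(sto2Values(computeStO2(cm)))), 0.5)
  cm@c_hbo2 <- mk(-0.1); cm@c_hb <- mk(0.1)
  expect_true(all(is.nan(sto2Values(computeStO2(cm)))))
  ## values always in [0,1] or NaN
  set.seed(9)
  cm@c_hbo2 <- mk(rnorm(4)); cm@c_hb <- mk(rnorm(4))
  v <- sto2Values(computeStO2(cm))
  expect_true(all(is.nan(v) | (v >= 0 & v <= 1)))
})

test_that("fused StO2 extraction equals the staged chain", {
  cfg <- syntheticConfig(n_subjects = 2, duration_s = 2)
  co <- simulateCohort(cfg, seed = 5)
  st <- co$stacks[[2]]
  fused <- sto2Values(extractStO2(st, cfg$reference))
  staged <- sto2Values(computeStO2(invertBeerLambert(
    computeAbsorbance(st, cfg$reference), basis)))
  expect_equal(is.nan(fused), is.nan(staged))
  d <- abs(fused - staged)
  expect_lt(max(d[!is.nan(d)]), 1e-12)
})

test_that("full simulator round trip reproduces the planted StO2", {
  cfg <- syntheticConfig(n_subjects = 2, duration_s = 2, noise_sd = 0)
  co <- simulateCohort(cfg, seed = 11)
  tt <- (seq_len(60) - 1) / 30
  for (i in 1:2) {
    S_true <- scnet:::plantedSto2(cfg, co$catalog, co$truth$labels[i],
                                  co$truth$subject_effects[i],
                                  co$truth$phases, tt)
    S_rec <- sto2Values(extractStO2(co$stacks[[i]], cfg$reference))
    expect_lt(sqrt(mean((S_rec - S_true)^2)), 1e-6)
  }
})

test_that("ROI channel series are masked spatial means", {
  ## constant stack -> constant series; single-pixel mask -> that pixel
  s <- makeTestStack(T_ = 4, H = 6, W = 6, seed = 12)
  sv <- new("StO2Stack", sto2 = array(0.5, c(4, 6, 6)))
  mask1 <- matrix(FALSE, 6, 6); mask1[2, 3] <- TRUE
  ser1 <- roiChannelSeries(s, sv, mask1)
  expect_equal(ser1$M2, s@data[, 2, 2, 3])
  expect_equal(ser1$S, rep(0.5, 4))
  ## checkerboard 0/1 band -> mean 0.5
  d <- array(0, c(1, 4, 6, 6))
  d[1, , , ] <- rep(outer(1:6, 1:6, function(i, j) (i + j) %% 2), each = 4)
  cb <- SpectralFrameStack(d, c(540, 556, 560, 576), 30)
  serc <- roiChannelSeries(cb, new("StO2Stack", sto2 = array(0.5, c(1, 6, 6))),
                           matrix(TRUE, 6, 6))
  expect_equal(serc$M1, 0.5)
  expect_error(roiChannelSeries(s, sv, matrix(FALSE, 6, 6)), "empty")
})
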