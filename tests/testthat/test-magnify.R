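bp <- BandpassSpec(1.2, 2.0, 30)

test_that("ideal band-pass keeps the band and rejects DC", {
  t <- (0:299) / 30
  pure <- sin(2 * pi * 1.5 * t)
  out <- temporalBandpass(pure, bp)
  expect_equal(max(abs(out)), 1, tolerance = 0.02)
  expect_equal(temporalBandpass(rep(3, 300), bp), rep(0, 300),
               tolerance = 1e-12)
  ## mixture: only the in-band component survives
  mix <- 0.7 * sin(2 * pi * 0.5 * t) + sin(2 * pi * 1.5 * t) +
    0.5 * sin(2 * pi * 5 * t) + 2
  outm <- temporalBandpass(mix, bp)
  sp <- Mod(fft(outm)) / 300 * 2
  bins <- round(c(0.5, 1.5, 5) * 300 / 30) + 1
  expect_equal(sp[bins[2]], 1, tolerance = 0.02)
  expect_lt(sp[bins[1]], 0.02)
  expect_lt(sp[bins[3]], 0.02)
  expect_error(BandpassSpec(1.2, 16, 30), "Nyquist")
  expect_error(BandpassSpec(2, 1.2, 30), "f_lo < f_hi")
})

test_that("Mexican-hat pyramid reconstructs exactly and localizes energy", {
  set.seed(31)
  fr <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  dec <- waveletDecompose(fr, scales = 3)
  expect_lt(max(abs(waveletReconstruct(dec) - fr)), 1e-6)
  ## constant frames: every detail sub-band vanishes
  decc <- waveletDecompose(array(5, c(2, 16, 16)), scales = 3)
  for (s in decc$subbands) expect_lt(max(abs(s$coeff)), 1e-10)
  ## single bright pixel: energy concentrated at the finest scale
  imp <- array(0, c(1, 32, 32)); imp[1, 16, 16] <- 1
  deci <- waveletDecompose(imp, scales = 3)
  en <- vapply(deci$subbands, function(s) sum(s$coeff^2), numeric(1))
  expect_equal(which.max(en), 1L)
  expect_gt(en[1], sum(en[-1]))
  expect_error(waveletDecompose(array(0, c(2, 4, 4))), "H, W >= 8")
})

test_that("noise-free amplification has the (1 + alpha) displacement gain", {
  ## alpha = 0 leaves the signal untouched
  set.seed(32)
  x <- array(rnorm(60 * 2 * 8), c(60, 2, 8))
  expect_equal(amplify(x, spec = MagnificationSpec(alpha = 0),
                       bandpass = bp), x, tolerance = 1e-12)
  ## in-band sub-pixel displacement of a linear ramp: gain 21 within 5%
  d <- 0.2
  stk <- rampStack(d = d, freq = 1.5)
  out <- amplify(stk, spec = MagnificationSpec(alpha = 20), bandpass = bp)
  pos <- apply(out[, 1, ], 1, trackCrossing)
  expect_equal(unname(fitAmplitude(pos, 1.5, 30) / d), 21,
               tolerance = 0.05)
  ## out-of-band displacement: gain stays 1 within 5%
  stk2 <- rampStack(d = d, freq = 0.3)
  out2 <- amplify(stk2, spec = MagnificationSpec(alpha = 20),
                  bandpass = bp)
  pos2 <- apply(out2[, 1, ], 1, trackCrossing)
  expect_equal(unname(fitAmplitude(pos2, 0.3, 30) / d), 1,
               tolerance = 0.05)
  ## linearity of the noise-free path
  s1 <- array(rnorm(60 * 2 * 8), c(60, 2, 8))
  s2 <- array(rnorm(60 * 2 * 8), c(60, 2, 8))
  spec <- MagnificationSpec(alpha = 7)
  expect_equal(amplify(s1 + s2, spec = spec, bandpass = bp),
               amplify(s1, spec = spec, bandpass = bp) +
                 amplify(s2, spec = spec, bandpass = bp),
               tolerance = 1e-10)
})

test_that("sub-band magnification with uniform alpha matches direct", {
  set.seed(33)
  stk <- array(rnorm(90 * 16 * 16), c(90, 16, 16))
  direct <- amplify(stk, spec = MagnificationSpec(alpha = 5),
                    bandpass = bp)
  viaSub <- magnifyStack(stk, bandpass = bp, alpha = 5, scales = 3)
  expect_equal(viaSub, direct, tolerance = 1e-8)
})

test_that("Eulerian error map follows the Taylor remainder", {
  spec <- MagnificationSpec(alpha = 20)
  ## delta = 0 and linear ramps (zero curvature) both give omega = 0
  x <- seq_len(40)
  lin <- array(rep(0.1 * x, each = 5), c(5, 1, 40))
  expect_equal(magnificationError(lin, 0.3, spec),
               array(0, c(5, 1, 40)), tolerance = 1e-12)
  quad <- array(rep(x^2 / 100, each = 5), c(5, 1, 40))
  expect_equal(magnificationError(quad, 0, spec),
               array(0, c(5, 1, 40)), tolerance = 1e-12)
  ## quadratic profile: matches the closed-form remainder pointwise
  d0 <- 0.25
  om <- magnificationError(quad, d0, spec)
  ix <- 0.1 * x / 5                        # dI/dx = 2x/100
  ixx <- 2 / 100
  ref <- abs(0.5 * 21 * d0^2 * ixx - 0.5 * 21^2 * d0^2 * ixx * ix)
  interior <- 3:38
  expect_equal(om[3, 1, interior], ref[interior], tolerance = 0.1)
  expect_true(all(om >= 0))
})

test_that("noise-aware amplification attenuates noise-dominated pixels", {
  set.seed(34)
  t <- (0:599) / 30
  ## clean in-band oscillation: full gain retained
  clean <- matrix(sin(2 * pi * 1.5 * t), ncol = 1)
  resC <- amplifyNoiseAware(clean, MagnificationSpec(alpha = 20), bp)
  expect_gt(resC$alpha_eff[1], 19)
  plain <- amplify(clean, spec = MagnificationSpec(alpha = 20),
                   bandpass = bp)
  expect_equal(resC$st_amplified, plain, tolerance = 0.05)
  ## noise-only input: effective gain collapses
  noise <- matrix(rnorm(600, sd = 0.5), ncol = 1)
  resN <- amplifyNoiseAware(noise, MagnificationSpec(alpha = 20), bp)
  expect_lt(resN$alpha_eff[1], 2)
  expect_lt(sd(resN$st_amplified), sd(noise) * (1 + resN$alpha_eff[1]))
  ## error maps: non-negative, and the noisy map dominates on average
  expect_true(all(resN$omega >= 0) && all(resN$omega_prime >= 0))
  expect_gt(mean(resN$omega_prime), mean(resN$omega))
  ## supplied noise floor is honored
  resF <- amplifyNoiseAware(noise, MagnificationSpec(alpha = 20,
                                                     noise_floor = 0.5),
                            bp)
  expect_equal(resF$tau[1], 0.5)
})
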