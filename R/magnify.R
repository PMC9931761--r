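## Eulerian temporal magnification of StO2 / intensity stacks in the
## 1.2-2 Hz band, on Mexican-hat wavelet sub-bands, with an optional
## noise-aware path that attenuates the gain where the predicted
## Eulerian error exceeds the local in-band signal.

#' Temporal band-pass specification
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < sample_rate/2`.
#' @param sample_rate sampling rate in Hz.
#' @return validated list of class `BandpassSpec`.
#' @export
BandpassSpec <- function(f_lo = 1.2, f_hi = 2.0, sample_rate = 30) {
  if (!(f_lo > 0 && f_hi > f_lo))
    stop("need 0 < f_lo < f_hi")
  if (f_hi >= sample_rate / 2)
    stop("f_hi must be below the Nyquist rate ", sample_rate / 2, " Hz")
  structure(list(f_lo = f_lo, f_hi = f_hi, sample_rate = sample_rate),
            class = "BandpassSpec")
}

#' Magnification specification
#'
#' @param alpha amplification factor (>= 0); the conservative default
#'   is 20.
#' @param noise_floor known SD of the additive sensor noise, or NULL to
#'   estimate it from out-of-band temporal differences.
#' @param noise_k attenuation strength: the pointwise effective gain is
#'   `alpha * s^2 / (s^2 + noise_k * tau^2)` for in-band amplitude `s`.
#' @return list of class `MagnificationSpec`.
#' @export
MagnificationSpec <- function(alpha = 20, noise_floor = NULL, noise_k = 1) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.null(noise_floor) && noise_floor < 0)
    stop("noise_floor must be >= 0")
  structure(list(alpha = alpha, noise_floor = noise_floor,
                 noise_k = noise_k), class = "MagnificationSpec")
}

## Fold a T x H x W array (or T x P matrix / length-T vector) into a
## T x P matrix plus a restorer.
foldTime <- function(x) {
  d <- dim(x)
  if (is.null(d)) {
    list(m = matrix(x, ncol = 1), restore = function(m) as.vector(m))
  } else if (length(d) == 2) {
    list(m = x, restore = identity)
  } else {
    list(m = matrix(x, d[1], prod(d[-1])),
         restore = function(m) array(m, d))
  }
}

#' Ideal zero-phase temporal band-pass filter
#'
#' FFT-domain mask: frequency bins whose |f| lies in `[f_lo, f_hi]` are
#' kept, all others (including DC) are zeroed; the filter is zero-phase
#' by construction.
#'
#' @param signal per-pixel time series: vector, T x P matrix or
#'   T x H x W array, time first.
#' @param spec a [BandpassSpec()].
#' @return band-passed signal, same shape as the input.
#' @export
temporalBandpass <- function(signal, spec) {
  stopifnot(inherits(spec, "BandpassSpec"))
  f <- foldTime(signal)
  T_ <- nrow(f$m)
  freqs <- (seq_len(T_) - 1) / T_ * spec$sample_rate
  freqs <- pmin(freqs, spec$sample_rate - freqs)   # fold to |f|
  keep <- freqs >= spec$f_lo & freqs <= spec$f_hi
  X <- mvfft(f$m)
  X[!keep, ] <- 0
  f$restore(Re(mvfft(X, inverse = TRUE)) / T_)
}

## Gaussian smoothing matrix with reflect padding (rows sum to 1).
gaussKernelMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    p <- i + ((-r):r)
    p <- ifelse(p < 1, 2 - p, p)
    p <- ifelse(p > n, 2 * n - p, p)
    for (k in seq_along(p)) K[i, p[k]] <- K[i, p[k]] + g[k]
  }
  K
}

smoothFrames <- function(frames, sigma) {
  d <- dim(frames)                        # T x H x W
  Kh <- gaussKernelMatrix(d[2], sigma)
  Kw <- gaussKernelMatrix(d[3], sigma)
  ## smooth rows: reshape to H x (T*W) by permuting time behind height
  x <- aperm(frames, c(2, 1, 3))          # H x T x W
  dim(x) <- c(d[2], d[1] * d[3])
  x <- Kh %*% x
  dim(x) <- c(d[2], d[1], d[3])
  x <- aperm(x, c(3, 2, 1))               # W x T x H
  dim(x) <- c(d[3], d[1] * d[2])
  x <- Kw %*% x
  dim(x) <- c(d[3], d[1], d[2])
  aperm(x, c(2, 3, 1))                    # T x H x W
}

#' Mexican-hat (a-trous) spatial sub-band decomposition
#'
#' Additive pyramid: each sub-band is the difference between successive
#' Gaussian smoothings of the frames (a discrete Mexican-hat /
#' difference-of-Gaussians band-pass at dyadically growing scale), plus
#' a residual low-pass stack. Because the decomposition is additive,
#' [waveletReconstruct()] (sum of sub-bands + residual) inverts it
#' exactly.
#'
#' @param frames numeric T x H x W array, `H, W >= 8`.
#' @param scales number of detail scales (default 3).
#' @param sigma0 base Gaussian scale in pixels.
#' @return list of class `SubbandStack` with `subbands` (list of
#'   `list(scale, coeff)`) and `residual`.
#' @export
waveletDecompose <- function(frames, scales = 3, sigma0 = 1) {
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be a T x H x W array")
  if (min(d[2:3]) < 8) stop("frames too small: need H, W >= 8")
  if (scales < 1 || 2^(scales - 1) * sigma0 * 6 > 4 * max(d[2:3]))
    stop("requested scales too deep for this frame size")
  sub <- vector("list", scales)
  cur <- frames
  for (s in seq_len(scales)) {
    sm <- smoothFrames(cur, sigma0 * 2^(s - 1))
    sub[[s]] <- list(scale = s, coeff = cur - sm)
    cur <- sm
  }
  structure(list(subbands = sub, residual = cur), class = "SubbandStack")
}

#' @rdname waveletDecompose
#' @param decomposition a `SubbandStack`.
#' @export
waveletReconstruct <- function(decomposition) {
  stopifnot(inherits(decomposition, "SubbandStack"))
  out <- decomposition$residual
  for (s in decomposition$subbands) out <- out + s$coeff
  out
}

#' Noise-free Eulerian amplification
#'
#' `st_amplified = signal + alpha * B`; for a translating profile
#' `f(x + delta(t))` with small in-band `delta`, this approximates
#' `f(x + (1 + alpha) * delta(t))`, i.e. a displacement gain of
#' `1 + alpha`.
#'
#' @param signal time-first array (vector / T x P / T x H x W).
#' @param B band-passed signal from [temporalBandpass()]; computed from
#'   `signal` when `bandpass` is supplied and `B` is NULL.
#' @param spec a [MagnificationSpec()].
#' @param bandpass optional [BandpassSpec()] used to compute `B`.
#' @return amplified signal, same shape.
#' @export
amplify <- function(signal, B = NULL, spec = MagnificationSpec(),
                    bandpass = NULL) {
  stopifnot(inherits(spec, "MagnificationSpec"))
  if (is.null(B)) {
    if (is.null(bandpass)) stop("either B or a bandpass spec is required")
    B <- temporalBandpass(signal, bandpass)
  }
  if (!identical(dim(signal), dim(B)) || length(signal) != length(B))
    stop("signal and B shapes differ")
  signal + spec$alpha * B
}

## Central differences along the last (x) dimension; one-sided at the
## edges so linear profiles have exactly zero curvature everywhere.
spatialDeriv <- function(x) {
  f <- foldX(x)
  n <- ncol(f$m)
  if (n < 2) return(f$restore(f$m * 0))
  ip <- c(2, if (n > 2) 3:n, n)
  im <- c(1, if (n > 2) 1:(n - 2), n - 1)
  h <- c(1, rep(2, max(0, n - 2)), 1)
  f$restore(sweep(f$m[, ip, drop = FALSE] - f$m[, im, drop = FALSE],
                  2, h, `/`))
}

foldX <- function(x) {
  d <- dim(x)
  if (is.null(d)) list(m = matrix(x, nrow = 1), restore = as.vector)
  else if (length(d) == 2) list(m = x, restore = identity)
  else list(m = matrix(aperm(x, c(1, 2, 3)), d[1] * d[2], d[3]),
            restore = function(m) array(m, d))
}

#' Pointwise Eulerian magnification error (noise-free)
#'
#' The first-order Taylor truncation error of the magnified signal:
#' `omega = | (1+a)/2 * delta^2 * I_xx - (1+a)^2/2 * delta^2 * I_xx * I_x |`,
#' with spatial derivatives by central differences (reflect padding)
#' along the last (x) dimension.
#'
#' @param signal time-first array (the image signal I).
#' @param delta_est displacement estimate: scalar, per-frame vector or
#'   full array (broadcast over pixels).
#' @param spec a [MagnificationSpec()].
#' @return non-negative error map, same shape as `signal`.
#' @export
magnificationError <- function(signal, delta_est, spec = MagnificationSpec()) {
  a <- spec$alpha
  Ix <- spatialDeriv(signal)
  Ixx <- spatialDeriv(Ix)
  d2 <- broadcastTime(delta_est, signal)^2
  abs(0.5 * (1 + a) * d2 * Ixx - 0.5 * (1 + a)^2 * d2 * Ixx * Ix)
}

broadcastTime <- function(v, like) {
  d <- dim(like)
  if (length(v) == length(like)) return(array(v, d))
  if (length(v) == 1) return(array(v, d %||% length(like)))
  if (!is.null(d) && length(v) == d[1]) return(array(v, d))
  stop("delta_est must be scalar, per-frame, or full-shape")
}

## Robust per-pixel SD of temporal first differences of the out-of-band
## component (everything except DC and the pass-band).
estimateNoiseFloor <- function(signal, bandpass) {
  f <- foldTime(signal)
  inband <- temporalBandpass(f$m, bandpass)
  dc <- matrix(colMeans(f$m), nrow(f$m), ncol(f$m), byrow = TRUE)
  oob <- f$m - inband - dc
  dif <- abs(diff(oob))
  tau <- apply(dif, 2, median) * 1.4826 / sqrt(2)
  list(tau = tau, oob = f$restore(oob))
}

#' Noise-aware Eulerian amplification
#'
#' Second-order magnified signal with pointwise gain attenuation.
#' The additive noise SD `tau` is either supplied
#' (`spec$noise_floor`) or estimated per pixel as the robust SD of
#' temporal first differences outside the pass-band. The effective gain
#' is `alpha * s^2 / (s^2 + k tau^2)` where `s` is the local in-band
#' amplitude, so clean oscillating pixels keep the full gain while
#' noise-dominated pixels are attenuated. The output includes both the
#' noise-free error map (`omega`) and its noisy counterpart
#' (`omega_prime`), which adds the amplified temporal noise derivative
#' and the noise itself.
#'
#' @param signal_noisy time-first array.
#' @param spec a [MagnificationSpec()].
#' @param bandpass a [BandpassSpec()].
#' @return list of class `MagnifiedStack`: `st_amplified`, `omega`,
#'   `omega_prime`, `alpha_eff`, `tau`.
#' @export
amplifyNoiseAware <- function(signal_noisy, spec = MagnificationSpec(),
                              bandpass = BandpassSpec()) {
  f <- foldTime(signal_noisy)
  B <- temporalBandpass(f$m, bandpass)
  nf <- estimateNoiseFloor(f$m, bandpass)
  tau <- if (!is.null(spec$noise_floor))
    rep(spec$noise_floor, ncol(f$m)) else nf$tau
  s_amp <- sqrt(2 * colMeans(B^2))          # in-band amplitude per pixel
  att <- s_amp^2 / (s_amp^2 + spec$noise_k * tau^2 + 1e-300)
  alpha_eff <- spec$alpha * att
  Ae <- matrix(alpha_eff, nrow(f$m), ncol(f$m), byrow = TRUE)

  sig3 <- f$restore(f$m)
  Ix <- spatialDeriv(sig3); Ixx <- spatialDeriv(Ix)
  Ixm <- foldTime(Ix)$m; Ixxm <- foldTime(Ixx)$m
  delta <- B / ifelse(abs(Ixm) > 1e-8, Ixm, Inf)  # delta = B / I_x
  second <- -0.5 * (1 + Ae) * delta^2 * Ixxm * Ixm +
             0.5 * (1 + Ae)^2 * delta^2 * Ixxm
  out <- f$m + Ae * B + second

  a <- spec$alpha
  om <- abs(0.5 * (1 + a) * delta^2 * Ixxm -
            0.5 * (1 + a)^2 * delta^2 * Ixxm * Ixm)
  tau_t <- rbind(nf$oob[1, , drop = FALSE] * 0,
                 diff(foldTime(nf$oob)$m)) * bandpass$sample_rate
  omp <- abs((1 + a) * tau_t + 0.5 * (1 + a) * delta^2 * Ixxm -
             0.5 * (1 + a)^2 * delta^2 * Ixxm * Ixm + foldTime(nf$oob)$m)
  structure(list(st_amplified = f$restore(out), omega = f$restore(om),
                 omega_prime = f$restore(omp), alpha_eff = alpha_eff,
                 tau = tau), class = "MagnifiedStack")
}

#' Sub-band Eulerian magnification of a frame stack
#'
#' Pipeline form of the magnification stage: each frame is decomposed
#' into Mexican-hat spatial sub-bands, every sub-band (and the residual)
#' is temporally band-passed and amplified, and the stack is rebuilt by
#' the exact additive reconstruction. With a scale-independent `alpha`
#' this is numerically equal to amplifying the stack directly (the
#' filter is linear); per-scale `alpha` vectors weight scales
#' differently.
#'
#' @param frames T x H x W array (e.g. an StO2 stack).
#' @param bandpass a [BandpassSpec()].
#' @param alpha scalar or per-scale vector (recycled over
#'   `scales + 1` components, residual last).
#' @param scales pyramid depth.
#' @param noise_aware use [amplifyNoiseAware()] per sub-band.
#' @param noise_k attenuation strength for the noise-aware path.
#' @return amplified T x H x W array.
#' @export
magnifyStack <- function(frames, bandpass = BandpassSpec(), alpha = 20,
                         scales = 3, noise_aware = FALSE, noise_k = 1) {
  dec <- waveletDecompose(frames, scales = scales)
  alphas <- rep_len(alpha, scales + 1)
  comps <- c(lapply(dec$subbands, `[[`, "coeff"), list(dec$residual))
  out <- array(0, dim(frames))
  for (i in seq_along(comps)) {
    sp <- MagnificationSpec(alpha = alphas[i], noise_k = noise_k)
    out <- out + if (noise_aware)
      amplifyNoiseAware(comps[[i]], sp, bandpass)$st_amplified
    else amplify(comps[[i]], spec = sp, bandpass = bandpass)
  }
  out
}
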