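## Shared fixture builders. Everything is generated in code; no stored
## binary data.

## Small valid multispectral stack with reproducible values.
makeTestStack <- function(T_ = 3, H = 6, W = 5, seed = 1,
                          integer_values = FALSE) {
  set.seed(seed)
  d <- array(runif(T_ * 4 * H * W, 100, 5000), c(T_, 4, H, W))
  if (integer_values) d <- round(d)
  SpectralFrameStack(d, c(540, 556, 560, 576), 30, "fixture")
}

## Forward-generate an absorbance array from known concentrations so
## the inversion can be checked against ground truth.
forwardAbsorbance <- function(basis, c_hbo2, c_hb, c_mel, gp) {
  dm <- designMatrix(basis)
  T_ <- dim(c_hbo2)[1]; H <- dim(c_hbo2)[2]; W <- dim(c_hbo2)[3]
  A <- array(0, c(T_, 4, H, W))
  for (b in 1:4)
    A[, b, , ] <- dm[b, 1] * c_hbo2 + dm[b, 2] * c_hb +
      dm[b, 3] * c_mel + dm[b, 4] * gp
  A
}

## Reference single-neighbor VLAD (independent oracle).
referenceVlad <- function(features, words) {
  M <- nrow(words); D <- ncol(words)
  V <- matrix(0, M, D)
  for (i in seq_len(nrow(features))) {
    r <- features[i, ]
    nn <- which.min(colSums((t(words) - r)^2))
    V[nn, ] <- V[nn, ] + r - words[nn, ]
  }
  V
}

## Sub-pixel edge tracker: position where a monotone profile crosses
## `level`, by linear interpolation (displacement oracle).
trackCrossing <- function(profile, level = 0.5) {
  i <- max(which(profile < level))
  i + (level - profile[i]) / (profile[i + 1] - profile[i])
}

## Fitted sinusoid amplitude of a per-frame position trace.
fitAmplitude <- function(pos, freq_hz, fs) {
  t <- (seq_along(pos) - 1) / fs
  X <- cbind(sin(2 * pi * freq_hz * t), cos(2 * pi * freq_hz * t))
  cf <- coef(lm(pos ~ X))
  sqrt(cf[2]^2 + cf[3]^2)
}

## Translating linear-ramp image stack: f(x + d * sin(2 pi f t)).
rampStack <- function(T_ = 300, W = 64, d = 0.2, freq = 1.5, fs = 30,
                      ramp_from = 12, ramp_len = 40, clamp = TRUE) {
  t <- (seq_len(T_) - 1) / fs
  x <- seq_len(W)
  stk <- array(0, c(T_, 1, W))
  for (i in seq_len(T_)) {
    v <- (x - ramp_from - d * sin(2 * pi * freq * t[i])) / ramp_len
    if (clamp) v <- pmin(pmax(v, 0), 1)
    stk[i, 1, ] <- v
  }
  stk
}
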