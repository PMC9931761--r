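## Composite ROI selection. Candidate facial regions are scored by
## epsilon = m * lambda_MSC + n * delta, where lambda_MSC compares the
## top eigenvalue of the across-subject equal-time correlation matrix
## with the Marchenko-Pastur upper edge (universality of the response),
## and delta is a coarse-wavelet normalized correlation against a known
## strong response signal (strength of the response).

#' Row-wise z-score a subject x time panel
#'
#' Each subject's StO2 series is centred and scaled by its population
#' standard deviation (the 1/T convention, matching the 1/T in the
#' correlation matrix). Rows with zero variance are rejected.
#'
#' @param series numeric N x T matrix (subjects x frames), T >= 2.
#' @return N x T matrix with row means 0 and population SDs 1.
#' @export
normalizePanel <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("panel needs at least T = 2 frames")
  mu <- rowMeans(series)
  centered <- series - mu
  sdp <- sqrt(rowMeans(centered^2))          # population SD
  if (any(sdp <= 0))
    stop("degenerate signal: zero-variance row(s) ",
         paste(which(sdp <= 0), collapse = ", "))
  out <- centered / sdp
  dimnames(out) <- NULL
  out
}

#' Equal-time correlation matrix across subjects
#'
#' `CR_ET = (1/T) * panel %*% t(panel)` for a row-normalized panel:
#' the zero-lag Pearson correlation matrix, symmetric with unit
#' diagonal.
#'
#' @param panel output of [normalizePanel()].
#' @return N x N correlation matrix.
#' @export
equalTimeCorrelation <- function(panel) {
  panel <- as.matrix(panel)
  cr <- tcrossprod(panel) / ncol(panel)
  (cr + t(cr)) / 2
}

#' Marchenko-Pastur reference for a random correlation matrix
#'
#' For N independent series of length T with aspect ratio `U = T/N > 1`,
#' the eigenvalue support of the correlation matrix is
#' `[lambda_minus, lambda_plus]` with
#' `lambda_pm = 1 + 1/U +- 2/sqrt(U)` and density
#' `E(lambda) = (U / 2 pi) sqrt((lambda_plus - lambda)(lambda -
#' lambda_minus)) / lambda` on the support, 0 outside. Eigenvalues above
#' `lambda_plus` indicate genuine cross-subject correlation.
#'
#' @param n_subjects N >= 2.
#' @param t_frames T > N.
#' @return list with `u_ratio`, `lambda_minus`, `lambda_plus` and a
#'   vectorized `density(lambda)` evaluator.
#' @examples
#' rmtReference(10, 40)$lambda_plus   # U = 4 -> 2.25
#' @export
rmtReference <- function(n_subjects, t_frames) {
  U <- t_frames / n_subjects
  if (n_subjects < 2 || U <= 1)
    stop("Marchenko-Pastur bound requires T > N >= 2 (U > 1)")
  lm <- 1 + 1 / U - 2 / sqrt(U)
  lp <- 1 + 1 / U + 2 / sqrt(U)
  density <- function(lambda) {
    out <- numeric(length(lambda))
    inside <- lambda >= lm & lambda <= lp & lambda > 0
    out[inside] <- (U / (2 * pi)) *
      sqrt((lp - lambda[inside]) * (lambda[inside] - lm)) / lambda[inside]
    out
  }
  list(u_ratio = U, lambda_minus = lm, lambda_plus = lp, density = density)
}

#' Full correlation report for one ROI panel
#'
#' Bundles the correlation matrix, its sorted eigenvalues, the
#' Marchenko-Pastur edges and the multisubject-correlation statistic
#' `lambda_MSC = lambda_max / lambda_plus`.
#'
#' @param panel row-normalized N x T panel (see [normalizePanel()]).
#' @return list of class `CorrelationReport`.
#' @export
correlationReport <- function(panel) {
  panel <- as.matrix(panel)
  cr <- equalTimeCorrelation(panel)
  ev <- sort(eigen(cr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ref <- rmtReference(nrow(panel), ncol(panel))
  structure(list(cr_et = cr, eigenvalues = ev, u_ratio = ref$u_ratio,
                 lambda_minus = ref$lambda_minus,
                 lambda_plus = ref$lambda_plus,
                 lambda_msc = ev[1] / ref$lambda_plus),
            class = "CorrelationReport")
}

#' Multisubject correlation statistic
#'
#' `lambda_MSC = lambda_max / lambda_plus`; values above 1 flag genuine
#' cross-subject correlation (the top eigenvalue escapes the random
#' bulk).
#'
#' @param report a `CorrelationReport` from [correlationReport()].
#' @return list with `ratio` and logical `correlated = ratio > 1`.
#' @export
lambdaMsc <- function(report) {
  list(ratio = report$lambda_msc, correlated = report$lambda_msc > 1)
}

#' Windowed feature-vector sequence of a five-channel ROI series
#'
#' Per non-overlapping window of `window` frames and per channel
#' (M1..M4, then S), the mean and the population variance, concatenated
#' in channel order: 10 numbers per window.
#'
#' @param series data.frame from [roiChannelSeries()] (or any
#'   `frame_index` + channels table).
#' @param window window length in frames, >= 2 and <= number of frames.
#' @return matrix `n_windows x (2 * n_channels)`, columns
#'   `mu_<ch>, var_<ch>` per channel.
#' @export
buildFV <- function(series, window) {
  ch <- as.matrix(series[, setdiff(names(series), "frame_index"),
                         drop = FALSE])
  T_ <- nrow(ch)
  if (window < 2) stop("window must span at least 2 frames")
  if (window > T_) stop("window longer than the series")
  nw <- T_ %/% window
  out <- matrix(0, nw, 2 * ncol(ch))
  for (w in seq_len(nw)) {
    block <- ch[((w - 1) * window + 1):(w * window), , drop = FALSE]
    mu <- colMeans(block)
    va <- colMeans(sweep(block, 2, mu)^2)    # population variance
    out[w, ] <- as.vector(rbind(mu, va))
  }
  colnames(out) <- as.vector(rbind(paste0("mu_", colnames(ch)),
                                   paste0("var_", colnames(ch))))
  out
}

## Dyadic level chosen so the step-function sampling has a desk-friendly
## number of points; finer detail is deliberately discarded.
chooseCoarseLevel <- function(period_p, lo = 64, hi = 256) {
  j <- ceiling(log2(lo / period_p))
  while (ceiling(period_p * 2^j) > hi && j > -30) j <- j - 1
  j
}

#' Coarse-scale inner product of two feature-vector sequences
#'
#' Both sequences are treated as vector-valued step functions on the
#' period [0, P] (P in window units), sampled at the dyadic grid
#' `t = l / 2^j`, and correlated with an orthonormal scaling basis
#' (identity Gram matrix). The result is normalized by the product of
#' norms, hence lies in [-1, 1]; signals are centred first so the value
#' is a correlation, not a raw cosine.
#'
#' @param fv_a,fv_b FV sequences (matrices or vectors) covering [0, P].
#' @param level_j dyadic sampling level; default picks j so the sample
#'   count lands in [64, 256].
#' @param period_p period in window units; defaults to the sequence
#'   length.
#' @return scalar in [-1, 1].
#' @export
coarseInnerProduct <- function(fv_a, fv_b, level_j = NULL, period_p = NULL) {
  a <- as.matrix(fv_a); b <- as.matrix(fv_b)
  if (nrow(a) != nrow(b))
    stop("both FV sequences must cover the same period")
  P <- period_p %||% nrow(a)
  j <- level_j %||% chooseCoarseLevel(P)
  nsamp <- floor(P * 2^j)
  if (nsamp < 1) stop("period shorter than one sampling step at level ", j)
  ## step-function sampling a_l = FV(l / 2^j)
  l <- 0:(nsamp - 1)
  idx <- pmin(floor(l / 2^j / P * nrow(a)) + 1L, nrow(a))
  sa <- a[idx, , drop = FALSE]; sb <- b[idx, , drop = FALSE]
  sa <- sweep(sa, 2, colMeans(sa)); sb <- sweep(sb, 2, colMeans(sb))
  num <- sum(sa * sb)                       # identity Gram
  den <- sqrt(sum(sa^2)) * sqrt(sum(sb^2))
  if (den == 0) return(0)
  max(-1, min(1, num / den))
}

#' Strength correlation of an ROI against a strong reference signal
#'
#' Maps the coarse inner product monotonically onto [0, 1]:
#' `delta = (cip + 1) / 2`. A perfect match gives 1, a sign-flipped
#' signal 0, an unrelated signal about 0.5.
#'
#' @param fv_roi FV sequence of the candidate ROI.
#' @param fv_reference_strong FV sequence of the known strong stress
#'   response; see [selectRoi()] for the default construction.
#' @param ... passed to [coarseInnerProduct()].
#' @return scalar in [0, 1].
#' @export
deltaStrength <- function(fv_roi, fv_reference_strong, ...) {
  if (missing(fv_reference_strong) || is.null(fv_reference_strong))
    stop("a strong-response reference FV sequence is required")
  (coarseInnerProduct(fv_roi, fv_reference_strong, ...) + 1) / 2
}

## Default strong-response reference: the cohort-median FV sequence of
## the ROI whose band-passed StO2 panels carry the largest variance.
strongReference <- function(panels, fvs, sample_rate, f_lo, f_hi) {
  bpvar <- vapply(names(panels), function(roi) {
    p <- as.matrix(panels[[roi]])
    bp <- temporalBandpass(t(p), BandpassSpec(f_lo, f_hi, sample_rate))
    mean(bp^2)
  }, numeric(1))
  strong <- names(panels)[which.max(bpvar)]
  seqs <- fvs[[strong]]
  arr <- simplify2array(seqs)               # windows x 10 x subjects
  ref <- apply(arr, c(1, 2), median)
  list(roi = strong, fv = ref)
}

#' Rank candidate ROIs by the composite criterion
#'
#' For every candidate region, computes `lambda_MSC` from the
#' across-subject StO2 panel and `delta` (mean over subjects) against a
#' strong-response reference, then the composite score
#' `epsilon = m * min(lambda_MSC / 2, 1) + n * delta`, which lies in
#' [0, 1] for m + n = 1. The returned table is sorted by decreasing
#' epsilon with lexicographic tie-break on the ROI name.
#'
#' @param panels named list (one entry per ROI) of N x T raw StO2
#'   panels, subjects in rows.
#' @param fvs named list (per ROI) of per-subject FV sequences from
#'   [buildFV()].
#' @param m,n non-negative weights with `m + n = 1`.
#' @param reference optional FV sequence overriding the default
#'   strong-response reference.
#' @param sample_rate,f_lo,f_hi band definition used only to pick the
#'   default reference ROI.
#' @return data.frame of class `ROIScore` with columns `roi`,
#'   `lambda_msc`, `lambda_msc_scaled`, `delta`, `epsilon`; attribute
#'   `reference_roi` names the reference used.
#' @export
selectRoi <- function(panels, fvs, m = 0.5, n = 0.5, reference = NULL,
                      sample_rate = 30, f_lo = 1.2, f_hi = 2.0) {
  if (length(panels) < 2) stop("need at least 2 candidate ROIs")
  if (m < 0 || n < 0 || abs(m + n - 1) > 1e-9)
    stop("weights must satisfy m, n >= 0 and m + n = 1")
  rois <- sort(names(panels))
  if (!all(rois %in% names(fvs)))
    stop("every ROI needs both a panel and an FV set")
  ref_roi <- NA_character_
  if (is.null(reference)) {
    sr <- strongReference(panels, fvs, sample_rate, f_lo, f_hi)
    reference <- sr$fv
    ref_roi <- sr$roi
  }
  rows <- lapply(rois, function(roi) {
    rep_ <- correlationReport(normalizePanel(panels[[roi]]))
    lam <- lambdaMsc(rep_)$ratio
    del <- mean(vapply(fvs[[roi]], deltaStrength, numeric(1),
                       fv_reference_strong = reference))
    lam_s <- min(lam / 2, 1)
    data.frame(roi = roi, lambda_msc = lam, lambda_msc_scaled = lam_s,
               delta = del, epsilon = m * lam_s + n * del)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$epsilon, out$roi), ]
  rownames(out) <- NULL
  attr(out, "reference_roi") <- ref_roi
  attr(out, "weights") <- c(m = m, n = n)
  class(out) <- c("ROIScore", "data.frame")
  out
}
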