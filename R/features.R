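## Dense local descriptors for the encoder: gradient-orientation
## histograms (8 orientation bins x 4 x 4 cells = 128 dims) on a dense
## grid, L2-normalized per descriptor. Dense sampling suits the
## low-texture StO2 maps better than interest-point detection.

#' Dense gradient-orientation-histogram features
#'
#' Extracts 128-dimensional descriptors (8 orientation bins over a
#' 4 x 4 cell grid) at dense grid positions of every frame of a window
#' stack. Gradients are central differences with reflect padding;
#' magnitudes are accumulated into orientation bins per cell; each
#' descriptor is L2-normalized. All-zero descriptors (flat patches) are
#' excluded and counted in the `n_dropped` attribute.
#'
#' @param frames T x H x W array (a single frame is accepted as H x W),
#'   `H, W >= 16`.
#' @param patch descriptor support in pixels (multiple of 4).
#' @param stride dense-grid stride in pixels.
#' @return list of class `LocalFeatureSet`: `features` (N x 128 matrix)
#'   and `positions` (N x 3: frame, row, col of the patch origin,
#'   1-based); attribute `n_dropped`.
#' @export
extractLocalFeatures <- function(frames, patch = 16, stride = 8) {
  if (is.matrix(frames)) frames <- array(frames, c(1, dim(frames)))
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be H x W or T x H x W")
  if (d[2] < 16 || d[3] < 16)
    stop("window too small: need at least 16 x 16 pixels")
  if (patch %% 4 != 0) stop("patch must be a multiple of 4")
  if (patch > min(d[2:3])) stop("patch larger than the frame")
  T_ <- d[1]; H <- d[2]; W <- d[3]
  cell <- patch %/% 4

  ## gradients over the whole stack (central differences, reflect)
  gy <- alongDim2Deriv(frames)
  gx <- spatialDeriv(frames)
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                      # (-pi, pi]
  bin <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1L, 8L)

  rows0 <- seq(1, H - patch + 1, by = stride)
  cols0 <- seq(1, W - patch + 1, by = stride)
  feats <- list(); pos <- list(); dropped <- 0L; k <- 1L
  magM <- matrix(mag, T_, H * W); binM <- matrix(bin, T_, H * W)
  for (r0 in rows0) for (c0 in cols0) {
    ## pixel -> cell map for this patch
    pr <- r0:(r0 + patch - 1); pc <- c0:(c0 + patch - 1)
    pix <- as.vector(outer(pr, (pc - 1) * H, `+`))
    cellIdx <- as.vector(outer((pr - r0) %/% cell + 1L,
                               ((pc - c0) %/% cell) * 4L, `+`))
    Mg <- magM[, pix, drop = FALSE]; Bn <- binM[, pix, drop = FALSE]
    cellInd <- matrix(0, length(pix), 16)
    cellInd[cbind(seq_along(pix), cellIdx)] <- 1
    desc <- matrix(0, T_, 128)
    for (b in 1:8) {                        # orientation-bin masks
      desc[, seq(b, 128, by = 8)] <- ((Bn == b) * Mg) %*% cellInd
    }
    nrm <- sqrt(rowSums(desc^2))
    keep <- nrm > 0
    dropped <- dropped + sum(!keep)
    if (any(keep)) {
      feats[[k]] <- desc[keep, , drop = FALSE] / nrm[keep]
      pos[[k]] <- cbind(frame = which(keep), row = r0, col = c0)
      k <- k + 1L
    }
  }
  features <- if (length(feats)) do.call(rbind, feats)
              else matrix(0, 0, 128)
  positions <- if (length(pos)) do.call(rbind, pos)
               else matrix(0L, 0, 3)
  structure(list(features = features, positions = positions),
            class = "LocalFeatureSet", n_dropped = dropped)
}

## Central differences along the height (row) dimension.
alongDim2Deriv <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(1, 3, 2))               # T x W x H
  out <- spatialDeriv(xp)
  aperm(out, c(1, 3, 2))
}
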