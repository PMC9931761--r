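## S4 containers for the pipeline's central data objects.

#' Multispectral frame stack
#'
#' A stack of multi-band video frames: a 4-D numeric array laid out
#' frames x bands x height x width, together with the band wavelengths,
#' the acquisition frame rate and a subject label. This is the raw input
#' of the pipeline (the default acquisition uses four bands at
#' 540/556/560/576 nm sampled at 30 Hz).
#'
#' @slot data numeric 4-D array, `T x B x H x W`, finite and non-negative.
#' @slot wavelengths_nm strictly increasing numeric vector of length `B`.
#' @slot frame_rate_hz positive scalar, frames per second.
#' @slot subject_id character label.
#' @export
setClass("SpectralFrameStack",
  representation(data = "array", wavelengths_nm = "numeric",
                 frame_rate_hz = "numeric", subject_id = "character"))

setValidity("SpectralFrameStack", function(object) {
  d <- object@data
  msg <- character(0)
  if (length(dim(d)) != 4)
    msg <- c(msg, "data must be a 4-D array (frames x bands x H x W)")
  else {
    if (dim(d)[1] < 1) msg <- c(msg, "need at least one frame")
    if (dim(d)[2] != length(object@wavelengths_nm))
      msg <- c(msg, "number of bands must match length(wavelengths_nm)")
    rng <- suppressWarnings(range(d))     # single pass over the array
    if (anyNA(rng) || !all(is.finite(rng)) || rng[1] < 0)
      msg <- c(msg, "intensities must be finite and >= 0")
  }
  if (length(object@wavelengths_nm) >= 2 &&
      any(diff(object@wavelengths_nm) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(object@frame_rate_hz) != 1 || !is.finite(object@frame_rate_hz) ||
      object@frame_rate_hz <= 0)
    msg <- c(msg, "frame_rate_hz must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralFrameStack
#'
#' @param data 4-D array, frames x bands x height x width.
#' @param wavelengths_nm band wavelengths in nanometres.
#' @param frame_rate_hz acquisition rate in Hz.
#' @param subject_id subject label.
#' @return A validated [SpectralFrameStack-class] object.
#' @examples
#' s <- SpectralFrameStack(array(1, c(2, 4, 4, 4)),
#'                         c(540, 556, 560, 576), 30)
#' dim(stackData(s))
#' @export
SpectralFrameStack <- function(data, wavelengths_nm = c(540, 556, 560, 576),
                               frame_rate_hz = 30, subject_id = "subject") {
  new("SpectralFrameStack", data = data,
      wavelengths_nm = as.numeric(wavelengths_nm),
      frame_rate_hz = as.numeric(frame_rate_hz),
      subject_id = as.character(subject_id))
}

#' Catalog of named region-of-interest masks
#'
#' Binary H x W masks sharing the frame geometry of a stack. The default
#' candidate set covers seven facial regions: forehead, nose, left_face,
#' right_face, mouth, meixin (middle-eyebrow region) and philtrum.
#'
#' @slot masks named list of logical H x W matrices, each non-empty.
#' @export
setClass("ROICatalog", representation(masks = "list"))

setValidity("ROICatalog", function(object) {
  m <- object@masks
  msg <- character(0)
  if (length(m) == 0) msg <- c(msg, "catalog must contain at least one mask")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    msg <- c(msg, "all masks must be named")
  dims <- lapply(m, dim)
  if (length(m)) {
    if (any(!vapply(m, is.logical, logical(1))))
      msg <- c(msg, "masks must be logical matrices")
    else {
      if (any(vapply(m, function(x) sum(x) == 0, logical(1))))
        msg <- c(msg, "every mask must be non-empty")
      if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
        msg <- c(msg, "all masks must share the same H x W geometry")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ROICatalog
#'
#' @param masks named list of logical matrices.
#' @return A validated [ROICatalog-class].
#' @export
ROICatalog <- function(masks) new("ROICatalog", masks = masks)

#' Chromophore extinction basis
#'
#' Molar absorptivities of oxyhemoglobin, deoxyhemoglobin and melanin at
#' the acquisition wavelengths, in any consistent linear scale. The
#' derived 4 x 4 design matrix `[eps_hbo2 | eps_hb | eps_melanin | 1]`
#' must be nonsingular so the four-band Beer-Lambert system has a unique
#' exact solution.
#'
#' @slot wavelengths_nm numeric wavelengths.
#' @slot eps_hbo2,eps_hb,eps_melanin positive absorptivities per wavelength.
#' @export
setClass("ChromophoreBasis",
  representation(wavelengths_nm = "numeric", eps_hbo2 = "numeric",
                 eps_hb = "numeric", eps_melanin = "numeric"))

setValidity("ChromophoreBasis", function(object) {
  n <- length(object@wavelengths_nm)
  msg <- character(0)
  if (length(object@eps_hbo2) != n || length(object@eps_hb) != n ||
      length(object@eps_melanin) != n)
    msg <- c(msg, "one absorptivity per wavelength per chromophore required")
  eps <- c(object@eps_hbo2, object@eps_hb, object@eps_melanin)
  if (any(!is.finite(eps)) || any(eps <= 0))
    msg <- c(msg, "absorptivities must be finite and > 0")
  if (n == 4 && length(msg) == 0) {
    dm <- cbind(object@eps_hbo2, object@eps_hb, object@eps_melanin, 1)
    if (abs(det(dm)) < .Machine$double.eps * max(abs(dm))^4)
      msg <- c(msg, "design matrix [eps_hbo2|eps_hb|eps_melanin|1] is singular")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ChromophoreBasis
#'
#' @param wavelengths_nm band wavelengths.
#' @param eps_hbo2,eps_hb,eps_melanin absorptivities per wavelength.
#' @return A validated [ChromophoreBasis-class].
#' @export
ChromophoreBasis <- function(wavelengths_nm, eps_hbo2, eps_hb, eps_melanin) {
  new("ChromophoreBasis", wavelengths_nm = as.numeric(wavelengths_nm),
      eps_hbo2 = as.numeric(eps_hbo2), eps_hb = as.numeric(eps_hb),
      eps_melanin = as.numeric(eps_melanin))
}

#' Per-pixel effective chromophore concentrations
#'
#' Result of the per-pixel four-band Beer-Lambert solve: effective
#' concentrations of HbO2, Hb and melanin plus the residual offset G'
#' collecting wavelength-flat nuisance terms (specular reflection,
#' regression error). Negative recovered concentrations are kept, not
#' clipped, to preserve diagnosability.
#'
#' @slot c_hbo2,c_hb,c_melanin,g_prime numeric T x H x W arrays.
#' @export
setClass("ChromophoreMap",
  representation(c_hbo2 = "array", c_hb = "array", c_melanin = "array",
                 g_prime = "array"))

setValidity("ChromophoreMap", function(object) {
  ds <- list(dim(object@c_hbo2), dim(object@c_hb), dim(object@c_melanin),
             dim(object@g_prime))
  msg <- character(0)
  if (length(unique(vapply(ds, paste, character(1), collapse = "x"))) != 1)
    msg <- c(msg, "all four fields must share the same T x H x W shape")
  finiteArr <- function(x) {
    r <- suppressWarnings(range(x))
    !anyNA(r) && all(is.finite(r))
  }
  if (!finiteArr(object@c_hbo2) || !finiteArr(object@c_hb) ||
      !finiteArr(object@c_melanin) || !finiteArr(object@g_prime))
    msg <- c(msg, "all fields must be finite")
  if (length(msg)) msg else TRUE
})

#' Tissue oxygen saturation stack
#'
#' Per-pixel StO2 fraction `c_hbo2 / (c_hbo2 + c_hb)` clipped to [0, 1];
#' pixels with non-positive total hemoglobin are NaN.
#'
#' @slot sto2 numeric T x H x W array in [0,1] or NaN.
#' @export
setClass("StO2Stack", representation(sto2 = "array"))

setValidity("StO2Stack", function(object) {
  rng <- suppressWarnings(range(object@sto2, na.rm = TRUE))
  if (!anyNA(rng) && is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    "sto2 values must lie in [0,1] or be NaN" else TRUE
})

#' Visual codebook for VLAD encoding
#'
#' K-means cluster centers ("visual words") over local-feature space,
#' with the training seed and iteration metadata.
#'
#' @slot words numeric M x D matrix of distinct centers.
#' @slot seed integer training seed.
#' @slot iterations iterations used by the k-means fit.
#' @export
setClass("Codebook",
  representation(words = "matrix", seed = "integer", iterations = "integer"))

setValidity("Codebook", function(object) {
  w <- object@words
  msg <- character(0)
  if (nrow(w) < 2) msg <- c(msg, "codebook needs at least 2 words")
  if (any(!is.finite(w))) msg <- c(msg, "words must be finite")
  if (nrow(w) >= 2 && min(dist(w)) <= 0)
    msg <- c(msg, "codebook centers must be pairwise distinct")
  if (length(msg)) msg else TRUE
})

#' Five-layer codeword neighbor graph (MSM)
#'
#' Multidimensional spatial relationship map over codewords: each word is
#' assigned to one of five layers; each word has up to six 1-hop
#' neighbors chosen nearest-first but balanced across layers, and up to
#' two 2-hop neighbors drawn from neighbors-of-neighbors.
#'
#' @slot layer integer layer index (1..5) per codeword.
#' @slot one_hop list of integer neighbor indices (length <= 6 each).
#' @slot two_hop list of integer neighbor indices (length <= 2 each).
#' @export
setClass("MSMGraph",
  representation(layer = "integer", one_hop = "list", two_hop = "list"))

setValidity("MSMGraph", function(object) {
  m <- length(object@layer)
  msg <- character(0)
  if (length(object@one_hop) != m || length(object@two_hop) != m)
    msg <- c(msg, "neighbor lists must have one entry per codeword")
  if (m && (min(object@layer) < 1 || max(object@layer) > 5))
    msg <- c(msg, "layers must be indices in 1..5")
  for (i in seq_len(m)) {
    if (i %in% object@one_hop[[i]] || i %in% object@two_hop[[i]])
      return("neighbor lists must not contain self-loops")
    if (length(object@one_hop[[i]]) > 6) return("at most 6 one-hop neighbors")
    if (length(object@two_hop[[i]]) > 2) return("at most 2 two-hop neighbors")
  }
  if (length(msg)) msg else TRUE
})
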