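## Readers/writers for the pipeline's on-disk formats: multi-page TIFF
## cubes with a JSON metadata sidecar, and per-frame channel CSV tables.
##
## Pages are ordered frame-major, band-minor (frame 1 bands 1..B, then
## frame 2, ...). Two pixel encodings are used so that read(write(x)) is
## the identity: integer stacks whose values fit 16 bits are written as
## native 16-bit pages ("uint16"); anything else is written bit-exactly
## as IEEE-754 byte planes ("float64"). The sidecar records the choice.

doubleToBytePlane <- function(m) {
  b <- writeBin(as.vector(m), raw(), size = 8, endian = "little")
  matrix(as.integer(b) / 255, nrow = nrow(m), ncol = ncol(m) * 8)
}

bytePlaneToDouble <- function(p, h, w) {
  b <- as.raw(round(p * 255))
  matrix(readBin(b, "double", n = h * w, size = 8, endian = "little"),
         nrow = h, ncol = w)
}

#' Write a multispectral stack to a TIFF cube with JSON sidecar
#'
#' @param stack a [SpectralFrameStack-class].
#' @param path TIFF output path.
#' @param sidecar JSON sidecar path; defaults to `path` with a
#'   `.json` extension appended.
#' @return Invisibly, the sidecar path.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(is(stack, "SpectralFrameStack"))
  d <- stack@data
  dm <- dim(d)
  integral <- all(d == round(d)) && max(d) <= 65535
  pages <- vector("list", dm[1] * dm[2])
  k <- 1
  for (t in seq_len(dm[1])) for (b in seq_len(dm[2])) {
    frame <- matrix(d[t, b, , ], dm[3], dm[4])
    pages[[k]] <- if (integral) frame / 65535 else doubleToBytePlane(frame)
    k <- k + 1
  }
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (integral) 16L else 8L,
                  compression = "none", reduce = FALSE)
  meta <- list(wavelengths_nm = stack@wavelengths_nm,
               frame_rate_hz = stack@frame_rate_hz,
               subject_id = stack@subject_id,
               height = dm[3], width = dm[4],
               encoding = if (integral) "uint16" else "float64")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  stageLog("write_stack", path = path, frames = dm[1], bands = dm[2],
           digest = contentDigest(d))
  invisible(sidecar)
}

#' Read a multispectral stack from a TIFF cube with JSON sidecar
#'
#' The TIFF pages must be ordered frame-major, band-minor and the JSON
#' sidecar must carry `wavelengths_nm` and `frame_rate_hz`.
#'
#' @param path TIFF container path.
#' @param sidecar JSON metadata path.
#' @return A validated [SpectralFrameStack-class].
#' @export
readStack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("wavelengths_nm", "frame_rate_hz"))
    if (is.null(meta[[key]]))
      stop("sidecar is missing required key '", key, "'")
  pages <- tiff::readTIFF(path, all = TRUE)
  B <- length(meta$wavelengths_nm)
  if (length(pages) %% B != 0)
    stop(sprintf("page count %d is not divisible by band count %d",
                 length(pages), B))
  T_ <- length(pages) %/% B
  enc <- meta$encoding %||% "uint16"
  h <- meta$height %||% nrow(pages[[1]])
  w <- meta$width %||%
    (if (enc == "float64") ncol(pages[[1]]) %/% 8 else ncol(pages[[1]]))
  d <- array(0, c(T_, B, h, w))
  k <- 1
  for (t in seq_len(T_)) for (b in seq_len(B)) {
    d[t, b, , ] <- if (enc == "float64")
      bytePlaneToDouble(pages[[k]], h, w)
    else round(pages[[k]] * 65535)
    k <- k + 1
  }
  SpectralFrameStack(d, meta$wavelengths_nm, meta$frame_rate_hz,
                     meta$subject_id %||% "subject")
}

#' Write / read a real-valued T x H x W map as a TIFF cube
#'
#' For derived per-pixel maps (StO2, magnified stacks, error maps) that
#' may be negative: frames are stored bit-exactly as IEEE-754 byte
#' planes with a JSON sidecar carrying the frame rate.
#'
#' @param arr numeric T x H x W array.
#' @param path TIFF path.
#' @param frame_rate_hz frames per second recorded in the sidecar.
#' @param sidecar JSON sidecar path.
#' @return `writeMapTiff` invisibly returns `path`; `readMapTiff`
#'   returns a list with `arr` and `frame_rate_hz`.
#' @export
writeMapTiff <- function(arr, path, frame_rate_hz = 30,
                         sidecar = paste0(path, ".json")) {
  d <- dim(arr)
  stopifnot(length(d) == 3)
  pages <- lapply(seq_len(d[1]), function(t)
    doubleToBytePlane(matrix(arr[t, , ], d[2], d[3])))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(kind = "map", frame_rate_hz = frame_rate_hz,
                            frames = d[1], height = d[2], width = d[3],
                            encoding = "float64"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), meta$height, meta$width))
  for (t in seq_along(pages))
    arr[t, , ] <- bytePlaneToDouble(pages[[t]], meta$height, meta$width)
  list(arr = arr, frame_rate_hz = meta$frame_rate_hz)
}

#' Write a per-frame channel table to CSV
#'
#' The table must be rectangular and fully finite, with a `frame_index`
#' column followed by one column per channel.
#'
#' @param series data.frame with `frame_index` first.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeRoiCsv <- function(series, path) {
  if (!is.data.frame(series) || names(series)[1] != "frame_index")
    stop("series must be a data.frame with 'frame_index' as first column")
  if (!all(vapply(series, is.numeric, logical(1))))
    stop("series must be numeric")
  if (!all(vapply(series, function(x) all(is.finite(x)), logical(1))))
    stop("series contains non-finite values; refusing to write")
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-frame channel table written by [writeRoiCsv()]
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
readRoiCsv <- function(path) read.csv(path)

#' Write and read an ROI catalog as JSON
#'
#' Masks are serialized as 0/1 integer matrices with their names.
#'
#' @param catalog an [ROICatalog-class].
#' @param path JSON path.
#' @return `writeRoiCatalog` invisibly returns `path`; `readRoiCatalog`
#'   returns an `ROICatalog`.
#' @export
writeRoiCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "ROICatalog"))
  jsonlite::write_json(lapply(roiMasks(catalog), function(m) {
    storage.mode(m) <- "integer"
    unname(m)
  }), path)
  invisible(path)
}

#' @rdname writeRoiCatalog
#' @export
readRoiCatalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ROICatalog(lapply(raw, function(m) matrix(as.logical(m), nrow(m), ncol(m))))
}
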