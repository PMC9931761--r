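## Run configuration: every tunable of every stage, with documented
## defaults, serializable to YAML and back without loss.

#' Pipeline run configuration
#'
#' Builds the full set of tunables consumed by [runAll()] and the stage
#' functions, as a nested named list of class `ScnetConfig`. Any field
#' may be overridden by name; unknown fields are rejected.
#'
#' Defaults (units in brackets):
#' * `seed` master seed for every source of randomness.
#' * `bandpass$f_lo`, `bandpass$f_hi` [Hz]: 1.2 and 2.0 — the
#'   amplification band used as the stress-discriminative range.
#' * `magnify$alpha`: 20 — conservative Eulerian amplification factor.
#' * `magnify$scales`: 3 Mexican-hat pyramid scales;
#'   `magnify$noise_aware`: FALSE (linear amplification path).
#' * `roi$m`, `roi$n`: 0.5/0.5 — composite-score weights (equal
#'   evidence weighting; both components are scale-normalized first).
#' * `encode$codebook_m`: 16 codewords, `encode$k_nn`: 3 neighbor cap,
#'   `encode$max_train_features`: subsample bound for k-means.
#' * `window_s` [s]: 2 — descriptor window length.
#' * `lstm`: 1 layer of 32 hidden units at desk scale, Adam lr 1e-3,
#'   up to 60 epochs, early-stopping patience 20.
#' * `synthetic`: see [syntheticConfig()].
#'
#' @param ... named overrides, e.g. `scnetConfig(magnify = list(alpha = 10))`
#'   (partial nested lists are merged into the defaults).
#' @return A named list of class `ScnetConfig`.
#' @examples
#' cfg <- scnetConfig(seed = 7, roi = list(m = 0.7, n = 0.3))
#' cfg$roi$m
#' @export
scnetConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    wavelengths_nm = c(540, 556, 560, 576),
    frame_rate_hz = 30,
    window_s = 2,
    bandpass = list(f_lo = 1.2, f_hi = 2.0),
    magnify = list(alpha = 20, scales = 3L, noise_aware = FALSE,
                   noise_k = 1),
    roi = list(m = 0.5, n = 0.5),
    encode = list(codebook_m = 16L, k_nn = 3L, grid_stride = 8L,
                  patch = 16L, max_train_features = 4000L),
    lstm = list(layers = 1L, hidden = 8L, lr = 1e-3, epochs = 60L,
                patience = 30L, restarts = 5L, ensemble = TRUE),
    synthetic = syntheticConfig()
  )
  mergeConfig(cfg, list(...), "config")
}

mergeConfig <- function(base, over, where) {
  if (length(over) == 0) return(structure(base, class = "ScnetConfig"))
  nm <- names(over)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("configuration overrides must be named")
  for (k in nm) {
    if (!k %in% names(base))
      stop(sprintf("unknown %s field '%s'", where, k))
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      modifyList(base[[k]], over[[k]]) else over[[k]]
  }
  structure(base, class = "ScnetConfig")
}

#' Serialize / deserialize a run configuration as YAML
#'
#' Numeric values are written with 17 significant digits so the
#' round trip is lossless for doubles.
#'
#' @param config a `ScnetConfig` (or plain named list).
#' @param path YAML file path.
#' @return `writeConfig` invisibly returns `path`; `readConfig` returns
#'   the configuration list.
#' @export
writeConfig <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config), precision = 17L), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$synthetic))
    cfg$synthetic <- structure(cfg$synthetic, class = "ScnetConfig")
  structure(cfg, class = "ScnetConfig")
}

#' @export
print.ScnetConfig <- function(x, ...) {
  cat("ScnetConfig (seed", x$seed, ")\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
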