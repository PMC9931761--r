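## Forward-model simulator: multi-subject, two-class multispectral
## face-patch cohorts with known ground truth. Concentrations are built
## from a planted StO2 field (baseline + class effects + cohort drift,
## scaled per subject), absorbance follows the same Beer-Lambert design
## used by the inversion, and intensities are the white reference
## attenuated by 10^-A plus additive Gaussian sensor noise.

#' Default facial ROI layout on a small patch
#'
#' Seven non-overlapping named regions laid out like a face on an
#' `h x w` grid: forehead, meixin (middle-eyebrow region), nose,
#' philtrum, mouth, left_face, right_face.
#'
#' @param h,w patch size in pixels (>= 16 each).
#' @return An [ROICatalog-class].
#' @export
defaultRoiLayout <- function(h = 16, w = 16) {
  if (h < 16 || w < 16) stop("patch must be at least 16 x 16")
  block <- function(rr, cc) {
    m <- matrix(FALSE, h, w)
    rows <- unique(pmax(1, pmin(h, round(rr / 16 * h))))
    cols <- unique(pmax(1, pmin(w, round(cc / 16 * w))))
    m[rows, cols] <- TRUE
    m
  }
  ROICatalog(list(
    forehead   = block(1:3,  3:14),
    meixin     = block(4:5,  7:10),
    left_face  = block(6:11, 1:4),
    nose       = block(6:9,  7:10),
    right_face = block(6:11, 13:16),
    philtrum   = block(10:11, 7:10),
    mouth      = block(12:14, 5:12)
  ))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the acquisition conditions of the pipeline's target
#' data: 30 Hz four-band (540/556/560/576 nm) skin-patch reflectance on
#' a 16 x 16 patch over 60 s, for 40 subjects with balanced classes.
#' Class signatures: emotional stress (ES) plants a narrow-band 1.5 Hz
#' StO2 oscillation plus a sustained saturation shift in one responsive
#' ROI (mouth); physical stress (PS) plants a broader-band
#' (2.6/3.3/4.1 Hz) spatially diffuse oscillation over
#' forehead/nose/left/right face. Both classes share a cohort-wide slow
#' drift. A per-subject scalar random effect scales effect amplitudes
#' so the multisubject correlation is strong but imperfect; noise is
#' additive Gaussian on intensities (sensor-like).
#'
#' @param ... named overrides of the defaults (nested lists merged).
#' @return list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    n_subjects = 40L,
    duration_s = 60,
    frame_rate_hz = 30,
    wavelengths_nm = c(540, 556, 560, 576),
    patch = c(16L, 16L),
    reference = 10000,
    baseline = list(sto2 = 0.65, c_total_hb = 0.155, c_melanin = 0.02,
                    g_prime = 0.05),
    es = list(responsive_roi = "mouth", osc_amplitude = 0.02,
              osc_freq_hz = 1.5, shift = 0.01),
    ps = list(rois = c("forehead", "nose", "left_face", "right_face"),
              osc_amplitude = 0.012, osc_freqs_hz = c(2.6, 3.3, 4.1)),
    ## multiplicative, spectrally flat illumination/exposure
    ## fluctuation (AR(1)): dominates raw band means but is absorbed
    ## into G' by the Beer-Lambert inversion, leaving StO2 untouched
    illumination = list(sd = 0.01, ar = 0.9),
    ## stress epoch (fractions of the recording): ramp up between onset
    ## and plateau, sustain, release back to baseline
    stress_window = list(onset = 0.2, plateau = 0.35, release = 0.7,
                         end = 0.9),
    drift = list(amplitude = 0.008, period_s = 40),
    noise_sd = 5,
    subject_effect_sd = 0.2,
    es_fraction = 0.5
  )
  mergeConfig(cfg, list(...), "synthetic config")
}

## Raised-cosine stress-epoch envelope on relative time u = t / T.
stressEnvelope <- function(u, w) {
  env <- numeric(length(u))
  up <- u >= w$onset & u < w$plateau
  env[up] <- 0.5 - 0.5 * cos(pi * (u[up] - w$onset) / (w$plateau - w$onset))
  env[u >= w$plateau & u < w$release] <- 1
  dn <- u >= w$release & u < w$end
  env[dn] <- 0.5 + 0.5 * cos(pi * (u[dn] - w$release) / (w$end - w$release))
  env
}

## Planted StO2 field for one subject: T x H x W.
plantedSto2 <- function(cfg, catalog, label, gamma, phases, tt) {
  d <- c(length(tt), cfg$patch[1], cfg$patch[2])
  drift <- cfg$drift$amplitude * gamma *
    sin(2 * pi * tt / cfg$drift$period_s + phases$drift)
  dur <- if (length(tt) > 1) tt[length(tt)] + tt[2] - tt[1] else 1
  env <- stressEnvelope(tt / dur, cfg$stress_window)
  Sm <- matrix(cfg$baseline$sto2 + drift, length(tt), prod(cfg$patch))
  masks <- roiMasks(catalog)
  if (label == 1L) {                       # ES: localized narrow-band
    px <- which(masks[[cfg$es$responsive_roi]])
    sig <- env * (cfg$es$shift * gamma + cfg$es$osc_amplitude * gamma *
      sin(2 * pi * cfg$es$osc_freq_hz * tt + phases$es))
    Sm[, px] <- Sm[, px] + sig
  } else {                                 # PS: diffuse broader-band
    fs <- cfg$ps$osc_freqs_hz
    sig <- env * Reduce(`+`, lapply(seq_along(fs), function(k)
      sin(2 * pi * fs[k] * tt + phases$ps[k]))) *
      (cfg$ps$osc_amplitude * gamma / length(fs))
    px <- which(Reduce(`|`, masks[cfg$ps$rois]))
    Sm[, px] <- Sm[, px] + sig
  }
  array(pmin(pmax(Sm, 0.01), 0.99), d)
}

#' Simulate a two-class multispectral cohort
#'
#' Runs the forward model for every subject: planted StO2 field ->
#' chromophore concentrations (constant total hemoglobin, constant
#' melanin and offset) -> Beer-Lambert absorbance -> intensities
#' `reference * 10^-A` plus Gaussian sensor noise (clamped at 0).
#' Labels alternate ES/PS so classes are balanced. Identical seeds give
#' bit-identical cohorts.
#'
#' @param config a [syntheticConfig()].
#' @param seed master seed.
#' @param basis the [ChromophoreBasis-class] used by the forward model.
#' @param keep_stacks return full [SpectralFrameStack-class] objects
#'   (set FALSE to receive a per-subject generator function instead,
#'   which keeps memory flat for large cohorts).
#' @return list of class `SyntheticCohort`: `stacks` (list, or
#'   `make_stack(i)` closure), `catalog`, `truth` (labels, subject
#'   effects, planted per-ROI mean StO2 trajectories, responsive ROI
#'   name, phases), `config`.
#' @examples
#' cohort <- simulateCohort(syntheticConfig(n_subjects = 2,
#'                                          duration_s = 2), seed = 1)
#' cohort$truth$labels
#' @export
simulateCohort <- function(config = syntheticConfig(), seed = 1L,
                           basis = defaultChromophoreBasis(),
                           keep_stacks = TRUE) {
  cfg <- config
  nyq <- cfg$frame_rate_hz / 2
  if (cfg$es$osc_freq_hz >= nyq || any(cfg$ps$osc_freqs_hz >= nyq))
    stop("effect frequency at or above the Nyquist rate ", nyq, " Hz")
  T_ <- round(cfg$duration_s * cfg$frame_rate_hz)
  tt <- (seq_len(T_) - 1) / cfg$frame_rate_hz
  catalog <- defaultRoiLayout(cfg$patch[1], cfg$patch[2])
  N <- cfg$n_subjects
  n_es <- round(N * cfg$es_fraction)       # 1 = ES, 2 = PS
  labels <- c(rep(1L, n_es), rep(2L, N - n_es))

  phases <- withSeed(childSeed(seed, 0), list(
    drift = runif(1, 0, 2 * pi), es = runif(1, 0, 2 * pi),
    ps = runif(3, 0, 2 * pi)))
  gammas <- withSeed(childSeed(seed, 1),
                     pmax(0.2, 1 + cfg$subject_effect_sd * rnorm(N)))

  design <- designMatrix(basis)
  ## A_b is affine in the planted StO2 field S:
  ## A_b = (e1 - e2) c_tot S + (e2 c_tot + e3 c_mel + g')
  slope <- (design[, 1] - design[, 2]) * cfg$baseline$c_total_hb
  const <- design[, 2] * cfg$baseline$c_total_hb +
    design[, 3] * cfg$baseline$c_melanin + cfg$baseline$g_prime

  makeStack <- function(i) {
    S <- plantedSto2(cfg, catalog, labels[i], gammas[i], phases, tt)
    ill <- cfg$illumination %||% list(sd = 0, ar = 0.9)
    I <- withSeed(childSeed(seed, 100 + i), {
      ## spectrally flat multiplicative illumination: a time-varying
      ## white level shared by all bands and pixels
      gl <- if (ill$sd > 0) {
        g <- as.numeric(stats::filter(rnorm(T_), ill$ar, "recursive"))
        pmax(1 + g * ill$sd * sqrt(1 - ill$ar^2), 0.5)
      } else rep(1, T_)
      .cppForwardBands(as.vector(S), slope, const,
                       cfg$reference * gl, cfg$noise_sd,
                       T_, cfg$patch[1], cfg$patch[2])
    })
    SpectralFrameStack(I, cfg$wavelengths_nm, cfg$frame_rate_hz,
                       sprintf("S%02d", i))
  }

  roiTruth <- function(i) {
    S <- plantedSto2(cfg, catalog, labels[i], gammas[i], phases, tt)
    vapply(roiMasks(catalog), function(m)
      rowMeans(matrix(S, T_, prod(cfg$patch))[, which(m), drop = FALSE]),
      numeric(T_))
  }

  truth <- list(labels = labels, subject_effects = gammas,
                responsive_roi = cfg$es$responsive_roi,
                phases = phases, roi_sto2 = roiTruth,
                class_names = c("ES", "PS"))
  structure(list(
    stacks = if (keep_stacks) lapply(seq_len(N), makeStack) else NULL,
    make_stack = makeStack, catalog = catalog, truth = truth,
    config = cfg), class = "SyntheticCohort")
}

#' Linearly separable descriptor sequences for classifier tests
#'
#' Gaussian descriptor sequences with class-dependent means: class 1
#' elements are centred at `+mean_sep`, class 2 at `-mean_sep`, with SD
#' `sd` per coordinate, so the Bayes accuracy at the defaults is
#' essentially 1.
#'
#' @param n_per_class sequences per class (>= 2).
#' @param seed RNG seed.
#' @param t_w sequence length (windows).
#' @param dim descriptor dimension.
#' @param mean_sep class mean magnitude.
#' @param sd coordinate noise SD.
#' @return list: `x` (2*n_per_class x t_w x dim array), `y` labels (1/2).
#' @export
makeSeparableDescriptorSet <- function(n_per_class, seed = 1L, t_w = 8,
                                       dim = 16, mean_sep = 1, sd = 0.1) {
  if (n_per_class < 2) stop("need at least 2 sequences per class")
  n <- 2L * n_per_class
  y <- rep(1:2, each = n_per_class)
  x <- withSeed(seed, {
    arr <- array(rnorm(n * t_w * dim, sd = sd), c(n, t_w, dim))
    arr + array(rep(ifelse(y == 1, mean_sep, -mean_sep), t_w * dim),
                c(n, t_w, dim))
  })
  list(x = x, y = y)
}
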