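## End-to-end orchestration: simulate -> StO2 -> ROI selection ->
## magnification -> MN-VLAD encoding -> LSTM train/classify, as one
## seeded, reproducible run, plus the feature-ladder ablation.

## Per-subject preprocessing shared by runAll and ablation: StO2 stack
## and 5-channel series per ROI (plus the whole-patch series). Uses a
## fused path: all masked means are one matrix product against a
## pixels x ROIs indicator matrix (equivalent to roiChannelSeries
## per mask, which the tests assert).
preprocessCohort <- function(cohort) {
  cfg <- cohort$config
  catalog <- cohort$catalog
  N <- cfg$n_subjects
  masks <- c(roiMasks(catalog),
             list(.patch = matrix(TRUE, cfg$patch[1], cfg$patch[2])))
  P <- prod(cfg$patch)
  ind <- vapply(masks, function(m) as.numeric(m) / sum(m),
                numeric(P))                     # P x (nROI+1)
  sto2 <- vector("list", N)
  series <- vector("list", N)
  for (i in seq_len(N)) {
    st <- if (!is.null(cohort$stacks)) cohort$stacks[[i]]
          else cohort$make_stack(i)
    s <- extractStO2(st, reference = cfg$reference)
    v <- sto2Values(s)
    sto2[[i]] <- v
    d <- dim(st@data)
    T_ <- d[1]
    ch <- vector("list", 5)
    for (b in 1:4)
      ch[[b]] <- matrix(st@data[, b, , ], T_, P) %*% ind
    sv <- matrix(v, T_, P)
    if (anyNA(sv)) {                      # NaN-robust StO2 means
      ch[[5]] <- vapply(masks, function(m)
        rowMeans(sv[, which(m), drop = FALSE], na.rm = TRUE),
        numeric(T_))
    } else ch[[5]] <- sv %*% ind
    series[[i]] <- lapply(seq_along(masks), function(k)
      data.frame(frame_index = seq_len(T_) - 1L, M1 = ch[[1]][, k],
                 M2 = ch[[2]][, k], M3 = ch[[3]][, k], M4 = ch[[4]][, k],
                 S = ch[[5]][, k]))
    names(series[[i]]) <- names(masks)
  }
  list(sto2 = sto2, series = series)
}

roiPanelsAndFvs <- function(series, rois, window_frames) {
  panels <- lapply(rois, function(roi)
    do.call(rbind, lapply(series, function(s) s[[roi]]$S)))
  names(panels) <- rois
  fvs <- lapply(rois, function(roi)
    lapply(series, function(s) buildFV(s[[roi]], window_frames)))
  names(fvs) <- rois
  list(panels = panels, fvs = fvs)
}

stratifiedSplit <- function(labels, seed) {
  train <- withSeed(seed, unlist(lapply(sort(unique(labels)), function(k) {
    ik <- which(labels == k)
    sort(sample(ik, floor(length(ik) / 2)))
  })))
  list(train = sort(train),
       test = setdiff(seq_along(labels), train))
}

## Per-subject MN-VLAD sequences. Local features are extracted for the
## whole stack in one pass and neighbor-resolved in one batch; window
## accumulation then groups residuals by (window, word) with rowsum.
## Numerically identical to calling encodeMNVlad per window (asserted
## in the tests), since descriptors are per-frame quantities.
encodeSequences <- function(magnified, codebook, msm, window_frames,
                            patch, stride, k_nn) {
  W <- codewords(codebook)
  M <- nrow(W); D <- ncol(W)
  lapply(magnified, function(stk) {
    T_ <- dim(stk)[1]
    nw <- T_ %/% window_frames
    fs <- extractLocalFeatures(stk[seq_len(nw * window_frames), , ,
                                   drop = FALSE],
                               patch = patch, stride = stride)
    feats <- fs$features
    win <- (fs$positions[, "frame"] - 1L) %/% window_frames + 1L
    sel <- if (k_nn == 1L) {
      d2 <- outer(rowSums(feats^2), rowSums(W^2), `+`) -
        2 * feats %*% t(W)
      as.list(max.col(-d2, ties.method = "first"))
    } else resolveNeighborsBatch(feats, codebook, msm, k_nn = k_nn)
    featIdx <- rep(seq_along(sel), lengths(sel))
    wordIdx <- unlist(sel)
    grp <- (win[featIdx] - 1L) * M + wordIdx
    acc <- rowsum(feats[featIdx, , drop = FALSE], grp)
    rows <- as.integer(rownames(acc))
    cnt_all <- tabulate(grp, nbins = nw * M)
    cnt <- cnt_all[rows]
    out <- matrix(0, nw, M * D)
    for (w in seq_len(nw)) {
      V <- matrix(0, M, D)
      here <- rows > (w - 1L) * M & rows <= w * M
      if (any(here)) {
        wr <- rows[here] - (w - 1L) * M
        V[wr, ] <- acc[here, , drop = FALSE] -
          cnt[here] * W[wr, , drop = FALSE]
      }
      nb <- sqrt(rowSums(V^2))
      V[nb > 0, ] <- V[nb > 0, , drop = FALSE] / nb[nb > 0]
      v <- as.vector(t(V))
      nv <- sqrt(sum(v^2))
      out[w, ] <- if (nv > 0) v / nv else v
    }
    out
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage in order on a freshly simulated cohort:
#' StO2 inversion, composite ROI selection, sub-band Eulerian
#' magnification of the StO2 stacks, MN-VLAD encoding of
#' 2-second windows, and LSTM classification with a subject-level
#' 50/50 train/test split. All artifacts (config echo, ROI report,
#' descriptor tables, report) are persisted under `out_dir`.
#'
#' @param config a [scnetConfig()].
#' @param seed master seed; every stage derives its randomness from it.
#' @param out_dir artifact directory (created); defaults to a fresh
#'   temporary directory.
#' @return list of class `RunReport`: `roi_ranking`, `selected_roi`,
#'   `confusion`, `accuracy`, `train_subjects`, `test_subjects`,
#'   `codebook_digest`, `seed`, `params` echo, `out_dir`.
#' @export
runAll <- function(config = scnetConfig(), seed = config$seed,
                   out_dir = tempfile("scnet_run_")) {
  cfg <- config
  cohort <- simulateCohort(cfg$synthetic, seed = childSeed(seed, 11),
                           keep_stacks = FALSE)
  stageLog("simulate", subjects = cfg$synthetic$n_subjects)
  prep <- preprocessCohort(cohort)
  runPipelineCore(cfg, seed, out_dir, cohort, prep)
}

## Stages downstream of simulation/preprocessing; shared by runAll and
## the ablation ladder so one cohort can serve several feature levels.
runPipelineCore <- function(cfg, seed, out_dir, cohort, prep) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syn <- cfg$synthetic
  wf <- round(cfg$window_s * syn$frame_rate_hz)
  rois <- roiNames(cohort$catalog)
  pf <- roiPanelsAndFvs(prep$series, rois, wf)
  roi_scores <- selectRoi(pf$panels, pf$fvs, m = cfg$roi$m, n = cfg$roi$n,
                          sample_rate = syn$frame_rate_hz,
                          f_lo = cfg$bandpass$f_lo,
                          f_hi = cfg$bandpass$f_hi)
  selected <- roi_scores$roi[1]
  stageLog("select_roi", winner = selected)

  bp <- BandpassSpec(cfg$bandpass$f_lo, cfg$bandpass$f_hi,
                     syn$frame_rate_hz)
  magnified <- lapply(prep$sto2, magnifyStack, bandpass = bp,
                      alpha = cfg$magnify$alpha,
                      scales = cfg$magnify$scales,
                      noise_aware = cfg$magnify$noise_aware,
                      noise_k = cfg$magnify$noise_k)
  stageLog("magnify", alpha = cfg$magnify$alpha)

  labels <- cohort$truth$labels
  split <- stratifiedSplit(labels, childSeed(seed, 7))
  train_feats <- do.call(rbind, lapply(split$train, function(i) {
    fs <- extractLocalFeatures(magnified[[i]],
                               patch = cfg$encode$patch,
                               stride = cfg$encode$grid_stride)
    fs$features
  }))
  if (nrow(train_feats) > cfg$encode$max_train_features) {
    keep <- withSeed(childSeed(seed, 13),
                     sample(nrow(train_feats),
                            cfg$encode$max_train_features))
    train_feats <- train_feats[keep, , drop = FALSE]
  }
  codebook <- trainCodebook(train_feats, M = cfg$encode$codebook_m,
                            seed = childSeed(seed, 17))
  msm <- buildMSM(codebook)
  sequences <- encodeSequences(magnified, codebook, msm, wf,
                               cfg$encode$patch, cfg$encode$grid_stride,
                               cfg$encode$k_nn)
  stageLog("encode", m = cfg$encode$codebook_m)

  fit <- trainLstm(sequences[split$train], labels[split$train],
                   hidden = cfg$lstm$hidden, layers = cfg$lstm$layers,
                   epochs = cfg$lstm$epochs, lr = cfg$lstm$lr,
                   patience = cfg$lstm$patience,
                   restarts = cfg$lstm$restarts %||% 1L,
                   ensemble = isTRUE(cfg$lstm$ensemble),
                   seed = childSeed(seed, 19))
  res <- evaluateLstm(fit, sequences[split$test], labels[split$test])
  stageLog("classify", accuracy = res$accuracy)

  report <- structure(list(
    roi_ranking = roi_scores, selected_roi = selected,
    confusion = res$confusion, accuracy = res$accuracy,
    train_subjects = split$train, test_subjects = split$test,
    codebook_digest = contentDigest(codewords(codebook)),
    responsive_roi = cohort$truth$responsive_roi,
    seed = seed, params = unclass(cfg), out_dir = out_dir),
    class = "RunReport")
  persistRun(report, cfg, cohort, sequences, out_dir)
  report
}

persistRun <- function(report, cfg, cohort, sequences, out_dir) {
  writeConfig(cfg, file.path(out_dir, "config.yaml"))
  writeRoiCatalog(cohort$catalog, file.path(out_dir, "rois.json"))
  jsonlite::write_json(list(
    roi_ranking = report$roi_ranking, selected_roi = report$selected_roi,
    accuracy = report$accuracy,
    confusion = as.data.frame(unclass(report$confusion)),
    codebook_digest = report$codebook_digest, seed = report$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  desc_dir <- file.path(out_dir, "descriptors")
  dir.create(desc_dir, showWarnings = FALSE)
  for (i in seq_along(sequences)) {
    df <- data.frame(frame_index = seq_len(nrow(sequences[[i]])) - 1L,
                     sequences[[i]])
    writeRoiCsv(df, file.path(desc_dir, sprintf("subject_%02d.csv", i)))
  }
  invisible(out_dir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("scnet run (seed", x$seed, ")\n")
  cat("  selected ROI:", x$selected_roi,
      sprintf("(planted: %s)\n", x$responsive_roi))
  cat("  held-out accuracy:", sprintf("%.3f", x$accuracy), "\n")
  print(x$confusion)
  invisible(x)
}

#' Feature-ladder ablation
#'
#' Truncates the pipeline to one of four input-feature levels and
#' reports the held-out accuracy under the same subject split and
#' classifier settings:
#' level 1 uses windowed mean/variance of the four raw band means
#' (whole patch); level 2 adds the StO2 channel; level 3 uses the
#' five-channel series of the selected ROI; level 4 is the full
#' magnified MN-VLAD pipeline (identical to [runAll()]).
#'
#' @param config a [scnetConfig()].
#' @param feature_level integer in 1..4, or a vector of levels to be
#'   evaluated on one shared simulated cohort.
#' @param seed master seed (same derivation as [runAll()], so level 4
#'   reproduces it exactly).
#' @return list: `accuracy`, `level`, `confusion`; for a vector of
#'   levels, a named list of such results.
#' @export
ablation <- function(config = scnetConfig(), feature_level,
                     seed = config$seed) {
  if (any(!feature_level %in% 1:4)) stop("feature_level must be in 1..4")
  cfg <- config
  syn <- cfg$synthetic
  wf <- round(cfg$window_s * syn$frame_rate_hz)
  cohort <- simulateCohort(syn, seed = childSeed(seed, 11),
                           keep_stacks = FALSE)
  prep <- preprocessCohort(cohort)
  if (length(feature_level) > 1) {
    out <- lapply(feature_level, function(lv)
      ablationLevel(cfg, lv, seed, cohort, prep, wf))
    names(out) <- paste0("level", feature_level)
    return(out)
  }
  ablationLevel(cfg, feature_level, seed, cohort, prep, wf)
}

ablationLevel <- function(cfg, feature_level, seed, cohort, prep, wf) {
  if (feature_level == 4) {
    rep_ <- runPipelineCore(cfg, seed, tempfile("scnet_abl_"), cohort,
                            prep)
    return(list(accuracy = rep_$accuracy, level = 4L,
                confusion = rep_$confusion))
  }
  syn <- cfg$synthetic
  labels <- cohort$truth$labels
  split <- stratifiedSplit(labels, childSeed(seed, 7))

  sequences <- if (feature_level == 1L) {
    lapply(prep$series, function(s)
      buildFV(s$.patch[, 1:5], wf))            # frame_index + M1..M4
  } else if (feature_level == 2L) {
    lapply(prep$series, function(s) buildFV(s$.patch, wf))
  } else {
    rois <- roiNames(cohort$catalog)
    pf <- roiPanelsAndFvs(prep$series, rois, wf)
    scores <- selectRoi(pf$panels, pf$fvs, m = cfg$roi$m, n = cfg$roi$n,
                        sample_rate = syn$frame_rate_hz,
                        f_lo = cfg$bandpass$f_lo, f_hi = cfg$bandpass$f_hi)
    sel <- scores$roi[1]
    lapply(prep$series, function(s) buildFV(s[[sel]], wf))
  }
  ## standardize descriptors with training-set statistics so the
  ## classifier sees comparable scales (no test leakage)
  trm <- do.call(rbind, sequences[split$train])
  mu <- colMeans(trm)
  sdv <- pmax(apply(trm, 2, sd), 1e-12)
  sequences <- lapply(sequences, function(m)
    sweep(sweep(m, 2, mu), 2, sdv, `/`))
  fit <- trainLstm(sequences[split$train], labels[split$train],
                   hidden = cfg$lstm$hidden, layers = cfg$lstm$layers,
                   epochs = cfg$lstm$epochs, lr = cfg$lstm$lr,
                   patience = cfg$lstm$patience,
                   restarts = cfg$lstm$restarts %||% 1L,
                   ensemble = isTRUE(cfg$lstm$ensemble),
                   seed = childSeed(seed, 19))
  res <- evaluateLstm(fit, sequences[split$test], labels[split$test])
  list(accuracy = res$accuracy, level = as.integer(feature_level),
       confusion = res$confusion)
}
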