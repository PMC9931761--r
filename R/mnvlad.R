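## Multi-neighbor VLAD: k-means codebook, five-layer codeword neighbor
## graph (MSM), GNSS-style integer-ambiguity neighbor resolution, and
## residual aggregation.

#' Train a k-means visual codebook
#'
#' Lloyd k-means with a fixed seed and bounded iterations over the
#' local-feature matrix; inertia is non-increasing across Lloyd
#' iterations by construction.
#'
#' @param features N x D matrix with `N >= M`.
#' @param M number of visual words (>= 2).
#' @param seed RNG seed for the initial centers.
#' @param iter_max iteration cap (default 300).
#' @return A [Codebook-class].
#' @export
trainCodebook <- function(features, M, seed = 1L, iter_max = 300L) {
  features <- as.matrix(features)
  if (nrow(features) < M)
    stop("need at least as many features as words (N >= M)")
  km <- NULL
  for (attempt in 0:9) {                  # Lloyd can hit empty clusters
    km <- withSeed(childSeed(seed, attempt), tryCatch(
      suppressWarnings(kmeans(features, centers = M, iter.max = iter_max,
                              nstart = 4, algorithm = "Lloyd")),
      error = function(e) NULL))
    if (!is.null(km)) break
  }
  if (is.null(km))
    stop("k-means failed to find ", M, " non-empty clusters")
  w <- unname(km$centers)
  ## Lloyd can leave duplicate centers on degenerate data; jitter apart
  ## deterministically so the codebook validity (distinct words) holds.
  if (M >= 2 && min(dist(w)) == 0) {
    eps <- 1e-9 * max(1, max(abs(w)))
    w <- w + outer(seq_len(M), seq_len(ncol(w)), function(i, j)
      eps * i * ((j %% 7) + 1))
  }
  new("Codebook", words = w, seed = as.integer(seed),
      iterations = as.integer(km$iter))
}

#' Build the five-layer codeword neighbor graph
#'
#' Codewords are assigned to five layers by quintiles of their distance
#' to the global codeword mean. Each word receives up to six 1-hop
#' neighbors, chosen nearest-first but balanced across layers (per-layer
#' quota of ceiling(6/5), relaxed only when layers run out), and up to
#' two 2-hop neighbors: the nearest words among neighbors-of-neighbors
#' that are not already 1-hop neighbors. With fewer than 8 words the
#' graph degenerates to all-pairs (with a warning).
#'
#' @param codebook a [Codebook-class].
#' @return An [MSMGraph-class].
#' @export
buildMSM <- function(codebook) {
  W <- codewords(codebook)
  M <- nrow(W)
  if (M < 8) {
    warning("fewer than 8 codewords: falling back to an all-pairs graph")
    one <- lapply(seq_len(M), function(i) setdiff(seq_len(M), i))
    return(new("MSMGraph", layer = rep(1L, M),
               one_hop = lapply(one, function(x) head(x, 6)),
               two_hop = lapply(seq_len(M), function(i) integer(0))))
  }
  ctr <- colMeans(W)
  dc <- sqrt(colSums((t(W) - ctr)^2))
  layer <- as.integer(cut(rank(dc, ties.method = "first"),
                          breaks = 5, labels = FALSE))
  D <- as.matrix(dist(W))
  quota <- ceiling(6 / 5)
  one_hop <- vector("list", M)
  for (i in seq_len(M)) {
    ord <- setdiff(order(D[i, ]), i)
    picked <- integer(0); cnt <- integer(5)
    for (j in ord) {                       # balanced nearest-first pass
      if (length(picked) == 6) break
      if (cnt[layer[j]] < quota) {
        picked <- c(picked, j); cnt[layer[j]] <- cnt[layer[j]] + 1L
      }
    }
    for (j in ord) {                       # relax quota if underfull
      if (length(picked) == 6) break
      if (!j %in% picked) picked <- c(picked, j)
    }
    one_hop[[i]] <- picked
  }
  two_hop <- vector("list", M)
  for (i in seq_len(M)) {
    cand <- setdiff(unique(unlist(one_hop[one_hop[[i]]])),
                    c(i, one_hop[[i]]))
    two_hop[[i]] <- cand[order(D[i, cand])][seq_len(min(2, length(cand)))]
  }
  new("MSMGraph", layer = layer, one_hop = one_hop, two_hop = two_hop)
}

#' Resolve multi-neighbor word assignment by integer ambiguity fixing
#'
#' Builds three distance profiles from the feature to (i) its six 1-hop
#' neighbor words, (ii) its two 2-hop words (recycled to length 6) and
#' (iii) its nearest word (replicated), all scaled by the nearest-word
#' distance. The weights (a, b) of the 1-hop / 2-hop profiles are first
#' estimated by unconstrained least squares of
#' `min || 1 - a CLX_1hop - b CLX_2hop - CLX_dict ||^2` (the float
#' solution, with its 2 x 2 covariance), then fixed to integers by an
#' exhaustive scan of the covariance-weighted quadratic over the box
#' [-3, 3]^2; the conditional update of b given the fixed a (and its
#' variance) is reported alongside. The returned word set always
#' contains the nearest word; 1-hop (2-hop) words are added when the
#' fixed a (b) weight is >= 1.
#'
#' @param r feature vector (length D).
#' @param codebook a [Codebook-class].
#' @param msm the matching [MSMGraph-class].
#' @param box integer search half-width (default 3).
#' @return list of class `AmbiguitySolution`: `words` (ordered candidate
#'   word indices, nearest first), `float` (a_hat, b_hat), `covariance`,
#'   `fixed` (a, b integers), `b_conditional`, `b_conditional_var`,
#'   `objective`.
#' @export
resolveNeighbors <- function(r, codebook, msm, box = 3L) {
  W <- codewords(codebook)
  dists <- sqrt(colSums((t(W) - as.numeric(r))^2))
  nearest <- which.min(dists)
  oneh <- msm@one_hop[[nearest]]
  twoh <- msm@two_hop[[nearest]]
  fallback <- list(words = nearest, float = c(NA, NA), covariance = NULL,
                   fixed = c(0L, 0L), b_conditional = NA_real_,
                   b_conditional_var = NA_real_, objective = NA_real_)
  class(fallback) <- "AmbiguitySolution"
  if (length(oneh) < 2 || length(twoh) < 1) return(fallback)
  ## a feature coinciding with its word has no assignment ambiguity
  if (dists[nearest] <= 1e-9 * (1 + max(dists))) return(fallback)

  scale <- dists[nearest] + 1e-12
  clx1 <- dists[oneh] / scale
  clx2 <- rep_len(dists[twoh], length(clx1)) / scale
  clxd <- rep_len(dists[nearest], length(clx1)) / scale
  X <- cbind(clx1, clx2)
  y <- 1 - clxd
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-12) return(fallback)
  XtXi <- solve(XtX)
  theta <- drop(XtXi %*% crossprod(X, y))
  rss <- sum((y - drop(X %*% theta))^2)
  sigma2 <- max(rss / max(1, length(y) - 2), 1e-12)
  Cov <- sigma2 * XtXi
  Covi <- solve(Cov)

  grid <- as.matrix(expand.grid(a = -box:box, b = -box:box))
  diffs <- sweep(-grid, 2, -theta)          # theta - candidate
  q <- rowSums((diffs %*% Covi) * diffs)
  best <- which.min(q)
  fixed <- grid[best, ]
  ## conditional update of b from the fixed integer a (Eqs. 29-30 form)
  b_cond <- theta[2] - Cov[2, 1] / Cov[1, 1] * (theta[1] - fixed[1])
  b_cond_var <- Cov[2, 2] - Cov[2, 1] / Cov[1, 1] * Cov[1, 2]

  words <- nearest
  if (fixed[1] >= 1) words <- c(words, oneh[order(dists[oneh])])
  if (fixed[2] >= 1) words <- c(words, twoh[order(dists[twoh])])
  structure(list(words = unique(words), float = theta, covariance = Cov,
                 fixed = as.integer(fixed), b_conditional = b_cond,
                 b_conditional_var = b_cond_var, objective = q[best]),
            class = "AmbiguitySolution")
}

## Vectorized neighbor resolution for a whole feature matrix: the same
## least-squares / integer-scan math as resolveNeighbors, evaluated
## with row-wise closed forms (tests assert equality per feature).
## Returns a list of selected-word vectors, nearest first.
resolveNeighborsBatch <- function(features, codebook, msm, box = 3L,
                                  k_nn = 3L) {
  W <- codewords(codebook)
  N <- nrow(features); M <- nrow(W)
  d2 <- outer(rowSums(features^2), rowSums(W^2), `+`) -
    2 * features %*% t(W)
  d2[d2 < 0] <- 0
  dists <- sqrt(d2)
  nearest <- max.col(-d2, ties.method = "first")
  dn <- dists[cbind(seq_len(N), nearest)]
  usable <- vapply(nearest, function(i)
    length(msm@one_hop[[i]]) >= 2 && length(msm@two_hop[[i]]) >= 1,
    logical(1))
  notzero <- dn > 1e-9 * (1 + apply(dists, 1, max))
  full6 <- vapply(nearest, function(i)
    length(msm@one_hop[[i]]) == 6, logical(1))
  ok <- usable & notzero & full6
  out <- as.list(nearest)
  ## irregular neighborhoods go through the scalar path
  for (f in which(usable & notzero & !full6))
    out[[f]] <- head(resolveNeighbors(features[f, ], codebook, msm,
                                      box)$words, k_nn)
  if (!any(ok)) return(out)

  oneM <- do.call(rbind, lapply(msm@one_hop[nearest[ok]], rep_len, 6))
  twoM <- do.call(rbind, lapply(msm@two_hop[nearest[ok]], rep_len, 6))
  idx <- which(ok)
  gather <- function(cols) matrix(dists[cbind(rep(idx, 6),
                                              as.vector(cols))],
                                  length(idx), 6)
  scale <- dn[ok] + 1e-12
  clx1 <- gather(oneM) / scale
  clx2 <- gather(twoM) / scale
  yv <- 1 - dn[ok] / scale
  a11 <- rowSums(clx1^2); a12 <- rowSums(clx1 * clx2)
  a22 <- rowSums(clx2^2)
  det <- a11 * a22 - a12^2
  sing <- abs(det) < 1e-12
  b1 <- yv * rowSums(clx1); b2 <- yv * rowSums(clx2)
  th1 <- (a22 * b1 - a12 * b2) / det
  th2 <- (a11 * b2 - a12 * b1) / det
  th1[sing] <- 0; th2[sing] <- 0
  rss <- rowSums((yv - clx1 * th1 - clx2 * th2)^2)
  sigma2 <- pmax(rss / 4, 1e-12)
  q11 <- a11 / sigma2; q12 <- a12 / sigma2; q22 <- a22 / sigma2
  grid <- as.matrix(expand.grid(a = -box:box, b = -box:box))
  qbest <- rep(Inf, length(idx)); abest <- integer(length(idx))
  bbest <- integer(length(idx))
  for (g in seq_len(nrow(grid))) {
    e1 <- th1 - grid[g, 1]; e2 <- th2 - grid[g, 2]
    q <- q11 * e1^2 + 2 * q12 * e1 * e2 + q22 * e2^2
    better <- q < qbest
    qbest[better] <- q[better]
    abest[better] <- grid[g, 1]; bbest[better] <- grid[g, 2]
  }
  for (j in seq_along(idx)) {
    if (sing[j] || !is.finite(qbest[j])) next
    f <- idx[j]
    words <- nearest[f]
    oneh <- msm@one_hop[[nearest[f]]]
    twoh <- msm@two_hop[[nearest[f]]]
    if (abest[j] >= 1) words <- c(words, oneh[order(dists[f, oneh])])
    if (bbest[j] >= 1) words <- c(words, twoh[order(dists[f, twoh])])
    out[[f]] <- head(unique(words), k_nn)
  }
  out
}

#' Encode a local feature set as a multi-neighbor VLAD descriptor
#'
#' For every feature, residuals `r - q_i` are accumulated into the
#' block of each selected neighbor word (selection via
#' [resolveNeighbors()], capped at `k_nn`, nearest word first). The raw
#' M x D block matrix is then intra-normalized per block and the
#' flattened vector L2-normalized. With `k_nn = 1` this reduces exactly
#' to standard single-neighbor VLAD.
#'
#' @param features N x D matrix (or a `LocalFeatureSet`).
#' @param codebook a [Codebook-class].
#' @param msm an [MSMGraph-class] from [buildMSM()]; built on the fly
#'   when NULL.
#' @param k_nn neighbor cap, >= 1.
#' @return list of class `VLADDescriptor`: `v` (normalized length M*D
#'   vector), `v_raw` (pre-normalization M x D matrix), `empty` flag.
#' @export
encodeMNVlad <- function(features, codebook, msm = NULL, k_nn = 3L) {
  if (inherits(features, "LocalFeatureSet")) features <- features$features
  features <- as.matrix(features)
  if (k_nn < 1) stop("k_nn must be >= 1")
  W <- codewords(codebook)
  M <- nrow(W); D <- ncol(W)
  if (nrow(features) == 0)
    return(structure(list(v = numeric(M * D), v_raw = matrix(0, M, D),
                          empty = TRUE), class = "VLADDescriptor"))
  if (ncol(features) != D) stop("feature dimension does not match codebook")
  if (is.null(msm)) msm <- suppressWarnings(buildMSM(codebook))
  V <- matrix(0, M, D)
  if (k_nn == 1L) {
    ## fast exact path: plain nearest-word VLAD
    d2 <- outer(rowSums(features^2), rowSums(W^2), `+`) -
      2 * features %*% t(W)
    nn <- max.col(-d2, ties.method = "first")
    for (i in unique(nn)) {
      sel <- features[nn == i, , drop = FALSE]
      V[i, ] <- colSums(sel) - nrow(sel) * W[i, ]
    }
  } else {
    sel <- resolveNeighborsBatch(features, codebook, msm, k_nn = k_nn)
    featIdx <- rep(seq_along(sel), lengths(sel))
    wordIdx <- unlist(sel)
    acc <- rowsum(features[featIdx, , drop = FALSE], wordIdx)
    cnt <- tabulate(wordIdx, nbins = M)
    rows <- as.integer(rownames(acc))
    V[rows, ] <- acc - cnt[rows] * W[rows, , drop = FALSE]
  }
  v_raw <- V
  nb <- sqrt(rowSums(V^2))
  V[nb > 0, ] <- V[nb > 0, , drop = FALSE] / nb[nb > 0]
  v <- as.vector(t(V))
  nv <- sqrt(sum(v^2))
  if (nv > 0) v <- v / nv
  structure(list(v = v, v_raw = v_raw, empty = FALSE),
            class = "VLADDescriptor")
}
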