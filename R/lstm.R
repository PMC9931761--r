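## LSTM sequence classifier. The cell follows the standard gate
## equations: input/forget/output gates are sigmoids of affine maps of
## the concatenation [h_{t-1}, x_t]; the memory cell is
## c_t = c_{t-1} * g_f + tanh(W_c [h,x] + b_c) * g_in and the output is
## h_t = tanh(c_t) * g_o. Training is full backpropagation through time
## with Adam; all gradients are exact (verified against central
## differences in the test suite).

sigm <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' Uniform initialization scaled by fan-in; the forget-gate bias starts
#' at 1 (standard practice, keeps early memory open).
#'
#' @param input_dim dimension of each sequence element.
#' @param hidden hidden units per layer.
#' @param layers number of stacked LSTM layers.
#' @param classes number of output classes.
#' @param seed RNG seed.
#' @return list of class `LSTMParams`.
#' @export
lstmInit <- function(input_dim, hidden = 64, layers = 2, classes = 2,
                     seed = 1L) {
  withSeed(seed, {
    mk <- function(r, c) matrix(runif(r * c, -1, 1) / sqrt(c), r, c)
    lay <- vector("list", layers)
    din <- input_dim
    for (l in seq_len(layers)) {
      z <- hidden + din
      lay[[l]] <- list(Wi = mk(hidden, z), Wf = mk(hidden, z),
                       Wo = mk(hidden, z), Wc = mk(hidden, z),
                       bi = numeric(hidden), bf = rep(1, hidden),
                       bo = numeric(hidden), bc = numeric(hidden))
      din <- hidden
    }
    structure(list(layers = lay, Wout = mk(classes, hidden),
                   bout = numeric(classes), input_dim = input_dim,
                   hidden = hidden, n_layers = layers, classes = classes),
              class = "LSTMParams")
  })
}

#' One LSTM cell step
#'
#' Applies the gate equations of layer `l` to a batch of inputs.
#'
#' @param x_t batch input, B x D_in matrix (a vector is treated as one
#'   sample).
#' @param state list with `h` and `c`, each a list of B x H matrices per
#'   layer (zeros when NULL).
#' @param params an `LSTMParams` object.
#' @param l layer index.
#' @return list: updated `state`, the layer output `h` and a `cache`
#'   for backpropagation.
#' @export
lstmCell <- function(x_t, state, params, l = 1) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, nrow = 1)
  H <- params$hidden
  B <- nrow(x_t)
  if (is.null(state)) state <- list(h = list(), c = list())
  getOr <- function(lst, i, default)
    if (length(lst) >= i && !is.null(lst[[i]])) lst[[i]] else default
  h_prev <- getOr(state$h, l, matrix(0, B, H))
  c_prev <- getOr(state$c, l, matrix(0, B, H))
  P <- params$layers[[l]]
  expect <- ncol(P$Wi) - H
  if (ncol(x_t) != expect)
    stop(sprintf("layer %d expects input width %d, got %d",
                 l, expect, ncol(x_t)))
  z <- cbind(h_prev, x_t)
  gi <- sigm(tcrossprod(z, P$Wi) + rep(P$bi, each = B))
  gf <- sigm(tcrossprod(z, P$Wf) + rep(P$bf, each = B))
  go <- sigm(tcrossprod(z, P$Wo) + rep(P$bo, each = B))
  gc <- tanh(tcrossprod(z, P$Wc) + rep(P$bc, each = B))
  c_t <- c_prev * gf + gc * gi
  tc <- tanh(c_t)
  h_t <- tc * go
  state$h[[l]] <- h_t
  state$c[[l]] <- c_t
  list(state = state, h = h_t,
       cache = list(z = z, gi = gi, gf = gf, go = go, gc = gc,
                    c_prev = c_prev, c_t = c_t, tc = tc))
}

softmaxRows <- function(a) {
  e <- exp(a - apply(a, 1, max))
  e / rowSums(e)
}

## Coerce sequences (list of T x D matrices, or B x T x D array) into an
## array; all sequences must share T and D.
asSeqArray <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, c(1, dim(x))))
  stopifnot(is.list(x), length(x) >= 1)
  dms <- unique(vapply(x, function(m) paste(dim(m), collapse = "x"),
                       character(1)))
  if (length(dms) != 1) stop("all sequences must share T x D shape")
  arr <- array(0, c(length(x), dim(x[[1]])))
  for (i in seq_along(x)) arr[i, , ] <- x[[i]]
  arr
}

#' Forward pass: class probabilities for descriptor sequences
#'
#' Runs the stacked LSTM over time and passes the final hidden state of
#' the top layer through a linear head and softmax.
#'
#' @param x sequences: B x T x D array, a single T x D matrix, or a
#'   list of equal-shape matrices.
#' @param params an `LSTMParams`.
#' @param cache keep per-step caches for backpropagation (internal).
#' @return B x classes probability matrix (rows sum to 1); with
#'   `cache = TRUE`, a list with `probs` and the caches.
#' @export
lstmForward <- function(x, params, cache = FALSE) {
  x <- asSeqArray(x)
  B <- dim(x)[1]; T_ <- dim(x)[2]
  if (T_ < 1) stop("empty sequence")
  state <- NULL
  caches <- if (cache) vector("list", T_)
  for (t in seq_len(T_)) {
    inp <- matrix(x[, t, ], B, dim(x)[3])
    step <- vector("list", params$n_layers)
    for (l in seq_len(params$n_layers)) {
      res <- lstmCell(inp, state, params, l)
      state <- res$state
      inp <- res$h
      step[[l]] <- res$cache
    }
    if (cache) caches[[t]] <- step
  }
  hT <- state$h[[params$n_layers]]
  logits <- hT %*% t(params$Wout) + rep(params$bout, each = B)
  probs <- softmaxRows(logits)
  if (cache) list(probs = probs, caches = caches, hT = hT, x = x)
  else probs
}

## Exact BPTT gradients of the mean cross-entropy loss.
lstmGradients <- function(params, x, y_onehot) {
  fw <- lstmForward(x, params, cache = TRUE)
  B <- nrow(fw$probs); T_ <- dim(fw$x)[2]
  L <- params$n_layers; H <- params$hidden
  loss <- -mean(log(rowSums(fw$probs * y_onehot) + 1e-300))
  dlogits <- (fw$probs - y_onehot) / B
  g <- list(Wout = t(dlogits) %*% fw$hT, bout = colSums(dlogits),
            layers = lapply(params$layers, function(P)
              lapply(P, function(m) m * 0)))
  dh_next <- vector("list", L); dc_next <- vector("list", L)
  for (l in seq_len(L)) {
    dh_next[[l]] <- matrix(0, B, H); dc_next[[l]] <- matrix(0, B, H)
  }
  dh_next[[L]] <- dlogits %*% params$Wout
  for (t in rev(seq_len(T_))) {
    dx_from_above <- NULL
    for (l in rev(seq_len(L))) {
      cc <- fw$caches[[t]][[l]]
      P <- params$layers[[l]]
      dh <- dh_next[[l]]
      if (!is.null(dx_from_above)) dh <- dh + dx_from_above
      dc <- dc_next[[l]] + dh * cc$go * (1 - cc$tc^2)
      da_o <- dh * cc$tc * cc$go * (1 - cc$go)
      da_i <- dc * cc$gc * cc$gi * (1 - cc$gi)
      da_c <- dc * cc$gi * (1 - cc$gc^2)
      da_f <- dc * cc$c_prev * cc$gf * (1 - cc$gf)
      G <- g$layers[[l]]
      G$Wi <- G$Wi + t(da_i) %*% cc$z; G$bi <- G$bi + colSums(da_i)
      G$Wf <- G$Wf + t(da_f) %*% cc$z; G$bf <- G$bf + colSums(da_f)
      G$Wo <- G$Wo + t(da_o) %*% cc$z; G$bo <- G$bo + colSums(da_o)
      G$Wc <- G$Wc + t(da_c) %*% cc$z; G$bc <- G$bc + colSums(da_c)
      g$layers[[l]] <- G
      dz <- da_i %*% P$Wi + da_f %*% P$Wf + da_o %*% P$Wo + da_c %*% P$Wc
      dh_next[[l]] <- dz[, seq_len(H), drop = FALSE]
      dc_next[[l]] <- dc * cc$gf
      dx_from_above <- if (l > 1)
        dz[, -seq_len(H), drop = FALSE] else NULL
    }
  }
  list(loss = loss, grads = g)
}

oneHot <- function(y, classes = 2) {
  y <- as.integer(y)
  m <- matrix(0, length(y), classes)
  m[cbind(seq_along(y), y)] <- 1
  m
}

flattenParams <- function(p) {
  out <- list(Wout = p$Wout, bout = p$bout)
  for (l in seq_along(p$layers)) for (nm in names(p$layers[[l]]))
    out[[paste0("L", l, "_", nm)]] <- p$layers[[l]][[nm]]
  out
}

applyUpdate <- function(params, grads, fun) {
  params$Wout <- fun(params$Wout, grads$Wout, "Wout")
  params$bout <- fun(params$bout, grads$bout, "bout")
  for (l in seq_along(params$layers)) for (nm in names(params$layers[[l]]))
    params$layers[[l]][[nm]] <- fun(params$layers[[l]][[nm]],
                                    grads$layers[[l]][[nm]],
                                    paste0("L", l, "_", nm))
  params
}

#' Train the LSTM classifier
#'
#' Full-batch Adam over BPTT gradients of the mean cross-entropy, with
#' an optional stratified validation split and early stopping; the
#' parameters achieving the best validation (or training) loss are
#' returned. All randomness flows from `seed`.
#'
#' @param x training sequences (see [lstmForward()]).
#' @param y integer/factor labels with exactly 2 levels, >= 2 samples
#'   per class.
#' @param hidden,layers architecture (defaults 64 units, 2 layers).
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed for initialization and the split.
#' @param val_frac fraction held out for early stopping (0 disables).
#' @param patience epochs without validation improvement before
#'   stopping.
#' @param l2 decoupled weight-decay coefficient (biases excluded);
#'   regularizes the high-dimensional descriptor weights when training
#'   cohorts are small.
#' @param restarts number of independent initializations; the fit with
#'   the best monitored (validation) loss is kept. Deterministic under
#'   `seed`.
#' @param ensemble keep every restart and average their softmax
#'   outputs at prediction time (variance reduction for small training
#'   cohorts); the reported `params` remain the best single fit.
#' @return list of class `LSTMFit`: `params`, `history` (data.frame of
#'   train/val loss per epoch), `best_epoch`.
#' @export
trainLstm <- function(x, y, hidden = 64, layers = 2, epochs = 100,
                      lr = 1e-3, seed = 1L, val_frac = 0.2, patience = 20,
                      l2 = 0, restarts = 1L, ensemble = FALSE) {
  x <- asSeqArray(x)
  y <- as.integer(factor(y))
  if (length(unique(y)) < 2) stop("need samples from both classes")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  B <- dim(x)[1]
  stopifnot(length(y) == B)

  makeSplit <- function(split_seed) {
    idx_val <- integer(0)
    if (val_frac > 0) {
      idx_val <- withSeed(split_seed, unlist(lapply(1:2, function(k) {
        ik <- which(y == k)
        if (length(ik) >= 4) sample(ik, max(1, round(val_frac * length(ik))))
        else integer(0)
      })))
    }
    idx_tr <- setdiff(seq_len(B), idx_val)
    list(xtr = x[idx_tr, , , drop = FALSE], ytr = oneHot(y[idx_tr]),
         has_val = length(idx_val) > 0,
         xva = if (length(idx_val))
           x[idx_val, , , drop = FALSE],
         yva = if (length(idx_val)) oneHot(y[idx_val]))
  }

  oneFit <- function(init_seed, sp) {
    xtr <- sp$xtr; ytr <- sp$ytr; has_val <- sp$has_val
    xva <- sp$xva; yva <- sp$yva
    params <- lstmInit(dim(x)[3], hidden, layers, 2, seed = init_seed)
    mom <- list(m = list(), v = list())
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0))
    stall <- 0L
    for (ep in seq_len(max(1, epochs))) {
      gr <- lstmGradients(params, xtr, ytr)
      if (lr > 0) {
        step <- ep
        params <- applyUpdate(params, gr$grads, function(w, g, key) {
          m <- mom$m[[key]] %||% (w * 0); v <- mom$v[[key]] %||% (w * 0)
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          mom$m[[key]] <<- m; mom$v[[key]] <<- v
          mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
          decay <- if (l2 > 0 && !grepl("^b|_b", key)) l2 * w else 0
          w - lr * (mh / (sqrt(vh) + epsA) + decay)
        })
      }
      vloss <- if (has_val) {
        p <- lstmForward(xva, params)
        -mean(log(rowSums(p * yva) + 1e-300))
      } else NA_real_
      monitor <- if (has_val) vloss else gr$loss
      hist <- rbind(hist, data.frame(epoch = ep, train = gr$loss,
                                     val = vloss))
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, params = params, epoch = ep)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= patience) break
    }
    list(loss = best$loss, params = best$params, epoch = best$epoch,
         history = hist)
  }

  base_split <- makeSplit(childSeed(seed, 1))
  fits <- lapply(seq_len(max(1L, restarts)), function(r) {
    ## ensemble members train on bagged validation splits for diversity
    sp <- if (ensemble && r > 1) makeSplit(childSeed(seed, 400 + r))
          else base_split
    oneFit(if (r == 1) childSeed(seed, 2) else childSeed(seed, 200 + r),
           sp)
  })
  pick <- which.min(vapply(fits, `[[`, numeric(1), "loss"))
  structure(list(params = fits[[pick]]$params,
                 history = fits[[pick]]$history,
                 best_epoch = fits[[pick]]$epoch,
                 restart = pick,
                 members = if (ensemble) lapply(fits, `[[`, "params")),
            class = "LSTMFit")
}

#' Serialize / deserialize LSTM parameters as JSON
#'
#' Weights are stored with their shapes at full printed precision; the
#' round trip preserves values to better than 1e-14 relative.
#'
#' @param params an `LSTMParams` or `LSTMFit`.
#' @param path JSON file path.
#' @return `writeLstmModel` invisibly returns `path`; `readLstmModel`
#'   returns an `LSTMParams`.
#' @export
writeLstmModel <- function(params, path) {
  if (inherits(params, "LSTMFit")) params <- params$params
  packTensor <- function(x)
    list(dim = if (is.matrix(x)) dim(x) else length(x), v = as.vector(x))
  enc <- list(input_dim = params$input_dim, hidden = params$hidden,
              n_layers = params$n_layers, classes = params$classes,
              Wout = packTensor(params$Wout), bout = packTensor(params$bout),
              layers = lapply(params$layers, lapply, packTensor))
  jsonlite::write_json(enc, path, digits = NA)
  invisible(path)
}

#' @rdname writeLstmModel
#' @export
readLstmModel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  unpack <- function(p) {
    v <- as.numeric(unlist(p$v))
    d <- as.integer(unlist(p$dim))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  layers <- lapply(raw$layers, function(P) lapply(P, unpack))
  structure(list(layers = layers, Wout = unpack(raw$Wout),
                 bout = unpack(raw$bout),
                 input_dim = raw$input_dim[[1]], hidden = raw$hidden[[1]],
                 n_layers = raw$n_layers[[1]], classes = raw$classes[[1]]),
            class = "LSTMParams")
}

#' Evaluate a trained classifier
#'
#' @param params an `LSTMParams` (or `LSTMFit`).
#' @param x labelled sequences.
#' @param y labels (2 classes).
#' @param class_names names for the confusion-matrix dimensions.
#' @return list of class `ClassificationResult`: `probs`, `predicted`,
#'   `confusion` (true in rows), `accuracy`.
#' @export
evaluateLstm <- function(params, x, y,
                         class_names = c("ES", "PS")) {
  members <- NULL
  if (inherits(params, "LSTMFit")) {
    members <- params$members
    params <- params$params
  }
  y <- if (is.numeric(y)) as.integer(y) else as.integer(factor(y))
  if (any(!y %in% 1:2)) stop("labels must be coded 1/2 (ES/PS)")
  probs <- if (!is.null(members)) {
    Reduce(`+`, lapply(members, function(p) lstmForward(x, p))) /
      length(members)
  } else lstmForward(x, params)
  pred <- max.col(probs, ties.method = "first")
  conf <- matrix(0L, 2, 2, dimnames = list(true = class_names,
                                           predicted = class_names))
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  structure(list(probs = probs, predicted = pred, confusion = conf,
                 accuracy = sum(diag(conf)) / length(y)),
            class = "ClassificationResult")
}
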