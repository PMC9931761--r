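zeroParams <- function(input_dim = 4, hidden = 3, layers = 1) {
  p <- lstmInit(input_dim, hidden, layers, seed = 1)
  p$layers <- lapply(p$layers, function(P) lapply(P, function(m) m * 0))
  p$Wout <- p$Wout * 0
  p$bout <- p$bout * 0
  p
}

test_that("the cell follows the gate equations in closed-form cases", {
  ## all-zero parameters: every gate is 0.5, memory and output are 0
  p <- zeroParams()
  res <- lstmCell(matrix(0, 1, 4), NULL, p, 1)
  expect_equal(unique(as.vector(res$cache$gi)), 0.5)
  expect_equal(unique(as.vector(res$cache$gf)), 0.5)
  expect_equal(unique(as.vector(res$cache$go)), 0.5)
  expect_equal(as.vector(res$state$c[[1]]), rep(0, 3))
  expect_equal(as.vector(res$h), rep(0, 3))
  ## saturated negative forget bias erases carried memory
  set.seed(51)
  p2 <- lstmInit(4, 3, 1, seed = 2)
  p2$layers[[1]]$bf <- rep(-50, 3)
  x <- matrix(rnorm(4), 1)
  st0 <- list(h = list(matrix(rnorm(3), 1)), c = list(matrix(5, 1, 3)))
  res2 <- lstmCell(x, st0, p2, 1)
  expect_equal(res2$state$c[[1]],
               res2$cache$gc * res2$cache$gi, tolerance = 1e-10)
  expect_error(lstmCell(matrix(0, 1, 7), NULL, p, 1), "input width")
})

test_that("forward produces normalized, deterministic probabilities", {
  set.seed(52)
  p <- lstmInit(5, 6, 2, seed = 3)
  x <- array(rnorm(4 * 7 * 5), c(4, 7, 5))
  pr <- lstmForward(x, p)
  expect_equal(rowSums(pr), rep(1, 4), tolerance = 1e-9)
  expect_identical(pr, lstmForward(x, p))     # bitwise repeatable
  ## zero head: uniform probabilities
  p0 <- p; p0$Wout <- p0$Wout * 0; p0$bout <- p0$bout * 0
  expect_equal(as.vector(lstmForward(x, p0)),
               rep(0.5, 8), tolerance = 1e-12)
  expect_error(lstmForward(array(0, c(1, 0, 5)), p), "empty")
})

test_that("BPTT gradients match central differences on every tensor", {
  set.seed(53)
  p <- lstmInit(3, 4, 2, seed = 4)
  x <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  y <- scnet:::oneHot(c(1, 2))
  g <- scnet:::lstmGradients(p, x, y)
  eps <- 1e-5
  checkTensor <- function(get, set) {
    w <- get(p); gw <- get(g$grads)
    rel <- vapply(seq_along(w), function(i) {
      wp <- replace(w, i, w[i] + eps); wm <- replace(w, i, w[i] - eps)
      gn <- (scnet:::lstmGradients(set(p, wp), x, y)$loss -
             scnet:::lstmGradients(set(p, wm), x, y)$loss) / (2 * eps)
      abs(gn - gw[i]) / max(1e-6, abs(gn) + abs(gw[i]))
    }, numeric(1))
    max(rel)
  }
  tensors <- list(
    list(function(q) q$Wout, function(q, v) { q$Wout[] <- v; q }),
    list(function(q) q$bout, function(q, v) { q$bout[] <- v; q }))
  for (l in 1:2) for (nm in c("Wi", "Wf", "Wo", "Wc",
                              "bi", "bf", "bo", "bc")) {
    tensors[[length(tensors) + 1]] <- local({
      l_ <- l; nm_ <- nm
      list(function(q) q$layers[[l_]][[nm_]],
           function(q, v) { q$layers[[l_]][[nm_]][] <- v; q })
    })
  }
  for (tns in tensors)
    expect_lt(checkTensor(tns[[1]], tns[[2]]), 1e-5)
})

test_that("training learns separable sequences and is seed-stable", {
  ds <- makeSeparableDescriptorSet(6, seed = 5, t_w = 5, dim = 8)
  fit <- trainLstm(ds$x, ds$y, hidden = 8, layers = 1, epochs = 200,
                   lr = 1e-2, seed = 0, val_frac = 0)
  acc <- evaluateLstm(fit, ds$x, ds$y)$accuracy
  expect_gte(acc, 0.95)
  ## zero learning rate leaves the parameters at their initialization
  fit0 <- trainLstm(ds$x, ds$y, hidden = 8, layers = 1, epochs = 3,
                    lr = 0, seed = 7, val_frac = 0)
  init <- lstmInit(8, 8, 1, seed = scnet:::childSeed(7, 2))
  expect_equal(fit0$params$Wout, init$Wout, tolerance = 1e-12)
  expect_equal(fit0$params$layers[[1]]$Wi, init$layers[[1]]$Wi,
               tolerance = 1e-12)
  ## identical seeds give identical loss trajectories
  f1 <- trainLstm(ds$x, ds$y, hidden = 8, layers = 1, epochs = 10,
                  lr = 1e-3, seed = 11)
  f2 <- trainLstm(ds$x, ds$y, hidden = 8, layers = 1, epochs = 10,
                  lr = 1e-3, seed = 11)
  expect_identical(f1$history$train, f2$history$train)
  expect_error(trainLstm(ds$x, rep(1, 12), epochs = 1), "both classes")
})

test_that("evaluation counts the confusion matrix correctly", {
  set.seed(54)
  ds <- makeSeparableDescriptorSet(5, seed = 6, t_w = 4, dim = 6)
  fit <- trainLstm(ds$x, ds$y, hidden = 6, layers = 1, epochs = 150,
                   lr = 1e-2, seed = 1, val_frac = 0)
  res <- evaluateLstm(fit, ds$x, ds$y)
  ## entries recomputed by brute-force counting
  for (a in 1:2) for (b in 1:2)
    expect_equal(res$confusion[a, b],
                 sum(ds$y == a & res$predicted == b))
  expect_equal(sum(res$confusion), length(ds$y))
  expect_equal(res$accuracy,
               mean(res$predicted == ds$y))
  ## a perfect fit has a diagonal confusion matrix
  if (res$accuracy == 1) expect_equal(sum(diag(res$confusion)), 10L)
})

test_that("model parameters round-trip through JSON exactly", {
  tmp <- withr::local_tempdir()
  p <- lstmInit(5, 4, 2, seed = 8)
  path <- file.path(tmp, "model.json")
  writeLstmModel(p, path)
  back <- readLstmModel(path)
  expect_equal(back$Wout, p$Wout, tolerance = 1e-14)
  expect_equal(back$layers[[2]]$Wc, p$layers[[2]]$Wc, tolerance = 1e-14)
  expect_equal(back$layers[[1]]$bf, p$layers[[1]]$bf, tolerance = 1e-14)
  ## forward passes agree on random input
  set.seed(55)
  x <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  expect_equal(lstmForward(x, back), lstmForward(x, p),
               tolerance = 1e-12)
})

test_that("label-shuffled data yields chance-level held-out accuracy", {
  accs <- vapply(1:6, function(s) {
    ds <- makeSeparableDescriptorSet(16, seed = 70 + s, t_w = 4, dim = 6)
    y_shuf <- scnet:::withSeed(s, sample(ds$y))
    tr <- c(1:8, 17:24); te <- c(9:16, 25:32)
    fit <- trainLstm(ds$x[tr, , , drop = FALSE], y_shuf[tr], hidden = 6,
                     layers = 1, epochs = 60, lr = 3e-3, seed = s,
                     val_frac = 0)
    evaluateLstm(fit, ds$x[te, , , drop = FALSE], y_shuf[te])$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})
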