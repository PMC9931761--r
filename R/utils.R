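## Internal helpers shared across stages.

## Derive a child seed from a base seed; kept below 2^31 so it is always a
## valid R integer.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k) * 101) %% 2147483647L)
}

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  ## normal.kind fixed explicitly (faster than inversion, still fully
  ## deterministic under the seed)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Kinderman-Ramage")
  force(expr)
}

## Cheap content digest used in stage logs and reports (not cryptographic).
contentDigest <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) return("empty")
  sprintf("%d:%.8e:%.8e", length(v), sum(v), sum(v * seq_along(v) %% 97))
}

## One structured line per pipeline stage; silenced unless option set.
stageLog <- function(stage, ..., verbose = getOption("scnet.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    kv <- list(...)
    msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, function(x)
      paste(format(x), collapse = ","), character(1))), collapse = " ")
    message(sprintf("[scnet:%s] %s", stage, msg))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assertPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}
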