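#' @importFrom stats pf pnorm qnorm phyper pnbinom rnorm rbinom rexp runif
#'   rnbinom rpois sd var median complete.cases p.adjust wilcox.test t.test
#'   cor setNames
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_flag01 <- function(x, what) {
  if (any(!x %in% c(0, 1)))
    stopf("%s must be 0 or 1", what)
  invisible(x)
}
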