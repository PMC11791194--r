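#' @import methods
#' @importFrom stats cor median pnorm pt qnorm rnorm runif sd var phyper
#'   setNames ave complete.cases coef
#' @importFrom utils head read.csv read.delim write.table modifyList
#'   packageVersion
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Case-fold and trim a label column (species, tissue) at ingest.
canonLabel <- function(x) tolower(trimws(as.character(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
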