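#' @useDynLib fundusOD, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All stochastic package code funnels through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive per-item child seeds from a base seed, kept well below 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max %/% 4L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
logMsg <- function(level, ..., verbose = getOption("fundusOD.verbose", FALSE)) {
  if (isTRUE(verbose) || level %in% c("WARNING", "ERROR")) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, paste0(...)))
  }
  invisible(NULL)
}

# round() with the usual away-from-zero convention for .5, matching how
# pixel counts are quoted in protocols (round(n * fraction)).
roundHalfUp <- function(x) floor(x + 0.5)
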