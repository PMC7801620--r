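#' @keywords internal
"_PACKAGE"

#' @useDynLib actisleep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad sd rnorm runif rgeom rpois predict
#' @importFrom utils head tail
NULL

# Run `expr` under a private RNG stream, restoring the caller's stream.
# All stochastic operations in the package funnel through this so a single
# master seed makes whole pipelines reproducible without clobbering the
# user's session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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

#' Derive a stage-specific seed from a master seed
#'
#' A single master seed fans out to per-subject, per-fold and per-epoch
#' seeds through a fixed counter scheme, so that every stage of a pipeline
#' run is independently reproducible. The scheme is a multiplicative hash
#' kept inside the 32-bit signed integer range.
#'
#' @param master Integer master seed.
#' @param stream Integer stream counter (subject index, fold index,
#'   training-epoch index, ...).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), is.numeric(stream), length(master) == 1,
            length(stream) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  as.integer(((abs(master) %% m) * 48271 + (abs(stream) %% m) * 16807 + 12345) %% m)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used for architecture fingerprints and fold-assignment audits.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  bytes <- utf8ToInt(x)
  # Work in double precision to avoid 32-bit overflow; reduce mod 2^32 after
  # each multiply. 16777619 is the FNV prime.
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# XOR of two non-negative doubles below 2^32, computed 16 bits at a time.
bitwXor64 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Stop with a classed condition so callers/tests can match on error class.
abort_actisleep <- function(msg, class) {
  abort(msg, class = c(class, "actisleep_error"))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
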