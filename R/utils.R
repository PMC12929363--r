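#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad runif rnorm optim setNames
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom grDevices chull
NULL

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer so nested seeded stages never collide or overflow.
derive_seed <- function(master, k) {
  master <- as.numeric(master) %% 2147483647
  as.integer((master * 48271 + as.numeric(k) * 16807 + 1) %% 2147483647)
}

# Evaluate expr under a local RNG state seeded with `seed` (restores the
# caller's RNG afterwards).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

vnorm <- function(x) sqrt(sum(x^2))

unit <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# FNV-1a hash of a character scalar, hex string; used for run manifests.
# Arithmetic kept in doubles (< 2^53) to avoid 32-bit integer overflow.
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
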