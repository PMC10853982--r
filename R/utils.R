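# Internal utilities: seeded substreams, validation conditions, small hashes.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validation error condition
#'
#' All input-validation failures in the package signal a condition of class
#' `fixelstats_validation_error` so callers (and the CLI) can distinguish
#' bad inputs (exit status 2) from programming errors.
#' @noRd
validation_error <- function(msg, ...) {
  structure(
    class = c("fixelstats_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
}

stop_invalid <- function(msg, ...) stop(validation_error(msg, ...))

#' Derive a reproducible sub-seed for a named stage
#'
#' A single global seed plus named substreams lets each simulation stage
#' (template, subjects, noise, dropout, ...) be regenerated independently.
#' The derivation is a small integer hash kept below 2^31.
#' @noRd
substream_seed <- function(seed, stage) {
  h <- 17
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`,
#' so library users' RNG streams are never disturbed.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' FNV-1a 32-bit hash of a character string (non-cryptographic)
#'
#' Used for config hashes and file digests in run manifests; chosen for
#' having a tiny, dependency-free implementation. Returns 8 hex digits.
#' @noRd
fnv1a_hash <- function(x) {
  if (is.raw(x)) bytes <- as.integer(x)
  else bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

fnv1a_file <- function(path) {
  fnv1a_hash(readBin(path, what = "raw", n = file.info(path)$size))
}

#' All permutations of 1..n (n small), as a list
#' @noRd
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Orthonormal basis completion: given unit vector v, return u, w with
# {v,u,w} right-handed orthonormal.
perp_basis <- function(v) {
  a <- if (abs(v[1]) <= abs(v[2]) && abs(v[1]) <= abs(v[3])) c(1, 0, 0)
       else if (abs(v[2]) <= abs(v[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- a - sum(a * v) * v
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  list(u = u, w = w)
}

# Linear voxel id (0-based) from 0-based (i,j,k) triples and grid dims.
voxel_linear_id <- function(ijk, dims) {
  ijk <- matrix(as.integer(as.matrix(ijk)), ncol = 3)
  ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
}
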