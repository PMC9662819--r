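## Internal helpers shared across modules.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != as.integer(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a probability in [0, 1]", name)
  }
  as.numeric(x)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards. All stochastic operations in the package go
## through this so no call perturbs global reproducibility.
with_seed <- function(seed, expr) {
  seed <- assert_count(seed, "seed", min = 0L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a stream-specific child seed so independent generators never share
## a stream; kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

euclidean_cross <- function(a, b) {
  ## a: n x 3, b: m x 3 -> n x m distance matrix
  a <- as.matrix(a); b <- as.matrix(b)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sq[sq < 0] <- 0
  sqrt(sq)
}
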