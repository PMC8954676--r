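#' @useDynLib voxscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All stochastic operations in the package route
# through this so every result is a pure function of its explicit seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("rng seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, so independent
# stages (pose, augment, init, noise, ...) get decorrelated, reproducible
# streams. 32-bit FNV-1a over the label, folded with the parent seed,
# reduced below 2^31.
derive_seed <- function(seed, label, index = 0L) {
  h <- fnv1a32(paste0(label, ":", index))
  as.integer((as.double(seed) * 2654435761 + h) %% 2147483647)
}

# 32-bit FNV-1a hash of a character string (scalar). Exact in double
# arithmetic: the multiply is split into 16-bit halves so every intermediate
# stays below 2^53.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) h <- mul_fnv(bitwXor32(h, b))
  h
}

# Exact (h * 16777619) mod 2^32 in doubles, used by hash_vec.
mul_fnv <- function(h) {
  # 16777619 = 0x01000193; split h into high/low 16-bit halves
  lo <- h %% 65536
  hi <- (h - lo) / 65536
  (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
}

bitwXor32 <- function(a, b) {
  # xor for doubles in [0, 2^32): do it on 16-bit halves via bitwXor
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(as.integer(ahi), as.integer(bhi)) * 65536 +
    bitwXor(as.integer(alo), as.integer(blo))
}

# Deterministic 32-bit hash of an integer vector (FNV-1a over 16-bit limbs).
# Used by the fingerprint module to fold substructure identifiers to bits.
hash_ints <- function(v) {
  h <- 2166136261
  for (x in v) {
    x <- as.double(x) %% 4294967296
    lo <- x %% 65536
    hi <- (x - lo) / 65536
    h <- mul_fnv(bitwXor32(h, lo))
    h <- mul_fnv(bitwXor32(h, hi))
  }
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vs_stop <- function(...) stop(sprintf(...), call. = FALSE)
vs_warn <- function(...) warning(sprintf(...), call. = FALSE)

# Fixed-format numeric for byte-stable CSV/JSON output across runs.
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "f", digits = digits)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
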