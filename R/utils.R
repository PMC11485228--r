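`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic sub-seed per concern, kept within 32-bit integer range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483587)
}

## evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

check_prob <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  invisible(p)
}

check_count <- function(n, what) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0 || n != round(n))
    stop(sprintf("'%s' must be a positive integer count", what), call. = FALSE)
  invisible(as.integer(n))
}

## FNV-1a 32-bit hash of a character string, hex-encoded; used for
## provenance stamps on pipeline outputs (stable across platforms)
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte only (b < 256); h itself stays a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply by the FNV prime, split to stay exact
    ## within double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(paste(deparse(config), collapse = "\n"))
}
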