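# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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

# Derive a stream seed from a master seed and an index. Multipliers are small
# enough that products stay exact in double precision; result is kept in
# [1, 2^31 - 2] so it is a valid set.seed() argument.
derive_seed <- function(seed, index, stratum = 0L) {
  m <- 2147483647
  s <- (as.double(seed) * 48271 + as.double(index) * 8191 +
          as.double(stratum) * 131071) %% m
  as.integer(s) + 1L
}

# FNV-1a style hash of a character scalar, returned as 8 hex digits.
# Used to stamp output tables with a configuration fingerprint without
# pulling in a hashing dependency.
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30   # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Canonical single-string rendering of a (possibly nested) named list.
deparse_config <- function(x) {
  flat <- unlist(x, use.names = TRUE)
  paste(names(flat), vapply(flat, format, "", digits = 15), sep = "=",
        collapse = ";")
}
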