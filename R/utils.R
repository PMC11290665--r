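# RNG plumbing shared by the bootstrap test, the simulator and sampling.

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` around `expr`, so seeded internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed; `NULL` leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Stable 31-bit hash of strings
#'
#' A small polynomial rolling hash (base 31, modulo 2^31 - 1) used to derive
#' independent per-population and per-genet RNG substreams from a master
#' seed, so results never depend on execution order. Not cryptographic.
#'
#' @param ... character/numeric components of the key.
#' @return non-negative integer < 2^31 - 1.
#' @export
stableHash <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  as.integer(h)
}

#' @rdname stableHash
#' @param masterSeed integer master seed.
#' @return `substreamSeed()` returns a derived integer seed < 2^31.
#' @export
substreamSeed <- function(masterSeed, ...) {
  as.integer((as.numeric(masterSeed) %% 2147483647 * 48271 +
                stableHash(...)) %% 2147483647)
}
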