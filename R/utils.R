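#' Run code with an isolated, explicitly seeded RNG stream
#'
#' All generators in the package take explicit integer seeds and must not
#' disturb (or depend on) the caller's global random state. This helper
#' saves `.Random.seed`, seeds the Mersenne-Twister stream, evaluates the
#' expression and restores the previous state on exit.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' FNV-1a hash of an R object's JSON serialization
#'
#' Lightweight provenance fingerprint for configs and reports; not
#' cryptographic.
#'
#' @param x an R object serializable by [jsonlite::toJSON()].
#' @return 16-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  # FNV-1a style mixing kept inside exact double integers (< 2^48)
  mod <- 2^48
  h <- 0x811c9dc5
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% mod
  }
  paste(sprintf("%x", floor(h / 16^(11:0)) %% 16), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
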