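`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# numerically stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

addBias <- function(M, b) M + rep(b, each = nrow(M))

#' Derive a child seed from a root seed
#'
#' All randomness in a run flows from one root seed, fanned out
#' deterministically to sub-tasks (world generation, pair sampling, splits,
#' parameter init, batch shuffling) so that any stage can be reproduced in
#' isolation. Plain 32-bit-safe modular arithmetic; results always lie in
#' [1, 2^31 - 2].
#'
#' @param root integer root seed.
#' @param k integer stream index (any small integer; distinct streams give
#'   distinct seeds).
#' @return integer seed.
#' @export
deriveSeed <- function(root, k) {
  stopifnot(is.numeric(root), is.numeric(k))
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.numeric(root) %% m) + 1
  for (i in seq_len(2)) {
    x <- (x * 48271 + as.numeric(k) * 16807 + 11) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Canonical fingerprint of a configuration list
#'
#' Deterministic string encoding of the name/value pairs of a flat
#' configuration list (vectors allowed), used to verify at transfer time that
#' an encoder checkpoint and a model configuration agree.
#'
#' @param config named list of atomic values.
#' @return single character string.
#' @export
configFingerprint <- function(config) {
  config <- config[order(names(config))]
  enc <- vapply(config, function(v) {
    if (is.function(v)) v <- "<function>"
    paste(format(v, digits = 15), collapse = ",")
  }, "")
  paste(names(config), enc, sep = "=", collapse = ";")
}

# compare two configs field by field, returning names of divergent fields
configDiff <- function(a, b) {
  keys <- union(names(a), names(b))
  bad <- vapply(keys, function(k) {
    !identical(format(a[[k]], digits = 15), format(b[[k]], digits = 15))
  }, TRUE)
  keys[bad]
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
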