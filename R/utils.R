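# Internal helpers: classed conditions and seed handling.
#
# Error categories mirror the CLI exit codes:
#   schema (bad input structure/values)   -> exit 2
#   stat   (statistical precondition)     -> exit 3
#   io     (missing/unreadable files)     -> exit 4

stopSchema <- function(...) {
  stop(errorCondition(paste0(...), class = c("theoceptor_schema_error", "theoceptor_error")))
}

stopStat <- function(...) {
  stop(errorCondition(paste0(...), class = c("theoceptor_stat_error", "theoceptor_error")))
}

stopIo <- function(...) {
  stop(errorCondition(paste0(...), class = c("theoceptor_io_error", "theoceptor_error")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stopSchema("seed must be a single finite number, got: ", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

checkFinite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stopSchema(what, " must be finite, got: ", paste(format(x), collapse = ", "))
  }
  invisible(x)
}

checkScalar <- function(x, what) {
  if (length(x) != 1L) stopSchema(what, " must be a single value, got length ", length(x))
  checkFinite(x, what)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
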