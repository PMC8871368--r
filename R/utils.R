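# Internal helpers shared across modules.

#' Derive a deterministic substream seed
#'
#' One root seed drives a whole pipeline run; per-unit, per-stack and per-map
#' random streams are derived from it so that cohorts are reproducible and
#' individual items can be regenerated in isolation.
#'
#' @param seed Integer root seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed strictly below 2^31.
#' @export
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  # splitmix-style integer hash, kept in double arithmetic below 2^31
  x <- (abs(seed) %% 2147483647) + 1
  for (i in seq_len(2)) {
    x <- (x * 48271 + index * 30269 + 11) %% 2147483647
  }
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

# shoelace polygon area in µm^2 (delegates to pracma)
polygon_area <- function(x, y) {
  abort_if(length(x) < 3 || length(x) != length(y),
           "polygon must have at least 3 vertices with matching x/y")
  abs(pracma::polyarea(x, y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
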