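#' @keywords internal
"_PACKAGE"

## Error helpers: every user-facing validation failure goes through one of
## these so messages carry a consistent prefix that tests can match on.

stop_validation <- function(fmt, ...) {
  stop(sprintf(paste0("validation error: ", fmt), ...), call. = FALSE)
}

stop_format <- function(fmt, ...) {
  stop(sprintf(paste0("format error: ", fmt), ...), call. = FALSE)
}

stop_config <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}

stop_statistics <- function(fmt, ...) {
  stop(sprintf(paste0("statistics error: ", fmt), ...), call. = FALSE)
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream.  All stochastic operations in the package take an explicit seed
## and route through here, which makes them bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number, got %s",
                    deparse(substitute(seed)))
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stream index, kept inside the
## 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
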