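# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible child seed from a master seed and a stream label.
# Kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

stopf <- function(fmt, ..., class = "agencymix_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s], got %s",
          name, format(lower), format(upper), paste(format(x), collapse = ","))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be an integer, got %s", name, format(x))
  invisible(as.integer(x))
}

# T x K x 3 array -> (K, 3, T) cube layout used by the compiled routines.
as_cube <- function(coords) aperm(coords, c(2L, 3L, 1L))
from_cube <- function(cube) aperm(cube, c(3L, 1L, 2L))

# Per-frame, per-landmark Euclidean step lengths of a T x K x 3 array:
# returns a (T-1) x K matrix of frame-to-frame displacements.
step_lengths <- function(coords) {
  dm <- dim(coords)
  d <- coords[-1, , , drop = FALSE] - coords[-dm[1], , , drop = FALSE]
  s <- d[, , 1, drop = FALSE]^2 + d[, , 2, drop = FALSE]^2 +
    d[, , 3, drop = FALSE]^2
  matrix(sqrt(s), nrow = dm[1] - 1L, ncol = dm[2])
}
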