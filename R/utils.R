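#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbeta rnbinom rlnorm runif rnorm p.adjust pt pnorm
#'   quantile median t.test dhyper lowess approx setNames lm.wfit var
#' @importFrom utils read.delim write.table head
NULL

# Internal parameter checks ---------------------------------------------------

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop_param("'%s' must be a single fraction in %s0,1%s (got %s)",
               name, if (open_left) "(" else "[",
               if (open_right) ")" else "]", format(x))
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_param("'%s' must be a single positive number (got %s)", name, format(x))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_param("'%s' must be an integer >= %d (got %s)", name, min, format(x))
  invisible(as.integer(x))
}

# Deterministic sub-seed derivation: all randomness flows from one master seed;
# sub-streams are tagged by name so stages never share or reuse a stream.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- as.numeric(seed) %% 2147483647
  for (k in codes) h <- (h * 69069 + k) %% 2147483647
  as.integer(h %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
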