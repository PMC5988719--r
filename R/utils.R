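# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so every generator is a pure function of its parameters
#' (including the seed) and never perturbs global random state.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a top-level seed and a stage index.
# Linear-congruential mixing keeps children distinct and inside 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 77777 * stage) %% 2147483647)
}

# Validation helpers: fail with messages that name the offending parameter.
check_number <- function(x, name, min = -Inf, max = Inf, allow_null = FALSE,
                         strict_min = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("'%s' must be > %g (got %g)", name, min, x), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("'%s' must be >= %g (got %g)", name, min, x), call. = FALSE)
  }
  if (x > max) {
    stop(sprintf("'%s' must be <= %g (got %g)", name, max, x), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != round(x)) {
    stop(sprintf("'%s' must be an integer (got %g)", name, x), call. = FALSE)
  }
  invisible(as.integer(x))
}
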