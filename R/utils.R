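# Internal helpers: classed conditions, seeded RNG scoping, modular arithmetic.

vk_stop <- function(code, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("vasckinetics_error_", code),
                                "vasckinetics_error")))
}

vk_warn <- function(code, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("vasckinetics_warning_", code),
                                     "vasckinetics_warning")))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Positive modulo: result in [0, m).
mod_pos <- function(x, m) x - floor(x / m) * m

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    vk_stop("bad_param", "`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    vk_stop("bad_param", "`%s` = %g outside the allowed range %s%g, %g%s",
            name, x, if (strict_lower) "(" else "[", lower, upper,
            if (strict_upper) ")" else "]")
  as.numeric(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) vk_stop("bad_param", "a `seed` is required for reproducibility")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed))
    vk_stop("bad_param", "`seed` must be a single integer")
  as.integer(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
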