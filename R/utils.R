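#' @keywords internal
#' @noRd
tapkin_error <- function(message, class, call = NULL) {
  stop(structure(
    class = c(class, "tapkin_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Validate a scalar numeric field, error names the offending field
#' @noRd
check_scalar <- function(value, field, lower = -Inf, upper = Inf,
                         allowed = NULL, strict_lower = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    tapkin_error(sprintf("parameter '%s' must be a finite numeric scalar", field),
                 "tapkin_parameter_error")
  }
  if (!is.null(allowed) && !value %in% allowed) {
    tapkin_error(sprintf("parameter '%s' must be one of {%s}, got %s",
                         field, paste(allowed, collapse = ", "), value),
                 "tapkin_parameter_error")
  }
  ok_lower <- if (strict_lower) value > lower else value >= lower
  if (!ok_lower || value > upper) {
    tapkin_error(sprintf("parameter '%s' = %s outside allowed range %s%s, %s]",
                         field, value, if (strict_lower) "(" else "[",
                         lower, upper),
                 "tapkin_parameter_error")
  }
  invisible(value)
}

#' Run code with a temporary RNG state seeded from `seed`
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

#' Derive a child seed from a master seed and a stream index.
#' Kept below 2^31 so it is always a valid R seed.
#' @noRd
child_seed <- function(master, index) {
  (as.double(master) * 48271 + as.double(index) * 16807) %% 2147483629
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Linear-interpolation percentile (type 7), the convention used throughout
#' @noRd
pctl <- function(x, p) as.numeric(quantile(x, p, type = 7, names = FALSE))
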