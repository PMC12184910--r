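#' Explicit "undefined" sentinel for buffering ratios
#'
#' The compartment ratios `T` (transfer/buffer) and `B` (buffer/transfer) are
#' genuinely undefined -- not merely unknown -- in the limits of perfect
#' transfer (`b = 0`, so `T` divides by zero) and perfect buffering
#' (`t_bar = 0`, so `B` divides by zero). These are meaningful states of a
#' buffered system, so they are represented by a dedicated sentinel rather
#' than `NaN` or `NA`: any attempt to use the sentinel in arithmetic raises a
#' typed error instead of silently propagating.
#'
#' @return `undefined_value()` returns the sentinel; `is_undefined()` tests
#'   for it.
#' @examples
#' s <- state_from_t_bar(1)
#' is_undefined(s$T)
#' @export
undefined_value <- function() {
  structure(list(), class = "epibuffer_undefined")
}

#' @rdname undefined_value
#' @param x object to test.
#' @export
is_undefined <- function(x) {
  inherits(x, "epibuffer_undefined")
}

#' @export
print.epibuffer_undefined <- function(x, ...) {
  cat("<undefined>\n")
  invisible(x)
}

#' @export
format.epibuffer_undefined <- function(x, ...) "undefined"

#' @export
Ops.epibuffer_undefined <- function(e1, e2) {
  stop_epibuffer(
    "arithmetic on an undefined buffering parameter (division by zero state)",
    class = "epibuffer_undefined_error"
  )
}

# internal: consistent condition classes across the package
stop_epibuffer <- function(message, class) {
  stop(structure(
    class = c(class, "epibuffer_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_epibuffer(
      sprintf("`%s` must be a single finite number", name),
      class = "epibuffer_validation_error"
    )
  }
  invisible(x)
}
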