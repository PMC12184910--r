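#' Buffering-parameter algebra
#'
#' A buffered system -- a measurable quantity partitioning between a patent
#' "transfer" compartment and a hidden "buffer" compartment -- is described in
#' its entirety by any one of five interconvertible parameters:
#'
#' * `t_bar`, the transfer fraction: change in the transfer compartment
#'   relative to the total change (may be negative or exceed 1);
#' * `b = 1 - t_bar`, the buffer fraction;
#' * `T = t_bar / b`, the transfer-to-buffer ratio (undefined when `b = 0`);
#' * `B = b / t_bar`, the buffer-to-transfer ratio (undefined when
#'   `t_bar = 0`); `T` and `B` are ratio-scale measures, so `T * B = 1`
#'   whenever both are defined;
#' * `alpha_deg`, the buffering angle: the angle between the `t_bar` axis and
#'   the ray from the origin to the point `(t_bar, b)`, in degrees on
#'   `(-45, 135]`. The angle expresses every regime -- amplification
#'   (-45..0), moderation (0..90), inversion (90..135) -- with a single
#'   finite value and no division-by-zero discontinuity.
#'
#' `state_from_t_bar()`, `state_from_B()`, `state_from_partition()`, and
#' `state_from_angle()` each build the full five-parameter state from one
#' starting point. `angle_from_state()` is the bare angle computation.
#'
#' @param t_bar transfer fraction (dimensionless).
#' @param B buffer-to-transfer ratio; `B = -1` is a divergence (the implied
#'   transfer fraction `1 / (1 + B)` has a pole there).
#' @param transfer_amount,buffer_amount quantities in the two compartments,
#'   in the units of the measured trait; their sum must be nonzero.
#' @param alpha_deg buffering angle in degrees, in `(-45, 135]`. Exactly 135
#'   degrees is the `cos + sin = 0` singularity where the transfer fraction
#'   diverges, and is rejected.
#' @param b buffer fraction; must satisfy `t_bar + b = 1`.
#'
#' @return A `buffering_state`: a list with elements `t_bar`, `b`, `T`, `B`
#'   (numeric, or the [undefined_value()] sentinel), and `alpha_deg`.
#'   `angle_from_state()` returns a numeric vector of degrees.
#'
#' @examples
#' state_from_t_bar(0.8)           # t=0.8, b=0.2, T=4, B=0.25
#' state_from_B(2)                 # three identical interconnected vessels
#' state_from_partition(80, 20)
#' state_from_angle(45)            # equal transfer and buffering
#' angle_from_state(-1, 2)         # inversion boundary, 116.57 degrees
#' @name buffering_state
NULL

new_buffering_state <- function(t_bar, alpha_deg = NULL) {
  b <- 1 - t_bar
  structure(
    list(
      t_bar = t_bar,
      b = b,
      T = if (b == 0) undefined_value() else t_bar / b,
      B = if (t_bar == 0) undefined_value() else b / t_bar,
      alpha_deg = if (is.null(alpha_deg)) angle_from_state(t_bar, b) else alpha_deg
    ),
    class = "buffering_state"
  )
}

#' @rdname buffering_state
#' @export
state_from_t_bar <- function(t_bar) {
  check_finite_scalar(t_bar, "t_bar")
  new_buffering_state(t_bar)
}

#' @rdname buffering_state
#' @export
state_from_B <- function(B) {
  check_finite_scalar(B, "B")
  if (B == -1) {
    stop_epibuffer(
      "B = -1 is a singularity: the transfer fraction 1 / (1 + B) diverges",
      class = "epibuffer_divergence_error"
    )
  }
  new_buffering_state(1 / (1 + B))
}

#' @rdname buffering_state
#' @export
state_from_partition <- function(transfer_amount, buffer_amount) {
  check_finite_scalar(transfer_amount, "transfer_amount")
  check_finite_scalar(buffer_amount, "buffer_amount")
  total <- transfer_amount + buffer_amount
  if (total == 0) {
    stop_epibuffer(
      "degenerate partition: transfer_amount + buffer_amount must be nonzero",
      class = "epibuffer_degenerate_error"
    )
  }
  new_buffering_state(transfer_amount / total)
}

#' @rdname buffering_state
#' @export
angle_from_state <- function(t_bar, b) {
  stopifnot(is.numeric(t_bar), is.numeric(b), length(t_bar) == length(b))
  bad <- abs(t_bar + b - 1) > 1e-9
  if (any(bad)) {
    stop_epibuffer(
      "invariant violation: t_bar + b must equal 1",
      class = "epibuffer_invariant_error"
    )
  }
  core <- acos(t_bar / sqrt(t_bar^2 + b^2)) * 180 / pi
  ifelse(t_bar > 1, -core, core)
}

#' @rdname buffering_state
#' @export
state_from_angle <- function(alpha_deg) {
  check_finite_scalar(alpha_deg, "alpha_deg")
  if (alpha_deg <= -45 || alpha_deg > 135) {
    stop_epibuffer(
      "alpha_deg must lie in (-45, 135]",
      class = "epibuffer_validation_error"
    )
  }
  a <- alpha_deg * pi / 180
  denom <- cos(a) + sin(a)
  if (abs(denom) < 1e-12) {
    stop_epibuffer(
      "alpha at the cos(alpha) + sin(alpha) = 0 singularity (135 degrees): the transfer fraction diverges",
      class = "epibuffer_divergence_error"
    )
  }
  t_bar <- cos(a) / denom
  # snap the exact axis angles so 0 and 90 degrees yield exact 1 / 0
  if (abs(alpha_deg) < 1e-12) t_bar <- 1
  if (abs(alpha_deg - 90) < 1e-12) t_bar <- 0
  new_buffering_state(t_bar, alpha_deg = alpha_deg)
}

#' Buffering angle from the buffer-to-transfer ratio
#'
#' Inverse-tangent conversion from `B` to the buffering angle. For `B > -1`
#' the principal branch applies; for `B < -1` (the inversion regimes, where
#' the transfer fraction is negative) 180 degrees is added so the result
#' stays on `(-45, 135]` and agrees with [angle_from_state()]. `B = -1` is a
#' divergence (angle 135 is only a limit point).
#'
#' @param B buffer-to-transfer ratio.
#' @return angle in degrees.
#' @examples
#' angle_from_B(1)    # 45
#' angle_from_B(-2)   # 116.57, the inversion boundary
#' @export
angle_from_B <- function(B) {
  check_finite_scalar(B, "B")
  if (B == -1) {
    stop_epibuffer(
      "B = -1 maps to the 135-degree limit point; the state itself diverges",
      class = "epibuffer_divergence_error"
    )
  }
  a <- atan(B) * 180 / pi
  if (B < -1) a <- a + 180
  a
}

#' @export
print.buffering_state <- function(x, digits = 4, ...) {
  fmt <- function(v) {
    if (is_undefined(v)) "undefined" else format(signif(v, digits))
  }
  cat("<buffering_state>\n")
  cat("  t_bar:", fmt(x$t_bar), "  b:", fmt(x$b), "\n")
  cat("  T:    ", fmt(x$T), "  B:", fmt(x$B), "\n")
  cat("  alpha:", fmt(x$alpha_deg), "degrees\n")
  invisible(x)
}

#' @export
format.buffering_state <- function(x, ...) {
  fmt <- function(v) if (is_undefined(v)) "undef" else format(signif(v, 4))
  sprintf(
    "buffering_state(t=%s, b=%s, T=%s, B=%s, alpha=%s)",
    fmt(x$t_bar), fmt(x$b), fmt(x$T), fmt(x$B), fmt(x$alpha_deg)
  )
}

#' @export
as.list.buffering_state <- function(x, ...) {
  list(
    t_bar = x$t_bar,
    b = x$b,
    T = if (is_undefined(x$T)) NULL else x$T,
    B = if (is_undefined(x$B)) NULL else x$B,
    alpha_deg = x$alpha_deg
  )
}

is_buffering_state <- function(x) inherits(x, "buffering_state")
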