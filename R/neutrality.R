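#' Neutrality models for combined allele action
#'
#' Two mutually exclusive rules predict the combined effect of independently
#' acting alleles:
#'
#' * serial action -- the output of one allele's effect is the input to the
#'   other's: the combined transfer fraction is the product of the
#'   individual `t_bar` values;
#' * parallel action -- the alleles act simultaneously and independently:
#'   the combined buffer-to-transfer ratio is the sum of the individual `B`
#'   values, and `t_bar = 1 / (1 + B)`.
#'
#' Both rules fold over any number of states and are order-independent. For
#' fitness values `f` on `(0, 1]` the parallel expectation always weakly
#' dominates the serial one, with equality only when some `f = 1`.
#'
#' @param states a list of two or more [buffering_state] objects.
#' @return An `expected_state`: list with `model`, `state` (a
#'   [buffering_state]), `time_varying` flag, and optional `trajectory`.
#' @examples
#' s <- lapply(c(0.7, 0.5), state_from_t_bar)
#' expected_serial(s)$state$t_bar     # 0.35
#' expected_parallel(s)$state$t_bar   # 0.412
#' @name neutrality
NULL

new_expected_state <- function(model, state, time_varying = FALSE, trajectory = NULL) {
  structure(
    list(model = model, state = state,
         time_varying = time_varying, trajectory = trajectory),
    class = "expected_state"
  )
}

#' @export
print.expected_state <- function(x, ...) {
  cat(sprintf("<expected_state> model = %s%s\n", x$model,
              if (x$time_varying) " (time-varying)" else ""))
  print(x$state)
  invisible(x)
}

check_state_list <- function(states) {
  if (!is.list(states) || length(states) < 2L ||
      !all(vapply(states, is_buffering_state, logical(1)))) {
    stop_epibuffer(
      "`states` must be a list of at least two buffering_state objects",
      class = "epibuffer_validation_error"
    )
  }
  invisible(states)
}

#' @rdname neutrality
#' @export
expected_serial <- function(states) {
  check_state_list(states)
  t_bars <- vapply(states, function(s) s$t_bar, numeric(1))
  new_expected_state("serial", state_from_t_bar(prod(t_bars)))
}

#' @rdname neutrality
#' @export
expected_parallel <- function(states) {
  check_state_list(states)
  if (any(vapply(states, function(s) is_undefined(s$B), logical(1)))) {
    stop_epibuffer(
      "parallel combination needs every B defined (t_bar = 0 states have undefined B)",
      class = "epibuffer_undefined_error"
    )
  }
  B_sum <- sum(vapply(states, function(s) s$B, numeric(1)))
  if (B_sum == -1) {
    stop_epibuffer("combined B = -1: the expected transfer fraction diverges",
                   class = "epibuffer_divergence_error")
  }
  new_expected_state("parallel", state_from_B(B_sum))
}

#' Expected exponential growth rate under serial action
#'
#' For exponential growth the serial rule (product of `t_bar` trajectories,
#' `exp((r_i - r_ref) t)`) collapses to a constant rate
#' `r_expected = sum(r_mut) - (k - 1) * r_ref`, i.e. `r1 + r2 - r_ref` for a
#' double mutant. This differs from the naive product of rates.
#'
#' @param r_ref reference (wild-type) rate, per hour.
#' @param r_mut numeric vector of two or more single-mutant rates.
#' @return expected double-(multi-)mutant rate, per hour.
#' @examples
#' expected_exponential_serial_rate(1, c(0.7, 0.5))  # 0.2
#' @export
expected_exponential_serial_rate <- function(r_ref, r_mut) {
  check_finite_scalar(r_ref, "r_ref")
  if (!is.numeric(r_mut) || length(r_mut) < 2L || any(!is.finite(r_mut))) {
    stop_epibuffer("`r_mut` must be a numeric vector of >= 2 finite rates",
                   class = "epibuffer_validation_error")
  }
  sum(r_mut) - (length(r_mut) - 1) * r_ref
}

#' Expected exponential trajectory under parallel action
#'
#' Under parallel action with exponential growth the combined rate is not a
#' constant; the expectation is the full trajectory
#' `N(t) = x0 * exp(r_ref t) / (sum_i exp((r_ref - r_i) t) - (k - 1))`,
#' obtained by summing the time-varying `B(t)` of each single mutant and
#' converting back through `t_bar = 1 / (1 + B)`.
#'
#' @inheritParams expected_exponential_serial_rate
#' @param x0 initial quantity.
#' @return An `expected_state` whose `trajectory` element is a function of
#'   time; `state` is `NULL` because the buffering parameters vary with the
#'   evaluation time (use [buffering_state_at()] against the reference for a
#'   chosen time).
#' @examples
#' e <- expected_exponential_parallel_trajectory(1, c(0.7, 0.5))
#' e$trajectory(1)
#' @export
expected_exponential_parallel_trajectory <- function(r_ref, r_mut, x0 = 1) {
  check_finite_scalar(r_ref, "r_ref")
  check_finite_scalar(x0, "x0")
  if (!is.numeric(r_mut) || length(r_mut) < 2L || any(!is.finite(r_mut))) {
    stop_epibuffer("`r_mut` must be a numeric vector of >= 2 finite rates",
                   class = "epibuffer_validation_error")
  }
  k <- length(r_mut)
  trajectory <- function(t) {
    denom <- vapply(t, function(tt) sum(exp((r_ref - r_mut) * tt)) - (k - 1),
                    numeric(1))
    if (any(denom <= 0)) {
      stop_epibuffer(
        "combined B(t) = -1 crossed: expected trajectory diverges at this time",
        class = "epibuffer_domain_error"
      )
    }
    x0 * exp(r_ref * t) / denom
  }
  new_expected_state("parallel", state = NULL, time_varying = TRUE,
                     trajectory = trajectory)
}

#' Expected double-mutant fitness
#'
#' Fitness here is the transfer fraction relative to wild type (for SGA
#' colony area, which scales linearly with both time and fitness, the
#' product and serial rules coincide). Serial: `f1 * f2`. Parallel: convert
#' to `B`, sum, convert back -- `1 / (1/f1 + 1/f2 - 1)`.
#'
#' @param f1,f2 single-mutant fitness values (vectorized). The parallel
#'   model requires positive fitness.
#' @param model `"serial"` or `"parallel"`.
#' @return expected double-mutant fitness.
#' @examples
#' expected_double_fitness(0.7, 0.5, "serial")    # 0.35
#' expected_double_fitness(0.7, 0.5, "parallel")  # 0.4118
#' @export
expected_double_fitness <- function(f1, f2, model = c("serial", "parallel")) {
  model <- match.arg(model)
  stopifnot(is.numeric(f1), is.numeric(f2))
  if (model == "serial") {
    f1 * f2
  } else {
    if (any(f1 <= 0 | f2 <= 0, na.rm = TRUE)) {
      stop_epibuffer(
        "parallel expectation undefined for nonpositive fitness (B undefined at f = 0)",
        class = "epibuffer_undefined_error"
      )
    }
    1 / (1 / f1 + 1 / f2 - 1)
  }
}
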