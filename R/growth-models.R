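#' Phenotype growth models
#'
#' Three trajectory families describe how a measured quantity (cell number,
#' colony volume, any trait) accumulates over time:
#'
#' * linear: `x(t) = x0 * r * t`
#' * quadratic: `x(t) = x0 * r * t^2`
#' * exponential: `x(t) = x0 * exp(r * t)`
#'
#' `r` is the rate (per hour) and doubles as the fitness of the genotype:
#' for exponential growth `r = 1` gives a doubling time of `ln 2` hours.
#' Negative `r` (mortality exceeding proliferation) is allowed; downstream
#' buffering parameters then take `t_bar < 0`.
#'
#' @param kind one of `"linear"`, `"quadratic"`, `"exponential"`.
#' @param r growth rate, per hour.
#' @param x0 initial quantity in trait units; must be positive.
#' @return A `growth_model` object.
#' @examples
#' wt <- growth_model("exponential", r = 1)
#' growth_value(wt, log(2))  # one doubling
#' @export
growth_model <- function(kind = c("exponential", "linear", "quadratic"),
                         r, x0 = 1) {
  kind <- match.arg(kind)
  check_finite_scalar(r, "r")
  check_finite_scalar(x0, "x0")
  if (x0 <= 0) {
    stop_epibuffer("`x0` must be positive", class = "epibuffer_validation_error")
  }
  structure(
    list(
      kind = kind,
      r = r,
      x0 = x0,
      degree_n = switch(kind, linear = 1L, quadratic = 2L, exponential = NA_integer_)
    ),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s, r = %g /hr, x0 = %g\n", x$kind, x$r, x$x0))
  invisible(x)
}

#' Evaluate a growth trajectory
#'
#' @param model a [growth_model()].
#' @param t time in hours; must be nonnegative (vectorized).
#' @return trajectory value(s) in trait units.
#' @export
growth_value <- function(model, t) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_epibuffer("`t` must be finite and nonnegative",
                   class = "epibuffer_validation_error")
  }
  switch(model$kind,
    linear      = model$x0 * model$r * t,
    quadratic   = model$x0 * model$r * t^2,
    exponential = model$x0 * exp(model$r * t)
  )
}

#' Transfer, buffer, and sigma functions of a mutant against a reference
#'
#' The sigma function is the reference trajectory (the phenotypic output
#' that is possible), the transfer function is the mutant trajectory (the
#' output actually observed), and the buffer function is their difference
#' (the output diverted into the inferred buffer compartment). Conservation
#' `sigma(t) = tau(t) + beta(t)` holds pointwise by construction.
#'
#' @param reference,mutant [growth_model()] objects of the same kind and
#'   initial quantity.
#' @return A `schmitt_triple`: list of functions `sigma`, `tau`, `beta`,
#'   each mapping time (hours) to trait units.
#' @examples
#' tr <- schmitt_triple(growth_model("exponential", 1),
#'                      growth_model("exponential", 0.7))
#' tr$beta(2)  # e^2 - e^1.4
#' @export
schmitt_triple <- function(reference, mutant) {
  stopifnot(inherits(reference, "growth_model"), inherits(mutant, "growth_model"))
  if (reference$kind != mutant$kind || reference$x0 != mutant$x0) {
    stop_epibuffer(
      "reference and mutant must share the same growth kind and initial quantity",
      class = "epibuffer_validation_error"
    )
  }
  structure(
    list(
      sigma = function(t) growth_value(reference, t),
      tau   = function(t) growth_value(mutant, t),
      beta  = function(t) growth_value(reference, t) - growth_value(mutant, t),
      reference = reference,
      mutant = mutant
    ),
    class = "schmitt_triple"
  )
}

#' Buffering state of a mutant at a time point
#'
#' The transfer fraction is `tau(t) / sigma(t)`. For linear and quadratic
#' growth this is constant in time and equals `r_mut / r_ref`; for
#' exponential growth it is `exp((r_mut - r_ref) * t)` and so varies with
#' the observation time.
#'
#' @inheritParams schmitt_triple
#' @param t observation time, hours; `sigma(t)` must be nonzero.
#' @return A [buffering_state].
#' @examples
#' buffering_state_at(growth_model("quadratic", 1),
#'                    growth_model("quadratic", 0.5), t = 7)$t_bar  # 0.5
#' @export
buffering_state_at <- function(reference, mutant, t) {
  tr <- schmitt_triple(reference, mutant)
  check_finite_scalar(t, "t")
  s <- tr$sigma(t)
  if (s == 0) {
    stop_epibuffer("sigma(t) = 0: buffering state undefined at this time",
                   class = "epibuffer_degenerate_error")
  }
  state_from_t_bar(tr$tau(t) / s)
}

#' Cumulative (integrated) phenotype over an observation window
#'
#' The definite integral of the trajectory over `[t_start, t_end]`, in units
#' of trait units times hours (e.g. cell-hours for microbial growth --
#' analogous to kilowatt-hours). Closed forms are used for all three
#' families; the exponential family with `r = 0` degenerates to
#' `x0 * (t_end - t_start)`.
#'
#' @param model a [growth_model()].
#' @param t_start,t_end observation window in hours, `t_start <= t_end`.
#' @return scalar, trait units times hours.
#' @examples
#' cumulative_phenotype(growth_model("exponential", 1), 0, 10)  # (e^10 - 1)
#' @export
cumulative_phenotype <- function(model, t_start, t_end) {
  stopifnot(inherits(model, "growth_model"))
  check_finite_scalar(t_start, "t_start")
  check_finite_scalar(t_end, "t_end")
  if (t_start > t_end) {
    stop_epibuffer("`t_start` must not exceed `t_end`",
                   class = "epibuffer_validation_error")
  }
  with(model, switch(kind,
    linear      = x0 * r * (t_end^2 - t_start^2) / 2,
    quadratic   = x0 * r * (t_end^3 - t_start^3) / 3,
    exponential = if (r == 0) x0 * (t_end - t_start)
                  else x0 * (exp(r * t_end) - exp(r * t_start)) / r
  ))
}

#' Time dilation or compression experienced by a mutant
#'
#' A mutant with transfer fraction `t_bar < 1` can be viewed as reaching the
#' same phenotypic output as the wild type, only later:
#' `t_mutant = (t_wt^n / t_bar)^(1/n)` where `n` is the degree of time in
#' the trajectory (1 linear, 2 quadratic). For `n = 1` this is
#' `t_wt / t_bar` -- a strain at half fitness takes twice as long.
#'
#' @param t_bar transfer fraction; must be positive (an inverted phenotype
#'   has no real dilation).
#' @param degree_n degree of time in the trajectory, integer >= 1.
#' @param t_wt reference time, hours.
#' @return mutant time, hours.
#' @export
time_dilation <- function(t_bar, degree_n = 1, t_wt) {
  check_finite_scalar(t_bar, "t_bar")
  check_finite_scalar(t_wt, "t_wt")
  if (t_bar <= 0) {
    stop_epibuffer("`t_bar` must be positive: no real time dilation for inverted phenotypes",
                   class = "epibuffer_domain_error")
  }
  if (!is.numeric(degree_n) || length(degree_n) != 1L || degree_n < 1) {
    stop_epibuffer("`degree_n` must be an integer >= 1",
                   class = "epibuffer_validation_error")
  }
  (t_wt^degree_n / t_bar)^(1 / degree_n)
}

#' Serialize / deserialize a growth model as JSON
#'
#' @param model a [growth_model()].
#' @param json a JSON string as produced by `growth_model_to_json()`.
#' @return a JSON string, or a [growth_model()].
#' @export
growth_model_to_json <- function(model) {
  stopifnot(inherits(model, "growth_model"))
  jsonlite::toJSON(list(kind = model$kind, r = model$r, x0 = model$x0),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname growth_model_to_json
#' @export
growth_model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  growth_model(kind = x$kind, r = x$r, x0 = if (is.null(x$x0)) 1 else x$x0)
}
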