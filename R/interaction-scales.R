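#' Epsilon interaction scales
#'
#' Interaction strength is the relative error between the observed and
#' expected double-mutant parameter under the stated neutrality model:
#'
#' * parallel: `epsilon = (B_cd - (B_c + B_d)) / (B_c + B_d)`
#' * serial:   `epsilon = -(t_cd - t_c * t_d) / (t_c * t_d)`
#'
#' The serial scale is negated so that aggravating interactions are positive
#' on both scales: +1 means the phenotype is twice as severe as expected
#' (serial: observed `t_bar` of zero), -1 means a wild-type-equivalent
#' double mutant (parallel), 0 means exact neutrality.
#'
#' `epsilon_landmarks()` gives the two reference points on the parallel
#' scale where the double mutant matches the weaker or the stronger single
#' mutant; observed epsilon between the landmarks means `B_cd` lies between
#' the single-mutant `B` values.
#'
#' @param B_c,B_d,B_cd single- and double-mutant buffer-to-transfer ratios.
#'   `B_cd` may be the [undefined_value()] sentinel or `Inf` for a lethal
#'   (zero-transfer) double mutant, in which case `epsilon_parallel()`
#'   returns `Inf`.
#' @param t_c,t_d,t_cd single- and double-mutant transfer fractions.
#' @return a single epsilon value; `epsilon_landmarks()` returns a named
#'   list with `epsilon_weak` and `epsilon_strong`.
#' @examples
#' epsilon_parallel(0.429, 1, 2.858)  # twice as severe as expected: 1
#' epsilon_serial(0.7, 0.5, 0.7)      # observed t twice the expected: -1
#' epsilon_landmarks(0.429, 1)
#' @name epsilon_scales
NULL

#' @rdname epsilon_scales
#' @export
epsilon_parallel <- function(B_c, B_d, B_cd) {
  check_finite_scalar(B_c, "B_c")
  check_finite_scalar(B_d, "B_d")
  if (B_c + B_d == 0) {
    stop_epibuffer("B_c + B_d = 0: parallel epsilon diverges",
                   class = "epibuffer_divergence_error")
  }
  if (is_undefined(B_cd) || (is.numeric(B_cd) && is.infinite(B_cd))) {
    return(Inf)  # synthetic lethality: B_cd unbounded
  }
  check_finite_scalar(B_cd, "B_cd")
  (B_cd - (B_c + B_d)) / (B_c + B_d)
}

#' @rdname epsilon_scales
#' @export
epsilon_serial <- function(t_c, t_d, t_cd) {
  check_finite_scalar(t_c, "t_c")
  check_finite_scalar(t_d, "t_d")
  check_finite_scalar(t_cd, "t_cd")
  expected <- t_c * t_d
  if (expected == 0) {
    stop_epibuffer("t_c * t_d = 0: serial epsilon diverges",
                   class = "epibuffer_divergence_error")
  }
  -(t_cd - expected) / expected
}

#' @rdname epsilon_scales
#' @export
epsilon_landmarks <- function(B_c, B_d) {
  check_finite_scalar(B_c, "B_c")
  check_finite_scalar(B_d, "B_d")
  denom <- abs(B_c + B_d)
  if (denom == 0) {
    stop_epibuffer("|B_c + B_d| = 0: landmarks diverge",
                   class = "epibuffer_divergence_error")
  }
  list(
    epsilon_weak   = (min(abs(B_c), abs(B_d)) - denom) / denom,
    epsilon_strong = (max(abs(B_c), abs(B_d)) - denom) / denom
  )
}

#' Classify a genetic interaction
#'
#' An interaction is called epistatic when the observed deviation from the
#' neutrality expectation is significant (`q_value <= q_threshold`);
#' otherwise the relationship is neutral -- additive under the parallel
#' model, multiplicative under the serial model. Epistatic interactions are
#' aggravating for positive epsilon and ameliorating for negative epsilon.
#' Aggravating interactions subdivide into synthetic lethal (double-mutant
#' fitness not observably above zero, i.e. `t_cd <= lethality_floor`) and
#' synthetic sick. An ameliorating interaction whose double mutant exceeds
#' the fitter single mutant is flagged as suppression when the single-mutant
#' transfer fractions are supplied.
#'
#' @param epsilon interaction score from [epsilon_parallel()] or
#'   [epsilon_serial()].
#' @param q_value multiplicity-adjusted significance of the deviation.
#' @param t_cd observed double-mutant transfer fraction.
#' @param model neutrality model the epsilon was computed under.
#' @param t_c,t_d optional single-mutant transfer fractions (used only to
#'   call suppression).
#' @param q_threshold significance cutoff (default 0.05).
#' @param lethality_floor transfer fraction at or below which growth is
#'   considered not observably greater than zero (default 0.01 of wild-type
#'   fitness).
#' @return An `interaction_assessment`: list with `model`, `epsilon`,
#'   `epsilon_weak`/`epsilon_strong` (when the landmarks are supplied via
#'   `B_c`, `B_d`), `label`, `sub_label`, `q_value`.
#' @param B_c,B_d optional single-mutant B values; when given, landmark
#'   epsilons are attached to the assessment.
#' @examples
#' classify_interaction(0.8, q_value = 0.001, t_cd = 0.2, model = "serial")
#' @export
classify_interaction <- function(epsilon, q_value, t_cd,
                                 model = c("serial", "parallel"),
                                 t_c = NULL, t_d = NULL,
                                 B_c = NULL, B_d = NULL,
                                 q_threshold = 0.05, lethality_floor = 0.01) {
  model <- match.arg(model)
  if (!is.numeric(q_value) || length(q_value) != 1L ||
      q_value < 0 || q_value > 1) {
    stop_epibuffer("`q_value` must be a probability in [0, 1]",
                   class = "epibuffer_validation_error")
  }
  check_finite_scalar(t_cd, "t_cd")

  if (q_value > q_threshold) {
    label <- if (model == "parallel") "neutral_additive" else "neutral_multiplicative"
    sub_label <- "none"
  } else if (epsilon > 0) {
    label <- "epistatic_aggravating"
    sub_label <- if (t_cd <= lethality_floor) "synthetic_lethal" else "synthetic_sick"
  } else if (epsilon < 0) {
    label <- "epistatic_ameliorating"
    sub_label <- "none"
    if (!is.null(t_c) && !is.null(t_d) && t_cd > max(t_c, t_d)) {
      sub_label <- "suppression"
    }
  } else {
    label <- if (model == "parallel") "neutral_additive" else "neutral_multiplicative"
    sub_label <- "none"
  }

  landmarks <- if (!is.null(B_c) && !is.null(B_d)) epsilon_landmarks(B_c, B_d)
               else list(epsilon_weak = NA_real_, epsilon_strong = NA_real_)

  structure(
    list(model = model, epsilon = epsilon,
         epsilon_weak = landmarks$epsilon_weak,
         epsilon_strong = landmarks$epsilon_strong,
         label = label, sub_label = sub_label, q_value = q_value),
    class = "interaction_assessment"
  )
}

#' @export
print.interaction_assessment <- function(x, ...) {
  cat(sprintf("<interaction_assessment> %s model\n", x$model))
  cat(sprintf("  epsilon = %.4g (weak %.4g, strong %.4g)\n",
              x$epsilon, x$epsilon_weak, x$epsilon_strong))
  cat(sprintf("  label = %s; sub_label = %s; q = %.4g\n",
              x$label, x$sub_label, x$q_value))
  invisible(x)
}

#' Quantify Hartwellian genetic buffering via the buffering angle
#'
#' The angular deviation expected from the single mutants under a neutrality
#' model, against the deviation actually observed, measures how much
#' phenotypic variation the genetic relationship can cryptically buffer.
#' For synthetically lethal parallel-acting singles at 23.2 and 45 degrees,
#' 55 degrees of deviation is expected but 90 degrees is observed: 35
#' degrees of variation is cryptically buffered.
#'
#' @param state_c,state_d single-mutant [buffering_state] objects.
#' @param state_cd_observed observed double-mutant [buffering_state].
#' @param model `"serial"` or `"parallel"`.
#' @return A `buffering_quantification` list with the four angles and
#'   `cryptic_range_deg = max(0, observed - expected)`.
#' @examples
#' q <- quantify_buffering(state_from_t_bar(0.7), state_from_t_bar(0.5),
#'                         state_from_t_bar(0), model = "parallel")
#' q$cryptic_range_deg  # 35 degrees
#' @export
quantify_buffering <- function(state_c, state_d, state_cd_observed,
                               model = c("serial", "parallel")) {
  model <- match.arg(model)
  stopifnot(is_buffering_state(state_c), is_buffering_state(state_d),
            is_buffering_state(state_cd_observed))
  expected <- switch(model,
    serial   = expected_serial(list(state_c, state_d)),
    parallel = expected_parallel(list(state_c, state_d))
  )
  alpha_exp <- expected$state$alpha_deg
  alpha_obs <- state_cd_observed$alpha_deg
  structure(
    list(
      alpha_single_c = state_c$alpha_deg,
      alpha_single_d = state_d$alpha_deg,
      alpha_expected = alpha_exp,
      alpha_observed = alpha_obs,
      cryptic_range_deg = max(0, alpha_obs - alpha_exp),
      model = model
    ),
    class = "buffering_quantification"
  )
}

#' @export
print.buffering_quantification <- function(x, ...) {
  cat(sprintf("<buffering_quantification> %s model\n", x$model))
  cat(sprintf("  singles: %.1f and %.1f degrees\n",
              x$alpha_single_c, x$alpha_single_d))
  cat(sprintf("  expected %.1f, observed %.1f -> cryptic range %.1f degrees\n",
              x$alpha_expected, x$alpha_observed, x$cryptic_range_deg))
  invisible(x)
}
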