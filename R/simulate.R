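#' Specification for a synthetic SGA-like cross table
#'
#' Describes the generative conditions: single-mutant fitnesses drawn
#' uniformly on a closed interval (default 0.1 to 0.9, so the default
#' fitness filter passes everything and test resolution is maximal -- the
#' difference between model predictions vanishes toward fitness 0 or 1);
#' each cross assigned a true relationship class (serial, parallel, or
#' epistatic); the true double-mutant fitness set by the class's neutrality
#' rule (perturbed by a true epsilon for epistatic pairs); additive Gaussian
#' measurement noise truncated at zero; and a reported per-cross standard
#' deviation dispersed around the true noise level.
#'
#' @param n_crosses number of crosses to generate.
#' @param frac_parallel probability a non-epistatic cross is parallel
#'   (remainder serial).
#' @param frac_epistatic probability a cross is truly epistatic.
#' @param epsilon_location,epsilon_scale normal location/scale of the true
#'   epsilon for epistatic pairs (placeholder values; the real-data epsilon
#'   distribution is not characterized).
#' @param fitness_min,fitness_max bounds of the uniform single-mutant
#'   fitness draw, within (0, 1].
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise on the double-mutant fitness.
#' @param replicate_sd_sd dispersion of the reported `sd_double` around
#'   `noise_sd`.
#' @param seed integer seed; the whole table is a deterministic function of
#'   the spec.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_crosses = 20000, frac_parallel = 0.5,
                            frac_epistatic = 0, epsilon_location = 0.5,
                            epsilon_scale = 0.25, fitness_min = 0.1,
                            fitness_max = 0.9, noise_sd = 0.05,
                            replicate_sd_sd = 0.005, seed = 1) {
  if (frac_parallel < 0 || frac_parallel > 1 ||
      frac_epistatic < 0 || frac_epistatic > 1) {
    stop_epibuffer("class fractions must lie in [0, 1]",
                   class = "epibuffer_validation_error")
  }
  if (fitness_min <= 0 || fitness_max > 1 || fitness_min > fitness_max) {
    stop_epibuffer("fitness bounds must satisfy 0 < min <= max <= 1",
                   class = "epibuffer_validation_error")
  }
  if (noise_sd < 0 || replicate_sd_sd < 0) {
    stop_epibuffer("noise parameters must be nonnegative",
                   class = "epibuffer_validation_error")
  }
  structure(
    list(n_crosses = n_crosses, frac_parallel = frac_parallel,
         frac_epistatic = frac_epistatic,
         epsilon_location = epsilon_location, epsilon_scale = epsilon_scale,
         fitness_min = fitness_min, fitness_max = fitness_max,
         noise_sd = noise_sd, replicate_sd_sd = replicate_sd_sd,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Generate a synthetic cross table with known ground truth
#'
#' @param spec a [simulation_spec()].
#' @return tibble with the canonical pipeline columns (`query_id`,
#'   `array_id`, `f_query`, `f_array`, `f_double`, `sd_double`) plus the
#'   ground-truth columns `true_class` (`"serial"`, `"parallel"`, or
#'   `"epistatic"`), `true_model` (the neutrality rule used), and
#'   `true_epsilon` (0 for non-epistatic crosses).
#' @examples
#' head(simulate_crosses(simulation_spec(n_crosses = 10, seed = 7)))
#' @export
simulate_crosses <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_crosses
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  f_query <- stats::runif(n, spec$fitness_min, spec$fitness_max)
  f_array <- stats::runif(n, spec$fitness_min, spec$fitness_max)
  epistatic <- stats::runif(n) < spec$frac_epistatic
  parallel_rel <- stats::runif(n) < spec$frac_parallel
  true_model <- ifelse(parallel_rel, "parallel", "serial")
  true_epsilon <- ifelse(
    epistatic, stats::rnorm(n, spec$epsilon_location, spec$epsilon_scale), 0)

  f_serial <- f_query * f_array
  f_parallel <- 1 / (1 / f_query + 1 / f_array - 1)

  # epistatic perturbation on the scale native to the cross's true model:
  # serial epsilon rescales t (t_cd = expected * (1 - eps)); parallel
  # epsilon rescales B (B_cd = (1 + eps) * B_expected)
  f_true <- ifelse(parallel_rel, f_parallel, f_serial)
  eps_serial_t <- f_serial * (1 - true_epsilon)
  B_expected <- 1 / f_parallel - 1
  B_cd <- (1 + true_epsilon) * B_expected
  eps_parallel_t <- ifelse(B_cd > -1, 1 / (1 + B_cd), 0)
  f_true[epistatic] <- ifelse(parallel_rel, eps_parallel_t, eps_serial_t)[epistatic]
  f_true <- pmax(f_true, 0)

  noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
  f_double <- pmax(f_true + noise, 0)
  sd_double <- pmax(
    stats::rnorm(n, spec$noise_sd, spec$replicate_sd_sd), 1e-6)

  tibble::tibble(
    query_id = sprintf("Q%05d", seq_len(n)),
    array_id = sprintf("A%05d", seq_len(n)),
    f_query = f_query, f_array = f_array,
    f_double = f_double, sd_double = sd_double,
    true_class = ifelse(epistatic, "epistatic", true_model),
    true_model = true_model,
    true_epsilon = true_epsilon
  )
}

#' Write a synthetic cross table and its ground-truth sidecar
#'
#' Writes the measurement columns as CSV in the dialect [load_crosses()]
#' reads, and the ground-truth labels as a JSON sidecar next to it.
#'
#' @param spec a [simulation_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulated_crosses <- function(spec, path) {
  tab <- simulate_crosses(spec)
  measured <- tab[, c("query_id", "array_id", "f_query", "f_array",
                      "f_double", "sd_double")]
  readr::write_csv(measured, path)
  truth <- tab[, c("query_id", "array_id", "true_class", "true_model",
                   "true_epsilon")]
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model-bias recovery experiment
#'
#' Generates a synthetic table and runs the full residual pipeline on it.
#' When parallel relationships are present, exclusive use of the serial
#' model underestimates double-mutant fitness (positive residual bias), the
#' parallel model overestimates it for serial pairs (negative bias), and
#' the hybrid model sits nearer zero than either.
#'
#' @param spec a [simulation_spec()].
#' @param fitness_range,q_min,df passed to [sga_run()].
#' @return the [sga_run()] result list, with the generated table attached
#'   as `truth`.
#' @examples
#' \donttest{
#' res <- bias_recovery_experiment(simulation_spec(n_crosses = 2000, seed = 3))
#' res$summaries
#' }
#' @export
bias_recovery_experiment <- function(spec, fitness_range = c(0.1, 0.9),
                                     q_min = 0.5, df = Inf) {
  tab <- simulate_crosses(spec)
  res <- sga_run(tab, fitness_range = fitness_range, q_min = q_min, df = df)
  res$truth <- tab
  res
}
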