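#' Column maps for SGA cross tables
#'
#' The pipeline works on a tibble with canonical columns `query_id`,
#' `array_id`, `f_query`, `f_array`, `f_double`, `sd_double`. A column map
#' is a named character vector `c(canonical = "header in the file")`
#' translating a delimited file's headers to those roles.
#' `sga_column_map()` is the identity map matching tables written by
#' [simulate_crosses()]; `costanzo2009_column_map()` targets the column
#' names commonly used for the genome-wide yeast interaction supplement and
#' can be edited to match the file actually downloaded.
#'
#' @return named character vector usable as the `column_map` argument of
#'   [load_crosses()].
#' @export
sga_column_map <- function() {
  c(query_id = "query_id", array_id = "array_id",
    f_query = "f_query", f_array = "f_array",
    f_double = "f_double", sd_double = "sd_double")
}

#' @rdname sga_column_map
#' @export
costanzo2009_column_map <- function() {
  c(query_id = "Query ORF", array_id = "Array ORF",
    f_query = "Query single mutant fitness (SMF)",
    f_array = "Array SMF",
    f_double = "Double mutant fitness",
    sd_double = "Double mutant fitness standard deviation")
}

#' Load an SGA cross table from delimited text
#'
#' Reads a delimited file with a header row, renames the mapped columns to
#' the canonical roles, coerces the fitness columns to numeric, and drops
#' (with a count) every row with a missing or unparseable value in any
#' mapped column.
#'
#' @param path file path (CSV, or TSV when `delim = "\t"` or the extension
#'   is `.tsv`).
#' @param column_map named character vector, see [sga_column_map()].
#' @param delim field delimiter; guessed from the extension when `NULL`.
#' @return A tibble of complete cross records; the number of dropped rows
#'   is attached as attribute `n_dropped` and reported via `message()`.
#' @export
load_crosses <- function(path, column_map = sga_column_map(), delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop_epibuffer(
      sprintf("mapped column(s) %s not found; available headers: %s",
              paste(sQuote(missing_cols), collapse = ", "),
              paste(sQuote(names(raw)), collapse = ", ")),
      class = "epibuffer_schema_error"
    )
  }
  out <- tibble::as_tibble(raw[, unname(column_map)])
  names(out) <- names(column_map)
  numeric_roles <- intersect(
    names(out), c("f_query", "f_array", "f_double", "sd_double",
                  "p_serial", "p_parallel"))
  for (cn in numeric_roles) {
    out[[cn]] <- suppressWarnings(as.numeric(out[[cn]]))
  }
  complete <- stats::complete.cases(out)
  n_dropped <- sum(!complete)
  out <- out[complete, ]
  message(sprintf("load_crosses: %d record(s) retained, %d dropped (incomplete)",
                  nrow(out), n_dropped))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Expected double-mutant fitness per cross
#'
#' Adds `f_expected_serial` (query fitness times array fitness) and
#' `f_expected_parallel` (B-sum rule, `1 / (1/f_q + 1/f_a - 1)`). Crosses
#' with nonpositive single-mutant fitness have an undefined parallel
#' expectation: they are flagged `parallel_defined = FALSE` with `NA` in the
#' parallel column and are excluded from parallel-model summaries
#' downstream, not dropped.
#'
#' @param crosses tibble with canonical columns (see [sga_column_map()]).
#' @return the tibble with expectation columns added.
#' @export
compute_expectations <- function(crosses) {
  stopifnot(all(c("f_query", "f_array", "f_double") %in% names(crosses)))
  ok <- crosses$f_query > 0 & crosses$f_array > 0
  dplyr::mutate(
    crosses,
    f_expected_serial = .data$f_query * .data$f_array,
    parallel_defined = ok,
    f_expected_parallel = dplyr::if_else(
      ok, 1 / (1 / .data$f_query + 1 / .data$f_array - 1), NA_real_)
  )
}

#' Per-cross significance of deviation from a neutrality model
#'
#' For each cross the statistic `(f_double - f_expected) / sd_double` is
#' referred to a two-tailed null distribution -- the standard normal by
#' default, or Student's t when a finite `df` is supplied -- and the
#' resulting p-values are Benjamini-Hochberg adjusted across all testable
#' crosses of the model family, giving q-values. Crosses with `sd_double <=
#' 0` or an undefined expectation are flagged with `NA` and excluded from
#' the adjustment.
#'
#' @param crosses tibble after [compute_expectations()].
#' @param model `"serial"` or `"parallel"`.
#' @param df degrees of freedom for a t reference distribution; `Inf`
#'   (default) uses the standard normal.
#' @return the tibble with `p_<model>` and `q_<model>` columns added.
#' @export
compute_qvalues <- function(crosses, model = c("serial", "parallel"), df = Inf) {
  model <- match.arg(model)
  exp_col <- paste0("f_expected_", model)
  stopifnot(exp_col %in% names(crosses), "sd_double" %in% names(crosses))
  z <- (crosses$f_double - crosses[[exp_col]]) / crosses$sd_double
  valid <- is.finite(z) & crosses$sd_double > 0
  p <- rep(NA_real_, nrow(crosses))
  p[valid] <- 2 * stats::pt(-abs(z[valid]), df = df)
  q <- rep(NA_real_, nrow(crosses))
  q[valid] <- stats::p.adjust(p[valid], method = "BH")
  crosses[[paste0("p_", model)]] <- p
  crosses[[paste0("q_", model)]] <- q
  crosses
}

#' Filter crosses on single-mutant fitness and neutrality q-values
#'
#' Keeps crosses whose single-mutant fitnesses both lie in
#' `[fitness_low, fitness_high]` (the deviation between model predictions
#' vanishes as fitness approaches 0 or 1, so the interval concentrates
#' resolution) and whose q-values strictly exceed `q_min` (removing likely
#' epistatic pairs, which by definition deviate from any neutrality
#' expectation). One shared filtered set is produced and feeds the residual
#' analysis of every model. A truly epistatic pair deviates from every
#' neutrality expectation, so the default rule (`q_rule = "any"`) keeps a
#' cross when its q exceeds `q_min` under at least one model -- the cross
#' fits some neutrality rule; `q_rule = "all"` demands it of every model,
#' and `q_cols` restricts the check to named q columns (e.g. a single
#' model's).
#'
#' @param crosses tibble after [compute_qvalues()].
#' @param fitness_low,fitness_high closed fitness interval (defaults 0.1,
#'   0.9).
#' @param q_min strict lower bound on q (default 0.5).
#' @param q_rule `"any"` (default) or `"all"`: how the q columns combine.
#' @param q_cols character vector of q column names; defaults to every
#'   column starting with `q_`.
#' @return the filtered tibble, with attribute `n_retained`.
#' @export
apply_filters <- function(crosses, fitness_low = 0.1, fitness_high = 0.9,
                          q_min = 0.5, q_rule = c("any", "all"),
                          q_cols = NULL) {
  q_rule <- match.arg(q_rule)
  if (is.null(q_cols)) q_cols <- grep("^q_", names(crosses), value = TRUE)
  if (length(q_cols) == 0) {
    stop_epibuffer("no q-value columns present: run compute_qvalues() first",
                   class = "epibuffer_validation_error")
  }
  keep <- crosses$f_query >= fitness_low & crosses$f_query <= fitness_high &
    crosses$f_array >= fitness_low & crosses$f_array <= fitness_high
  qmat <- vapply(q_cols, function(qc) {
    q <- crosses[[qc]]
    !is.na(q) & q > q_min
  }, logical(nrow(crosses)))
  qmat <- matrix(qmat, nrow = nrow(crosses))
  q_ok <- if (q_rule == "any") rowSums(qmat) > 0 else
    rowSums(qmat) == ncol(qmat)
  keep <- keep & q_ok
  out <- crosses[keep & !is.na(keep), ]
  attr(out, "n_retained") <- nrow(out)
  out
}

#' Hybrid neutrality expectation
#'
#' Per cross, adopts the expectation of whichever model is least likely to
#' conclude a true deviation -- the one with the larger q-value. Ties (and
#' crosses whose parallel expectation is undefined) resolve to the serial
#' model, the field's incumbent.
#'
#' @param crosses tibble with `q_serial` and `q_parallel` computed.
#' @return the tibble with `hybrid_model` and `f_expected_hybrid` added.
#' @export
hybrid_expectation <- function(crosses) {
  stopifnot(all(c("q_serial", "q_parallel") %in% names(crosses)))
  pick_parallel <- !is.na(crosses$q_parallel) &
    (is.na(crosses$q_serial) | crosses$q_parallel > crosses$q_serial)
  dplyr::mutate(
    crosses,
    hybrid_model = dplyr::if_else(pick_parallel, "parallel", "serial"),
    f_expected_hybrid = dplyr::if_else(pick_parallel,
                                       .data$f_expected_parallel,
                                       .data$f_expected_serial)
  )
}

#' Standardized residuals against a neutrality model
#'
#' Raw residuals `f_double - f_expected` divided by a single scale
#' `s = sqrt(sum(residual^2) / (n - 2))` computed over the supplied
#' (already filtered) set. Standardization is a positive rescaling, so sign
#' patterns and the fraction at or below zero are unchanged. When every
#' cross sits exactly on the model (`s = 0`) the residuals are returned as
#' exact zeros.
#'
#' @param crosses filtered tibble carrying `f_expected_<model>`.
#' @param model `"serial"`, `"parallel"`, or `"hybrid"`.
#' @return numeric vector of standardized residuals (crosses with an
#'   undefined expectation are omitted).
#' @export
standardized_residuals <- function(crosses,
                                   model = c("serial", "parallel", "hybrid")) {
  model <- match.arg(model)
  exp_col <- paste0("f_expected_", model)
  stopifnot(exp_col %in% names(crosses))
  raw <- crosses$f_double - crosses[[exp_col]]
  raw <- raw[is.finite(raw)]
  n <- length(raw)
  if (n < 3L) {
    stop_epibuffer("need at least 3 crosses for the residual scale (n - 2 > 0)",
                   class = "epibuffer_insufficient_data_error")
  }
  s <- sqrt(sum(raw^2) / (n - 2))
  if (s == 0) return(rep(0, n))
  raw / s
}

#' Summarize a residual distribution
#'
#' @param residuals numeric vector of (standardized) residuals.
#' @param model optional model label carried into the output.
#' @return one-row tibble: `model`, `n`, `median`, `mean`, `frac_le_zero`
#'   (the empirical `P(x) <= 0`).
#' @export
summarize_residuals <- function(residuals, model = NA_character_) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) == 0L) {
    stop_epibuffer("no residuals to summarize",
                   class = "epibuffer_insufficient_data_error")
  }
  tibble::tibble(
    model = model,
    n = length(residuals),
    median = stats::median(residuals),
    mean = mean(residuals),
    frac_le_zero = mean(residuals <= 0)
  )
}

#' Run the full SGA residual-analysis pipeline
#'
#' Convenience orchestrator: load (or accept) a cross table, compute serial
#' and parallel expectations and q-values, apply the fitness and q filters,
#' select the hybrid expectation, compute standardized residuals and
#' summaries per model, and compare the residual distributions pairwise
#' with the two-sample Cramér–von Mises test.
#'
#' @param input a file path or a tibble of cross records.
#' @param column_map used when `input` is a path.
#' @param fitness_range length-2 numeric, closed single-mutant fitness
#'   interval (default `c(0.1, 0.9)`).
#' @param q_min strict q-value floor (default 0.5).
#' @param q_rule,q_cols passed to [apply_filters()].
#' @param df degrees of freedom for the per-cross test (default `Inf`:
#'   standard normal).
#' @param models models to summarize, subset of serial/parallel/hybrid.
#' @param out_dir optional directory; when given, the augmented per-cross
#'   table (CSV) and a JSON summary are written there.
#' @return list with `crosses` (augmented, unfiltered), `filtered`,
#'   `residuals` (named list of vectors), `summaries` (tibble), and `cvm`
#'   (tibble of pairwise comparisons).
#' @export
sga_run <- function(input, column_map = sga_column_map(),
                    fitness_range = c(0.1, 0.9), q_min = 0.5,
                    q_rule = c("any", "all"), q_cols = NULL, df = Inf,
                    models = c("serial", "parallel", "hybrid"),
                    out_dir = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  crosses <- if (is.character(input)) load_crosses(input, column_map) else
    tibble::as_tibble(input)

  crosses <- compute_expectations(crosses)
  crosses <- compute_qvalues(crosses, "serial", df = df)
  crosses <- compute_qvalues(crosses, "parallel", df = df)
  crosses <- hybrid_expectation(crosses)

  filtered <- apply_filters(crosses, fitness_low = fitness_range[1],
                            fitness_high = fitness_range[2], q_min = q_min,
                            q_rule = q_rule, q_cols = q_cols)
  message(sprintf("apply_filters: %d of %d cross(es) retained",
                  nrow(filtered), nrow(crosses)))

  residuals <- lapply(stats::setNames(models, models), function(m) {
    standardized_residuals(filtered, m)
  })
  summaries <- dplyr::bind_rows(
    lapply(models, function(m) summarize_residuals(residuals[[m]], model = m))
  )

  pairs <- utils::combn(models, 2, simplify = FALSE)
  cvm <- dplyr::bind_rows(lapply(pairs, function(pr) {
    ht <- cvm_2sample_test(residuals[[pr[1]]], residuals[[pr[2]]])
    tibble::tibble(model_a = pr[1], model_b = pr[2],
                   statistic = unname(ht$statistic), p_value = ht$p.value)
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(crosses, file.path(out_dir, "crosses_augmented.csv"))
    jsonlite::write_json(
      list(summaries = summaries, cvm = cvm,
           n_input = nrow(crosses), n_retained = nrow(filtered)),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }

  list(crosses = crosses, filtered = filtered, residuals = residuals,
       summaries = summaries, cvm = cvm)
}

#' Density plot of standardized residuals by model
#'
#' @param residuals named list of residual vectors, as returned in
#'   `sga_run()$residuals`.
#' @return a ggplot object.
#' @export
residual_density_plot <- function(residuals) {
  df <- dplyr::bind_rows(lapply(names(residuals), function(m) {
    tibble::tibble(model = m, residual = residuals[[m]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residual, colour = .data$model)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "standardized residual", y = "density") +
    ggplot2::theme_minimal()
}
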