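test_that("loading drops incomplete rows and reports unknown columns", {
  df <- tiny_crosses()
  df$f_double[3] <- NA
  df <- rbind(df, df[1, ])  # 6 rows, one blank fitness cell
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_csv(df, path)
  expect_message(loaded <- load_crosses(path), "1 dropped")
  expect_equal(nrow(loaded), 5)
  expect_equal(attr(loaded, "n_dropped"), 1)

  bad_map <- sga_column_map()
  bad_map[["f_double"]] <- "no_such_column"
  err <- expect_error(suppressMessages(load_crosses(path, bad_map)),
                      class = "epibuffer_schema_error")
  expect_match(conditionMessage(err), "f_query")  # lists available headers

  # a simulated table round-trips losslessly through CSV
  tab <- simulate_crosses(simulation_spec(n_crosses = 50, seed = 9))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_simulated_crosses(simulation_spec(n_crosses = 50, seed = 9), p2)
  reread <- suppressMessages(load_crosses(p2))
  expect_equal(reread$f_double, tab$f_double, tolerance = 1e-12)
  expect_equal(reread$sd_double, tab$sd_double, tolerance = 1e-12)
})

test_that("expectations follow the product and B-sum rules per cross", {
  cr <- compute_expectations(tiny_crosses())
  expect_equal(cr$f_expected_serial[1], 0.35)
  expect_equal(cr$f_expected_parallel[1], 0.412, tolerance = 2e-3)
  expect_equal(compute_expectations(
    tibble::tibble(f_query = 1, f_array = 0.37, f_double = 0.37,
                   sd_double = 0.1))$f_expected_parallel, 0.37)
  expect_equal(compute_expectations(
    tibble::tibble(f_query = 0.9, f_array = 0.9, f_double = 0.8,
                   sd_double = 0.1))$f_expected_serial, 0.81)
  expect_equal(compute_expectations(
    tibble::tibble(f_query = 0.9, f_array = 0.9, f_double = 0.8,
                   sd_double = 0.1))$f_expected_parallel, 0.81818,
    tolerance = 5e-5)
  # nonpositive fitness flags the parallel branch instead of failing
  flagged <- compute_expectations(
    tibble::tibble(f_query = c(0.5, 0), f_array = c(0.5, 0.5),
                   f_double = c(0.2, 0.1), sd_double = c(0.1, 0.1)))
  expect_false(flagged$parallel_defined[2])
  expect_true(is.na(flagged$f_expected_parallel[2]))
})

test_that("q-values come from a two-tailed test with BH adjustment", {
  cr <- compute_expectations(tiny_crosses())
  cr <- compute_qvalues(cr, "serial")
  # cross 1 sits exactly on the serial model
  expect_equal(cr$p_serial[1], 1)
  expect_equal(cr$q_serial[1], 1)
  # z = 1.96 should give p near 0.05 under the normal reference
  one <- compute_qvalues(compute_expectations(
    tibble::tibble(f_query = 1, f_array = 0.5,
                   f_double = 0.5 + 1.959964 * 0.05, sd_double = 0.05)),
    "serial")
  expect_equal(one$p_serial, 0.05, tolerance = 1e-5)
  # BH oracle on a hand case: p = (.01,.02,.03,.04) -> q all 0.04
  hand <- compute_qvalues(
    tibble::tibble(f_query = rep(1, 4), f_array = rep(0.5, 4),
                   f_double = 0.5 + qnorm(1 - c(.01, .02, .03, .04) / 2) * 0.1,
                   sd_double = 0.1,
                   f_expected_serial = 0.5),
    "serial")
  expect_equal(hand$q_serial, rep(0.04, 4), tolerance = 1e-6)
  # q >= p and capped at 1
  cr2 <- compute_qvalues(compute_expectations(
    simulate_crosses(simulation_spec(n_crosses = 200, seed = 4))), "serial")
  expect_true(all(cr2$q_serial >= cr2$p_serial - 1e-12))
  expect_true(all(cr2$q_serial <= 1))
  # nonpositive sd is flagged, not fatal
  sd0 <- compute_qvalues(compute_expectations(
    tibble::tibble(f_query = 0.5, f_array = 0.5, f_double = 0.3,
                   sd_double = 0)), "serial")
  expect_true(is.na(sd0$p_serial))
})

test_that("filters keep the fitness window and neutrality-consistent crosses", {
  cr <- tibble::tibble(
    query_id = paste0("q", 1:10), array_id = paste0("a", 1:10),
    f_query  = c(0.5, 0.95, 0.5, 0.05, 0.5, 0.5, 0.3, 0.9, 0.1, 0.5),
    f_array  = c(0.5, 0.5, 0.96, 0.5, 0.5, 0.5, 0.4, 0.9, 0.1, 0.5),
    f_double = c(0.25, 0.4, 0.4, 0.02, 0.25, 0.1, 0.12, 0.81, 0.01, 0.26),
    sd_double = rep(0.02, 10))
  cr <- compute_qvalues(compute_qvalues(compute_expectations(cr), "serial"),
                        "parallel")
  kept <- apply_filters(cr)
  # out-of-window singles are gone regardless of q
  expect_false(any(kept$f_query < 0.1 | kept$f_query > 0.9 |
                   kept$f_array < 0.1 | kept$f_array > 0.9))
  # strongly deviating cross 6 (f_double far from both expectations) is gone
  expect_false("q6" %in% kept$query_id)
  # boundary fitness 0.1 and 0.9 are inside the closed interval
  expect_true("q9" %in% kept$query_id || cr$q_serial[9] <= 0.5)
  expect_equal(attr(kept, "n_retained"), nrow(kept))
  expect_equal(nrow(apply_filters(cr[0, ])), 0)
  expect_error(apply_filters(tiny_crosses()),
               class = "epibuffer_validation_error")
})

test_that("standardized residuals use the shared n-2 scale and keep signs", {
  # hand fixture: raw residuals (0.1, -0.1, 0.2, 0, -0.2)
  raw <- c(0.1, -0.1, 0.2, 0, -0.2)
  cr <- tibble::tibble(
    f_query = rep(1, 5), f_array = rep(0.5, 5),
    f_double = 0.5 + raw, sd_double = 0.05,
    f_expected_serial = 0.5)
  std <- standardized_residuals(cr, "serial")
  s <- sqrt(sum(raw^2) / 3)
  expect_equal(s, 0.1826, tolerance = 2e-3)
  expect_equal(std, c(0.548, -0.548, 1.095, 0, -1.095), tolerance = 5e-3)
  expect_equal(sign(std), sign(raw))
  # frac <= 0 is invariant to standardization
  expect_equal(mean(std <= 0), mean(raw <= 0))
  # all-on-model set yields exact zeros
  on_model <- tibble::tibble(f_query = rep(0.8, 4), f_array = 0.5,
                             f_double = 0.4, sd_double = 0.05,
                             f_expected_serial = 0.4)
  expect_equal(standardized_residuals(on_model, "serial"), rep(0, 4))
  expect_error(standardized_residuals(cr[1:2, ], "serial"),
               class = "epibuffer_insufficient_data_error")
})

test_that("residual summaries report median, mean, and P(x) <= 0", {
  sm <- summarize_residuals(c(-1, 0, 1), model = "serial")
  expect_equal(sm$median, 0)
  expect_equal(sm$mean, 0)
  expect_equal(sm$frac_le_zero, 2 / 3)
  expect_equal(sm$n, 3)
  expect_error(summarize_residuals(numeric(0)),
               class = "epibuffer_insufficient_data_error")
})

test_that("the hybrid model adopts the least-rejecting expectation", {
  cr <- tibble::tibble(
    f_expected_serial = c(0.35, 0.35, 0.35),
    f_expected_parallel = c(0.41, 0.41, 0.41),
    q_serial = c(0.9, 0.2, 0.5),
    q_parallel = c(0.3, 0.8, 0.5))
  h <- hybrid_expectation(cr)
  expect_equal(h$hybrid_model, c("serial", "parallel", "serial"))  # tie -> serial
  expect_equal(h$f_expected_hybrid, c(0.35, 0.41, 0.35))
  # on noise-free single-model data the true model is selected essentially always
  for (fp in c(0, 1)) {
    tab <- simulate_crosses(simulation_spec(n_crosses = 400, frac_parallel = fp,
                                            noise_sd = 0, seed = 21))
    aug <- hybrid_expectation(compute_qvalues(compute_qvalues(
      compute_expectations(tab), "serial"), "parallel"))
    expect_gte(mean(aug$hybrid_model == aug$true_model), 0.99)
  }
})

test_that("per-cross parallel expectation dominance orders the residuals", {
  tab <- compute_expectations(
    simulate_crosses(simulation_spec(n_crosses = 300, seed = 13)))
  expect_true(all(tab$f_expected_parallel >= tab$f_expected_serial - 1e-12))
  res_serial <- tab$f_double - tab$f_expected_serial
  res_parallel <- tab$f_double - tab$f_expected_parallel
  expect_true(all(res_serial >= res_parallel - 1e-12))
})

test_that("sga_run writes the augmented table and summary JSON", {
  out <- withr::local_tempdir()
  tab <- simulate_crosses(simulation_spec(n_crosses = 500, seed = 17))
  res <- suppressMessages(sga_run(tab, out_dir = out))
  expect_true(file.exists(file.path(out, "crosses_augmented.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  js <- jsonlite::fromJSON(file.path(out, "summary.json"))
  expect_equal(js$n_retained, nrow(res$filtered))
  expect_setequal(res$summaries$model, c("serial", "parallel", "hybrid"))
  p <- residual_density_plot(res$residuals)
  expect_s3_class(p, "ggplot")
})
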