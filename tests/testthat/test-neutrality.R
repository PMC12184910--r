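test_that("serial expectation is the product of transfer fractions", {
  e <- expected_serial(states_from(c(0.7, 0.5)))
  expect_equal(e$state$t_bar, 0.35)
  expect_equal(e$state$b, 0.65)
  expect_equal(e$state$T, 0.538, tolerance = 5e-3)
  expect_equal(e$state$B, 1.857, tolerance = 5e-3)
  expect_equal(e$state$alpha_deg, 61.7, tolerance = 5e-3)
  # neutral cofactor
  expect_equal(expected_serial(states_from(c(0.42, 1)))$state$t_bar, 0.42)
  expect_error(expected_serial(states_from(0.5)),
               class = "epibuffer_validation_error")
})

test_that("parallel expectation sums B and converts back", {
  e <- expected_parallel(states_from(c(0.5, 0.5)))  # two unit-B vessels
  expect_equal(e$state$B, 2)
  expect_equal(e$state$t_bar, 1 / 3)

  e2 <- expected_parallel(states_from(c(0.7, 0.5)))
  expect_equal(e2$state$t_bar, 0.412, tolerance = 2e-3)
  expect_equal(e2$state$B, 1.429, tolerance = 2e-3)
  expect_equal(e2$state$T, 0.700, tolerance = 2e-3)
  expect_equal(e2$state$alpha_deg, 55, tolerance = 5e-2)

  # neutral cofactor: B = 0 adds nothing
  expect_equal(expected_parallel(states_from(c(0.42, 1)))$state$t_bar, 0.42)
  # a zero-transfer state has no B
  expect_error(expected_parallel(states_from(c(0, 0.5))),
               class = "epibuffer_undefined_error")
})

test_that("fold rules are commutative and associative", {
  t3 <- c(0.8, 0.5, 0.6)
  perms <- list(t3, rev(t3), t3[c(2, 1, 3)])
  ser <- vapply(perms, function(p) expected_serial(states_from(p))$state$t_bar,
                numeric(1))
  par <- vapply(perms, function(p) expected_parallel(states_from(p))$state$t_bar,
                numeric(1))
  expect_equal(max(ser) - min(ser), 0)
  expect_equal(max(par) - min(par), 0)
  # pairwise folding equals the flat fold
  inner_s <- expected_serial(states_from(t3[1:2]))$state
  expect_equal(expected_serial(list(inner_s, state_from_t_bar(t3[3])))$state$t_bar,
               ser[1])
  inner_p <- expected_parallel(states_from(t3[1:2]))$state
  expect_equal(expected_parallel(list(inner_p, state_from_t_bar(t3[3])))$state$t_bar,
               par[1])
})

test_that("exponential serial action collapses to the rate sum rule", {
  expect_equal(expected_exponential_serial_rate(1, c(0.7, 0.5)), 0.2)
  expect_equal(expected_exponential_serial_rate(1, c(0.9, 0.3)), 0.2)
  expect_equal(expected_exponential_serial_rate(0.8, c(0.8, 0.8)), 0.8)
  # product-of-t_bar trajectory equals the closed-form rate trajectory
  r_ref <- 1; r1 <- 0.7; r2 <- 0.5
  r_iv <- expected_exponential_serial_rate(r_ref, c(r1, r2))
  ts <- seq(0, 10, length.out = 101)
  prod_traj <- exp((r1 - r_ref) * ts) * exp((r2 - r_ref) * ts) * exp(r_ref * ts)
  expect_equal(prod_traj, exp(r_iv * ts), tolerance = 1e-9)
})

test_that("exponential parallel action yields a time-varying trajectory", {
  e <- expected_exponential_parallel_trajectory(1, c(0.7, 0.5))
  expect_true(e$time_varying)
  ts <- c(0.5, 1, 2, 5)
  expect_equal(e$trajectory(ts),
               exp(ts + log(1 / (exp(0.3 * ts) + exp(0.5 * ts) - 1))))
  expect_equal(e$trajectory(1), 1.3601, tolerance = 2e-3)
  # wild-type cofactors leave the reference untouched
  ewt <- expected_exponential_parallel_trajectory(1, c(1, 1))
  expect_equal(ewt$trajectory(3), exp(3))
  # pointwise equal to the generic B-sum recipe applied at each time
  ref <- growth_model("exponential", 1)
  for (t in ts) {
    B1 <- buffering_state_at(ref, growth_model("exponential", 0.7), t)$B
    B2 <- buffering_state_at(ref, growth_model("exponential", 0.5), t)$B
    expect_equal(e$trajectory(t), exp(t) / (1 + B1 + B2), tolerance = 1e-12)
  }
})

test_that("parallel fitness expectation dominates the serial one on (0,1]", {
  expect_equal(expected_double_fitness(0.7, 0.5, "serial"), 0.35)
  expect_equal(expected_double_fitness(0.7, 0.5, "parallel"), 0.412,
               tolerance = 2e-3)
  expect_equal(expected_double_fitness(0.63, 1, "parallel"), 0.63)

  f <- seq(0.05, 1, by = 0.05)
  grid <- expand.grid(f1 = f, f2 = f)
  ser <- expected_double_fitness(grid$f1, grid$f2, "serial")
  par <- expected_double_fitness(grid$f1, grid$f2, "parallel")
  expect_true(all(par >= ser - 1e-12))
  interior <- grid$f1 < 1 & grid$f2 < 1
  expect_true(all(par[interior] > ser[interior]))
  expect_error(expected_double_fitness(0, 0.5, "parallel"),
               class = "epibuffer_undefined_error")

  # exponential-growth gap: serial rate minus product rate = -(1-r1)(1-r2)
  r <- seq(0, 1, by = 0.1)
  g <- expand.grid(r1 = r, r2 = r)
  gap <- (g$r1 + g$r2 - 1) - g$r1 * g$r2
  expect_equal(gap, -(1 - g$r1) * (1 - g$r2))
  expect_true(all(gap <= 1e-12))
})
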