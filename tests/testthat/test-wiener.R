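test_that("closed forms for accuracy and expected times evaluate correctly", {
  # zero drift is symmetric
  expect_equal(p_correct(diffusion_params(1.5, 0)), 0.5)
  # antisymmetry in the drift sign
  for (pars in list(c(1, 1), c(2, -0.7), c(0.6, 3))) {
    expect_equal(p_correct(diffusion_params(pars[1], pars[2])) +
                   p_correct(diffusion_params(pars[1], -pars[2])), 1)
  }
  # direct evaluation at a*v = 3.66
  expect_equal(p_correct(diffusion_params(1.5, 2.44)), plogis(3.66),
               tolerance = 1e-12)
  expect_equal(p_correct(diffusion_params(1.5, 2.44)), 0.9749,
               tolerance = 1e-4)
  # accuracy depends on the product a*v only
  expect_equal(p_correct(diffusion_params(1, 2.2)),
               p_correct(diffusion_params(2, 1.1)))

  # drift-free limit a^2/4 and closed-form decision times
  expect_equal(mean_decision_time(diffusion_params(2, 0)), 1.0)
  expect_equal(mean_decision_time(diffusion_params(2, 1e-12)), 1.0,
               tolerance = 1e-9)
  expect_equal(mean_decision_time(diffusion_params(2, 1)), tanh(1),
               tolerance = 1e-12)
  expect_equal(mean_decision_time(diffusion_params(1.5, 2.44)), 0.292,
               tolerance = 1e-3)

  # expected RT is decision time plus t0, additively
  expect_equal(expected_rt(diffusion_params(2, 1, 0.5)), tanh(1) + 0.5)
  expect_equal(expected_rt(diffusion_params(2, 1, 0, 0)),
               mean_decision_time(diffusion_params(2, 1)))
  base <- expected_rt(diffusion_params(1.3, 1.7, 0.4))
  expect_equal(expected_rt(diffusion_params(1.3, 1.7, 0.8)), base + 0.4)
})

test_that("parameter domain violations are rejected", {
  expect_error(diffusion_params(-1, 1), "positive")
  expect_error(diffusion_params(1, 1, -0.1), "non-negative")
  expect_error(diffusion_params(1, 1, 0.1, 0.5), "negative")
  expect_error(fpt_density(c(0.5, Inf), diffusion_params(1, 1)), "finite")
})

test_that("defective FPT densities integrate to the boundary masses", {
  for (pars in list(c(1, 1), c(1.5, 2), c(2, 0), c(0.8, -1.5),
                    c(3, 3), c(1.5, 2.44))) {
    dp <- diffusion_params(pars[1], pars[2])
    ic <- integrate(function(t) fpt_density(t, dp, "correct"), 0, Inf,
                    rel.tol = 1e-10)$value
    ie <- integrate(function(t) fpt_density(t, dp, "error"), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(ic, p_correct(dp), tolerance = 1e-8)
    expect_equal(ic + ie, 1, tolerance = 1e-8)
  }
})

test_that("zero drift makes the two boundary densities identical", {
  dp <- diffusion_params(1.7, 0)
  tt <- c(0.05, 0.2, 0.5, 1, 2)
  expect_equal(fpt_density(tt, dp, "correct"),
               fpt_density(tt, dp, "error"))
})

test_that("FPT distribution matches quadrature of the density", {
  dp <- diffusion_params(1.5, 2)
  for (t in c(0.02, 0.1, 0.3, 0.5, 1, 2.5)) {
    q <- integrate(function(s) fpt_density(s, dp, "correct"), 0, t,
                   rel.tol = 1e-11)$value
    expect_equal(fpt_cdf(t, dp, "correct"), q, tolerance = 1e-5)
  }
  # end-point behaviour
  expect_equal(fpt_cdf(0, dp, "correct"), 0)
  expect_equal(fpt_cdf(0, dp, "error"), 0)
  expect_equal(fpt_cdf(Inf, dp, "correct"), p_correct(dp))
  expect_equal(fpt_cdf(50, dp, "error"), 1 - p_correct(dp),
               tolerance = 1e-10)
  # nondecreasing
  tt <- seq(0.01, 4, by = 0.01)
  expect_true(all(diff(fpt_cdf(tt, dp, "correct")) >= 0))
})

test_that("FPT density matches a Monte-Carlo simulation oracle", {
  set.seed(101)
  dp <- diffusion_params(1, 1)
  tr <- simulate_trials(2e5, dp)
  # mass in a bin around t = 0.3 at the correct boundary
  inbin <- tr$correct == 1 & tr$rt >= 0.25 & tr$rt <= 0.35
  model_mass <- fpt_cdf(0.35, dp, "correct") - fpt_cdf(0.25, dp, "correct")
  se <- sqrt(model_mass * (1 - model_mass) / 2e5)
  expect_lt(abs(mean(inbin) - model_mass), 3 * se)
  # density consistent with its CDF by central differencing
  h <- 1e-4
  expect_equal(fpt_density(0.3, dp, "correct"),
               (fpt_cdf(0.3 + h, dp, "correct") -
                  fpt_cdf(0.3 - h, dp, "correct")) / (2 * h),
               tolerance = 1e-5)
})

test_that("signed CDF has the right mass at zero, limits and monotonicity", {
  set.seed(4)
  for (i in 1:15) {
    dp <- diffusion_params(runif(1, 0.5, 3), runif(1, -3, 3),
                           t0 <- runif(1, 0.2, 0.9),
                           runif(1, 0, 1.8 * t0))
    expect_equal(signed_rt_cdf(0, dp), 1 - p_correct(dp),
                 tolerance = 1e-9)
    grid <- seq(-6, 8, by = 0.05)
    fm <- signed_rt_cdf(grid, dp)
    expect_true(all(diff(fm) >= -1e-12))
    expect_true(all(fm >= 0 & fm <= 1))
    # limits far in the tails (slow-drift parameter sets decay slowly)
    expect_lt(signed_rt_cdf(-80, dp), 1e-6)
    expect_gt(signed_rt_cdf(80, dp), 1 - 1e-6)
  }
})

test_that("zero-width non-decision window reduces to a pure shift", {
  dp0 <- diffusion_params(1.4, 1.8, 0, 0)
  dp <- diffusion_params(1.4, 1.8, 0.55, 0)
  tt <- c(0.2, 0.5, 1, 2)
  expect_equal(signed_rt_cdf(tt + 0.55, dp), signed_rt_cdf(tt, dp0),
               tolerance = 1e-12)
})

test_that("signed CDF matches the empirical CDF of simulated trials", {
  set.seed(202)
  dp <- diffusion_params(1.5, 2, 0.7, 0.2)
  tr <- simulate_trials(3e5, dp)
  s <- ifelse(tr$correct == 1, tr$rt, -tr$rt)
  grid <- seq(-3.5, 4.5, by = 0.005)
  sup <- max(abs(signed_rt_cdf(grid, dp) - ecdf(s)(grid)))
  expect_lt(sup, 0.005)  # KS 99.9% band at n = 3e5 is ~0.0036
})

test_that("simulator agrees with the closed forms (bias check)", {
  set.seed(303)
  dp <- diffusion_params(1.5, 2)
  tr <- simulate_trials(1e5, dp)
  pc <- p_correct(dp)
  expect_lt(abs(mean(tr$correct) - pc), 3 * sqrt(pc * (1 - pc) / 1e5))

  dp2 <- diffusion_params(2, 1, 0.5, 0)
  tr2 <- simulate_trials(1e5, dp2)
  se_rt <- sd(tr2$rt) / sqrt(1e5)
  expect_lt(abs(mean(tr2$rt) - expected_rt(dp2)), 3 * se_rt)

  dp3 <- diffusion_params(1.5, 0)
  tr3 <- simulate_trials(1e5, dp3)
  expect_lt(abs(mean(tr3$correct) - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("predicted quartiles are ordered, shift with t0 and match simulation", {
  dp <- diffusion_params(1.5, 2, 0.7, 0.2)
  pq <- predicted_quartiles(dp)
  expect_true(all(diff(pq$quartiles) > 0))
  expect_equal(pq$accuracy, p_correct(dp))

  # location shift with degenerate window
  q1 <- predicted_quartiles(diffusion_params(1.5, 2, 0.4, 0))$quartiles
  q2 <- predicted_quartiles(diffusion_params(1.5, 2, 0.65, 0))$quartiles
  expect_equal(q2 - q1, rep(0.25, 3), tolerance = 1e-5,
               ignore_attr = TRUE)

  set.seed(404)
  tr <- simulate_trials(2e5, dp)
  eq <- quantile(tr$rt, c(0.25, 0.5, 0.75))
  expect_equal(unname(pq$quartiles), unname(eq), tolerance = 0.005)
  pqc <- predicted_quartiles(dp, mode = "correct")
  eqc <- quantile(tr$rt[tr$correct == 1], c(0.25, 0.5, 0.75))
  expect_equal(unname(pqc$quartiles), unname(eqc), tolerance = 0.005)
})
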