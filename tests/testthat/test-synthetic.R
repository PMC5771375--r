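test_that("symbolic design invariants hold across seeds", {
  for (seed in 1:40) {
    set.seed(seed)
    d <- make_symbolic_design()
    test <- d[!d$practice, ]
    expect_equal(nrow(test), 24)
    expect_equal(sum(d$practice), 3)
    dist <- abs(test$left_value - test$right_value)
    expect_equal(unname(table(factor(dist, levels = 1:6))),
                 rep(4L, 6), ignore_attr = TRUE)
    expect_true(all(test$left_value %in% 1:9))
    expect_true(all(test$right_value %in% 1:9))
    expect_true(all(test$left_value != test$right_value))
    # larger side counterbalanced within each distance
    larger_left <- test$left_value > test$right_value
    expect_true(all(tapply(larger_left, dist, sum) == 2))
  }
})

test_that("non-symbolic design invariants hold across seeds", {
  for (seed in 1:40) {
    set.seed(seed)
    d <- make_nonsymbolic_design()
    test <- d[!d$practice, ]
    expect_equal(nrow(test), 48)
    expect_equal(sum(d$practice), 2)
    expect_equal(unname(table(test$ratio_bin)), rep(12L, 4),
                 ignore_attr = TRUE)
    expect_true(all(test$n1 %in% 5:21 & test$n2 %in% 5:21))
    r <- pmax(test$n1, test$n2) / pmin(test$n1, test$n2)
    expect_true(all(abs(r - test$ratio_bin) <= 0.05 + 1e-9))
    expect_equal(sum(test$size_control), 24)
    # half of each bin is size-controlled
    expect_true(all(tapply(test$size_control, test$ratio_bin, sum) == 6))
  }
})

test_that("infeasible ratio bins are refused", {
  expect_error(make_nonsymbolic_design(ratio_bins = c(1.2, 1.4, 1.6, 9)),
               "no integer dot pair")
})

test_that("population sampling matches the configured sizes and means", {
  pop <- sample_population(seed = 51)
  expect_equal(nrow(pop), 353)
  expect_equal(sum(pop$group == "con"), 272)
  expect_equal(sum(pop$group == "dys"), 81)
  expect_true(all(pop$a_symbolic > 0))
  expect_true(all(pop$t0_symbolic - pop$st0_symbolic / 2 >= 0))
  expect_true(all(pop$weber_true >= 0 & pop$weber_true <= 3))

  # con-group symbolic drift mean close to its configured value
  means <- vapply(1:8, function(i) {
    p <- sample_population(seed = 600 + i)
    mean(p$v_symbolic[p$group == "con"])
  }, numeric(1))
  se <- 0.9 / sqrt(272)  # configured SD over the group size
  expect_lt(abs(mean(means) - 2.44), 3 * se / sqrt(8) + 0.02)
})

test_that("zero-variance configuration collapses to the group means", {
  cfg <- small_config(3, 2)
  for (g in names(cfg$groups))
    for (task in c("symbolic", "nonsymbolic"))
      for (par in names(cfg$groups[[g]][[task]]))
        cfg$groups[[g]][[task]][[par]][2] <- 0
  pop <- sample_population(cfg, seed = 52)
  expect_equal(unique(pop$v_symbolic[pop$group == "con"]), 2.44)
  expect_equal(unique(pop$a_nonsymbolic[pop$group == "dys"]), 1.60)
})

test_that("the same master seed reproduces the dataset byte for byte", {
  cfg <- small_config(4, 3)
  run <- function() {
    set.seed(99)
    pop <- sample_population(cfg)
    trials <- simulate_dataset(pop)
    inject_contaminants(trials, 0.0101, 0.0125)
  }
  expect_identical(run(), run())
})

test_that("achievement loadings induce the expected correlation signs", {
  pop <- sample_population(seed = 53)
  expect_gt(cor(pop$achievement[pop$group == "con"],
                pop$v_symbolic[pop$group == "con"]), 0.1)
  expect_lt(cor(pop$achievement[pop$group == "con"],
                pop$a_symbolic[pop$group == "con"]), -0.1)
  # cross-task coupling of the same parameter
  expect_gt(cor(pop$v_symbolic, pop$v_nonsymbolic), 0.3)
})

test_that("simulated cohorts reproduce the closed-form accuracy oracle", {
  set.seed(54)
  cfg <- small_config(25, 0)
  cfg$groups$dys <- NULL
  designs <- list(symbolic = make_symbolic_design(),
                  nonsymbolic = make_nonsymbolic_design())
  pop <- sample_population(cfg)
  trials <- simulate_dataset(pop, designs = designs)
  sym_acc <- mean(trials$correct[trials$task == "symbolic"])
  ns_acc <- mean(trials$correct[trials$task == "nonsymbolic"])
  # closed-form oracle: accuracy is plogis(a * v) per subject (averaged
  # over the per-item drift scaling for the dot task)
  oracle_sym <- mean(plogis(pop$a_symbolic * pop$v_symbolic))
  ns_items <- designs$nonsymbolic[!designs$nonsymbolic$practice, ]
  ratio <- pmax(ns_items$n1, ns_items$n2) / pmin(ns_items$n1, ns_items$n2)
  scale <- log(ratio) / mean(log(ratio))
  oracle_ns <- mean(vapply(seq_len(nrow(pop)), function(i)
    mean(plogis(pop$a_nonsymbolic[i] * pop$v_nonsymbolic[i] * scale)),
    numeric(1)))
  # ~1100 Bernoulli trials per task: 3 binomial SDs is ~2.5 points
  expect_lt(abs(sym_acc - oracle_sym), 0.03)
  expect_lt(abs(ns_acc - oracle_ns), 0.03)
  # and the control group stays a high performer on both tasks
  expect_gt(sym_acc, 0.88)
  expect_gt(ns_acc, 0.75)
  # a drift-free subject performs at chance
  pop0 <- pop[1, ]
  pop0$v_symbolic <- 1e-6
  tr0 <- do.call(rbind, replicate(30, simulate_dataset(pop0),
                                  simplify = FALSE))
  acc0 <- mean(tr0$correct[tr0$task == "symbolic"])
  expect_equal(acc0, 0.5, tolerance = 3 * sqrt(0.25 / 720))
})

test_that("contaminant injection hits the requested rates and is optional", {
  set.seed(55)
  cfg <- small_config(40, 15)
  pop <- sample_population(cfg)
  trials <- simulate_dataset(pop)
  expect_identical(inject_contaminants(trials, 0, 0), trials)
  dirty <- inject_contaminants(trials, 0.0101, 0.0125)
  pre <- preprocess_trials(dirty)
  n_post <- pre$report$n_input - pre$report$n_removed_practice
  frac_fast <- pre$report$n_removed_fast / n_post
  frac_slow <- pre$report$n_removed_slow / n_post
  # binomial noise plus a small genuine-tail leak: both stay within
  # about half a percentage point of the injected rates
  expect_lt(abs(frac_fast - 0.0101), 0.006)
  expect_lt(abs(frac_slow - 0.0125), 0.006)
})

test_that("filtering contaminated data improves parameter recovery", {
  set.seed(56)
  truth <- diffusion_params(1.5, 2.44, 0.73, 0.23)
  err_filtered <- c(); err_raw <- c()
  for (i in 1:12) {
    tr <- sim_cell(200, truth)
    tr <- make_trials(rt_s = tr$rt_s, correct = tr$correct)
    dirty <- inject_contaminants(tr, 0.05, 0.08)
    f_raw <- fit_subject_task(dirty, seed = i, n_restarts = 3,
                              reltol = 1e-4, maxit = 250)
    kept <- apply_rt_cutoffs(dirty)$kept
    f_fil <- fit_subject_task(kept, seed = i, n_restarts = 3,
                              reltol = 1e-4, maxit = 250)
    dist <- function(f) abs(f$params$v - truth$v) + abs(f$params$a - truth$a)
    err_raw <- c(err_raw, dist(f_raw))
    err_filtered <- c(err_filtered, dist(f_fil))
  }
  expect_lt(mean(err_filtered), mean(err_raw))
})
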