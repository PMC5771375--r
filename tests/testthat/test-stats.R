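test_that("Pearson correlation handles identity, nulls and missing values", {
  x <- rnorm(50)
  expect_equal(pearson_r(x, x)$r, 1)
  set.seed(41)
  big <- pearson_r(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(big$r), 0.03)
  # pairwise deletion
  y <- x + rnorm(50, 0, 0.3)
  y[c(3, 7)] <- NA
  pr <- pearson_r(x, y)
  expect_equal(pr$n, 48)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("Holm adjustment matches hand-worked examples and its invariants", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.001, 0.001, 0.5)),
               c(0.003, 0.003, 0.5))
  # order invariance and domination of the raw values
  set.seed(42)
  p <- runif(12)
  perm <- sample(12)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(holm_adjust(p) <= 1))
})

test_that("Williams' test is antisymmetric and matches an independent formula", {
  # equal correlations give t = 0
  expect_equal(williams_test(0.3, 0.3, 0.5, 100)$t, 0)
  # swapping the two dependent correlations flips the sign
  w1 <- williams_test(0.4, 0.1, 0.3, 80)
  w2 <- williams_test(0.1, 0.4, 0.3, 80)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  # independent transcription of the textbook formula
  oracle <- function(rjk, rjh, rkh, n) {
    R <- 1 - rjk^2 - rjh^2 - rkh^2 + 2 * rjk * rjh * rkh
    rb <- (rjk + rjh) / 2
    (rjk - rjh) * sqrt(((n - 1) * (1 + rkh)) /
      (2 * R * (n - 1) / (n - 3) + rb^2 * (1 - rkh)^3))
  }
  got <- williams_test(-0.21, -0.03, 0.3, 279)
  expect_equal(got$t, oracle(-0.21, -0.03, 0.3, 279), tolerance = 1e-10)
  expect_equal(got$df, 276)
  expect_error(williams_test(0.99, -0.99, 0.99, 50), "singular")
})

test_that("Spearman-Brown correction follows the step-up formula", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
})

test_that("pooled Cohen's d reproduces printed effect sizes and is antisymmetric", {
  expect_equal(round(cohens_d(2.44, 0.9, 272, 1.92, 0.62, 81)$d, 2),
               0.62)
  expect_equal(round(cohens_d(0.88, 0.1, 272, 0.87, 0.1, 81)$d, 2),
               0.10)
  expect_equal(cohens_d(1, 1, 30, 1, 1, 30)$d, 0)
  d1 <- cohens_d(2.44, 0.9, 272, 1.92, 0.62, 81)
  d2 <- cohens_d(1.92, 0.62, 81, 2.44, 0.9, 272)
  expect_equal(d1$d, -d2$d)
  expect_equal(d1$ci_low, -d2$ci_up)
  expect_equal(d1$ci_up, -d2$ci_low)
  expect_true(d1$ci_low <= d1$d && d1$d <= d1$ci_up)
})

test_that("Welch test from summaries matches its closed form", {
  expect_equal(welch_t(1, 1, 30, 1, 1, 30)$t, 0)
  # equal sizes and spreads reduce to the pooled df
  expect_equal(welch_t(1.2, 0.8, 25, 1.0, 0.8, 25)$df, 48)
  # printed group summaries give t ~ 5.9 on ~190 df
  wt <- welch_t(2.44, 0.9, 272, 1.92, 0.62, 81)
  expect_equal(wt$t, 5.9, tolerance = 0.01)
  expect_equal(wt$df, 190, tolerance = 0.01)
  expect_lt(wt$p, 0.001)
})

test_that("mixed ANOVA reproduces a hand-computed split-plot table", {
  d <- data.frame(subject_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
                  group = rep(c("g1", "g1", "g2", "g2"), each = 2),
                  task = rep(c("t1", "t2"), 4),
                  value = c(10, 12, 14, 16, 20, 26, 24, 22))
  # by hand: SS_group 200, SS_subj(group) 16, SS_task 8, SS_int 0,
  # SS_resid 16, SS_total 240
  a <- mixed_anova(d)
  expect_equal(a$F[a$effect == "group"], 25, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "task"], 1, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "group:task"], 0, tolerance = 1e-10)
  expect_equal(a$eta2[a$effect == "group"], 200 / 240, tolerance = 1e-10)
  expect_equal(a$eta2[a$effect == "task"], 8 / 240, tolerance = 1e-10)
  expect_equal(a$eta2_partial[a$effect == "group"], 200 / 216,
               tolerance = 1e-10)
  expect_equal(a$df1, c(1, 1, 1))
  expect_equal(a$df2, c(2, 2, 2))
})

test_that("mixed ANOVA degenerate cases behave", {
  # zero within-subject difference -> task SS exactly zero
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:8), each = 2),
                  group = rep(c("g1", "g2"), each = 8),
                  task = rep(c("t1", "t2"), 8),
                  value = rep(c(3, 5, 4, 6, 7, 2, 8, 1), each = 2))
  a <- mixed_anova(d)
  expect_equal(a$eta2[a$effect == "task"], 0, tolerance = 1e-12)
  # subjects with a missing cell are dropped and counted
  d2 <- d[-1, ]
  a2 <- mixed_anova(d2)
  expect_equal(attr(a2, "n_subjects"), 7)
  expect_equal(attr(a2, "n_dropped"), 1)
})

test_that("mixed ANOVA holds its type-I error rate under the null", {
  set.seed(43)
  n_rep <- 400
  rejections <- vapply(seq_len(n_rep), function(i) {
    n <- 24
    d <- data.frame(subject_id = rep(sprintf("s%d", 1:n), each = 2),
                    group = rep(c("g1", "g2"), each = n),
                    task = rep(c("t1", "t2"), n),
                    value = rnorm(2 * n))
    mixed_anova(d)$p[1] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  # 400 replicates: 3 binomial Sds around 0.05 is ~ +/- 0.033
  expect_gt(rate, 0.017)
  expect_lt(rate, 0.083)
})

test_that("split-half reliability applies the step-up formula per cell", {
  set.seed(44)
  cfg <- small_config(14, 0)
  cfg$groups$dys <- NULL
  pop <- sample_population(cfg)
  trials <- simulate_dataset(pop)
  pre <- preprocess_trials(trials)
  rel <- split_half_reliability(pre$trials, n_restarts = 2,
                                reltol = 1e-4, maxit = 200, seed = 3)
  expect_setequal(rel$parameter, c("a", "v", "t0"))
  expect_setequal(rel$task, c("symbolic", "nonsymbolic"))
  expect_equal(rel$r_sb, 2 * rel$r / (1 + rel$r))
  expect_true(all(rel$n_subjects + rel$n_failed == 14))
})
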