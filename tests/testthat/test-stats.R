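test_that("one-way ANOVA matches the brute-force SS oracle", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    g <- rep(letters[1:k], times = sample(3:6, k, TRUE))
    y <- rnorm(length(g)) + as.integer(factor(g)) * runif(1, 0, 2)
    res <- one_way_anova(y, g)
    expect_equal(res$F, oracle_one_way_f(y, g))
    expect_equal(res$p, pf(res$F, res$df_num, res$df_den, lower.tail = FALSE))
  }
})

test_that("one-way ANOVA degenerate conventions", {
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$F, 0)
  res <- one_way_anova(c(0, 0, 1, 1), c("a", "a", "b", "b"))
  expect_identical(res$F, Inf)
  expect_identical(res$p, 0)
  expect_error(one_way_anova(1:3, c("a", "a", "a")), "2 groups")
})

test_that("ANOVA sums of squares decompose the total (conservation)", {
  set.seed(43)
  y <- rnorm(24) + rep(c(0, 1, 3), each = 8)
  g <- rep(c("a", "b", "c"), each = 8)
  grand <- mean(y)
  ss_tot <- sum((y - grand)^2)
  ss_b <- sum(tapply(y, g, function(x) length(x) * (mean(x) - grand)^2))
  ss_w <- sum(unlist(tapply(y, g, function(x) (x - mean(x))^2)))
  expect_equal(ss_b + ss_w, ss_tot)
  expect_equal(one_way_anova(y, g)$F, (ss_b / 2) / (ss_w / 21))
})

test_that("mixed ANOVA agrees with closed-form split-plot F ratios on a balanced design", {
  set.seed(47)
  n_subj <- 8; reps <- 2
  subj <- rep(1:(2 * n_subj), each = 3 * reps)
  group <- rep(c("child", "adult"), each = n_subj * 3 * reps)
  stage <- rep(rep(c(33, 66, 99), each = reps), 2 * n_subj)
  y <- rnorm(2 * n_subj, sd = 1.5)[subj] - 0.02 * stage +
    0.4 * (group == "child") + rnorm(length(subj))
  res <- mixed_anova(y, subj, data.frame(group = group, stage = stage))
  orc <- oracle_split_plot(y, subj, group, stage)
  expect_equal(res$F[res$effect == "group"], orc$F_group)
  expect_equal(res$F[res$effect == "stage"], orc$F_stage)
  expect_equal(res$F[res$effect == "group:stage"], orc$F_int)
  expect_equal(res$df_den[res$effect == "group"], 2 * n_subj - 2)
})

test_that("mixed ANOVA p-values are consistent with their F distribution", {
  set.seed(53)
  subj <- rep(1:12, each = 6)
  group <- rep(c("a", "b"), each = 36)
  stage <- rep(rep(1:3, each = 2), 12)
  y <- rnorm(12)[subj] + rnorm(72)
  res <- mixed_anova(y, subj, data.frame(group = group, stage = stage))
  expect_equal(res$p, pf(res$F, res$df_num, res$df_den, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("mixed ANOVA rejects confounded and unreplicated designs", {
  subj <- rep(1:4, each = 3)
  y <- rnorm(12)
  expect_error(
    mixed_anova(y, subj, data.frame(g = factor(subj), s = rep(1:3, 4))),
    "confounded")
  expect_error(
    mixed_anova(y, subj, data.frame(group = rep(c("a", "b"), each = 6),
                                    stage = rep(1:3, 4)),
                interaction = TRUE),
    "single observation")
  # the same design is fine without the interaction
  res <- mixed_anova(y, subj, data.frame(group = rep(c("a", "b"), each = 6),
                                         stage = rep(1:3, 4)),
                     interaction = FALSE)
  expect_true(all(c("group", "stage") %in% res$effect))
})

test_that("triangle test matches the recursive-ratio oracle to 1e-12", {
  for (n in c(10, 30, 45)) {
    for (k in c(0, 1, floor(n / 3), floor(n / 2), n)) {
      expect_equal(triangle_test(k, n)$p_value, oracle_triangle_tail(k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("triangle test classifies reference session counts and extremes", {
  expect_false(triangle_test(5, 30)$significant)
  expect_false(triangle_test(9, 30)$significant)
  perfect <- triangle_test(30, 30)
  expect_true(perfect$significant)
  expect_equal(perfect$p_value, (1 / 3)^30)
  # exact one-sided minimum at n = 30, alpha = 0.05
  tt <- triangle_test(5, 30)
  expect_equal(tt$min_correct_for_alpha, 15)
  expect_true(triangle_test(15, 30)$significant)
  expect_false(triangle_test(14, 30)$significant)
  # unattainable at tiny panels
  expect_true(is.na(triangle_test(2, 2, alpha = 0.05)$min_correct_for_alpha))
  expect_error(triangle_test(3, 30, alpha = 1.2), "alpha")
  expect_error(triangle_test(31, 30), "n_correct")
})
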