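test_that("AUT scores follow their defining formulas", {
  # 5 ideas all rated (4, 4) across 3 categories: creativity sum 20
  ideas <- data.frame(rater1 = rep(4, 5), rater2 = rep(4, 5),
                      category = c("a", "a", "b", "c", "c"))
  s <- score_aut(ideas)
  expect_equal(s$fluency, 5L)
  expect_equal(s$flexibility, 3L)
  expect_equal(s$creativity_sum, 20)
  expect_equal(s$creativity_mean, 4)
  expect_equal(s$odt, 7)

  one <- score_aut(data.frame(rater1 = 3, rater2 = 5, category = "a"))
  expect_equal(one$creativity_sum, 4)
  expect_equal(one$odt, 5)

  expect_warning(zero <- score_aut(ideas[0, ]), "no ideas")
  expect_equal(zero$odt, 0)
  expect_true(is.na(zero$creativity_mean))

  expect_error(score_aut(data.frame(rater1 = 6, rater2 = 1, category = "a")),
               "1, 5")
})

test_that("ODT is invariant to idea order", {
  ideas <- data.frame(rater1 = c(2, 5, 3), rater2 = c(4, 5, 1),
                      category = c("x", "y", "x"))
  expect_equal(score_aut(ideas)$odt, score_aut(ideas[c(3, 1, 2), ])$odt)
})

test_that("consistency ICC matches its mean-squares definition", {
  r1 <- c(3, 1, 4, 5, 2, 4, 3, 5)
  expect_equal(icc_consistency(r1, r1)$single, 1)
  expect_equal(icc_consistency(r1, r1 + 0.7)$single, 1)  # additive shift
  expect_equal(icc_consistency(r1, r1 + 0.7)$average, 1)

  # oracle: two-way ANOVA table mean squares on simulated ratings
  set.seed(42)
  truth <- rnorm(20, 3, 1)
  x1 <- truth + rnorm(20)
  x2 <- truth + rnorm(20)
  long <- data.frame(y = c(x1, x2),
                     item = factor(rep(1:20, 2)),
                     rater = factor(rep(1:2, each = 20)))
  ms <- anova(aov(y ~ item + rater, data = long))[["Mean Sq"]]
  ms_r <- ms[1]; ms_e <- ms[3]
  icc <- icc_consistency(x1, x2)
  expect_equal(icc$single, (ms_r - ms_e) / (ms_r + ms_e), tolerance = 1e-10)
  expect_equal(icc$average, (ms_r - ms_e) / ms_r, tolerance = 1e-10)

  expect_warning(flat <- icc_consistency(rep(2, 5), rep(2, 5)), "undefined")
  expect_true(is.nan(flat$single))
})

test_that("index correlations are Spearman on log-transformed scores", {
  sc <- data.frame(flexibility = 1:8, fluency = (1:8)^2,
                   creativity_sum = exp(1:8), odt = 2 * (1:8) + 1)
  ct <- correlate_indices(sc)
  expect_true(all(ct$rho == 1))   # identical ranks everywhere

  sc$odt <- rev(sc$odt)
  ct2 <- correlate_indices(sc)
  expect_equal(ct2$rho["odt", "fluency"], -1)

  # oracle: rank-then-Pearson on a simulated Gaussian copula
  set.seed(5)
  x <- rnorm(58)
  y <- 0.6 * x + 0.8 * rnorm(58)
  sc3 <- data.frame(flexibility = exp(x), fluency = exp(y),
                    creativity_sum = exp(x + y), odt = x - y)
  ct3 <- correlate_indices(sc3)
  expect_equal(ct3$rho["flexibility", "fluency"],
               cor(rank(x), rank(y)), tolerance = 1e-12)

  # zero values fall back to log1p and are reported
  sc4 <- sc
  sc4$fluency[1] <- 0
  expect_equal(correlate_indices(sc4)$log_substituted, "fluency")
})

test_that("median split yields equal deterministic halves", {
  sp <- median_split(c(P1 = 1, P2 = 2, P3 = 3, P4 = 4))
  expect_equal(as.character(sp$group), c("low", "low", "high", "high"))

  expect_warning(tie <- median_split(c(A = 5, B = 5, C = 5, D = 5)), "tie")
  expect_equal(as.character(tie$group[tie$participant %in% c("A", "B")]),
               c("low", "low"))

  set.seed(9)
  scores <- setNames(runif(58), sprintf("P%02d", 1:58))
  sp58 <- median_split(scores)
  expect_equal(unname(table(sp58$group)), c(29L, 29L), ignore_attr = TRUE)
  expect_identical(sp58, median_split(scores))  # deterministic

  expect_warning(odd <- median_split(c(A = 1, B = 2, C = 3)), "odd")
  expect_equal(sum(odd$group == "low"), 2)
})

test_that("pooled t-test and Cohen's d behave and swap sign together", {
  same <- compare_groups(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)

  set.seed(13)
  x <- rnorm(1000, 0); y <- rnorm(1000, 1)
  cmp <- compare_groups(y, x)
  expect_lt(abs(cmp$d - 1), 3 * sqrt(2 / 1000))
  expect_equal(cmp$df, 1998)

  swapped <- compare_groups(x, y)
  expect_equal(swapped$t, -cmp$t)
  expect_equal(abs(swapped$d), abs(cmp$d))

  expect_warning(deg <- compare_groups(c(0, 0), c(1, 1)), "degenerate")
  expect_true(deg$degenerate)
  expect_equal(deg$t, -Inf)
})
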