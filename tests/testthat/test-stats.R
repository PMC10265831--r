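test_that("Lilliefors test holds its nominal level and has power", {
  set.seed(71)
  # level under the null (normal data, estimated parameters)
  rej <- replicate(1000, lilliefors_test(rnorm(20))$reject)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
  # power against a clearly skewed alternative
  rej_exp <- replicate(100, lilliefors_test(rexp(50))$reject)
  expect_gt(mean(rej_exp), 0.8)
  # degenerate constant sample is flagged and rejected
  r <- lilliefors_test(rep(1, 10))
  expect_true(r$degenerate)
  expect_true(r$reject)
  expect_error(lilliefors_test(1:2), "at least 3")
})

test_that("normality gate passes joint normals at the expected rate", {
  set.seed(72)
  # two groups of n = 20 from one normal: joint pass probability is
  # (1 - 0.05)^2 = 0.9025; assert within Monte-Carlo slack of that value
  verdicts <- replicate(300, {
    normality_gate(list(a = rnorm(20), b = rnorm(20)))$normal
  })
  expect_gt(mean(verdicts), 0.9025 - 3 * sqrt(0.9025 * 0.0975 / 300))
  expect_lt(mean(verdicts), 0.9025 + 3 * sqrt(0.9025 * 0.0975 / 300))
  # one exponential group forces a non-normal verdict in most seeds
  nn <- replicate(100, {
    normality_gate(list(a = rnorm(20), b = rexp(50)))$normal
  })
  expect_lt(mean(nn), 0.2)
  # undersized groups are excluded with a warning
  expect_warning(g <- normality_gate(list(a = rnorm(20), b = c(1, 2))),
                 "excluded")
  expect_equal(g$excluded, "b")
  # nested (region -> condition) tables flatten across all groups
  nested <- list(ctx = list(MED = rnorm(10), ISO = rnorm(10)),
                 bs = list(MED = rexp(40) * 5, ISO = rnorm(10)))
  gn <- normality_gate(nested)
  expect_equal(nrow(gn$per_group), 4)
})

test_that("omnibus branch follows the verdict and detects shifts", {
  set.seed(73)
  tab <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  expect_equal(omnibus_test(tab, TRUE)$method, "ANOVA")
  expect_equal(omnibus_test(tab, FALSE)$method, "Kruskal-Wallis")
  expect_error(omnibus_test(list(a = rnorm(5)), TRUE), "2 groups")
  # two groups only: statistic finite, both branches
  two <- list(a = rnorm(6), b = rnorm(6) + 1)
  expect_true(is.finite(omnibus_test(two, TRUE)$statistic))
  expect_true(is.finite(omnibus_test(two, FALSE)$statistic))
  # power: one group shifted by 2 SD at n = 8
  hits <- replicate(100, {
    tab <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 2))
    omnibus_test(tab, TRUE)$p.value < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("post-hoc pairs cover all pairs on the verdict's branch", {
  set.seed(74)
  tab <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8))
  pw_t <- posthoc_pairs(tab, TRUE)
  expect_equal(nrow(pw_t), 3)
  expect_true(all(pw_t$test == "t-test"))
  pw_w <- posthoc_pairs(tab, FALSE)
  expect_true(all(pw_w$test == "Mann-Whitney"))
  # t-test branch agrees with the closed-form pooled-variance computation
  x <- tab$a; y <- tab$b
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  p_oracle <- 2 * pt(-abs(tstat), length(x) + length(y) - 2)
  expect_equal(pw_t$p[pw_t$group1 == "a" & pw_t$group2 == "b"], p_oracle)
  # Mann-Whitney branch agrees with a hand-rolled normal approximation
  u_oracle <- function(x, y) {
    r <- rank(c(x, y)); n1 <- length(x); n2 <- length(y)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2; sig <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    z <- (abs(u - mu) - 0.5) / sig
    2 * pnorm(-z)
  }
  heavy <- list(a = rcauchy(12), b = rcauchy(12) + 3)
  pw_h <- posthoc_pairs(heavy, FALSE)
  expect_equal(pw_h$p, u_oracle(heavy$a, heavy$b), tolerance = 1e-10)
  expect_error(posthoc_pairs(list(a = rnorm(5), a = rnorm(5)), TRUE),
               "duplicated")
})

test_that("stronger planted shifts never raise the median post-hoc p", {
  set.seed(75)
  med_p <- sapply(c(0.5, 1.5, 3), function(shift) {
    median(replicate(60, {
      posthoc_pairs(list(a = rnorm(8), b = rnorm(8, shift)), TRUE)$p
    }))
  })
  expect_true(all(diff(med_p) <= 0))
})

test_that("boxplot summaries use linear-interpolation quantiles", {
  s <- boxplot_summary(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$q25, 25.75)
  expect_equal(s$q75, 75.25)
  expect_equal(s$p5, quantile(1:100, 0.05, names = FALSE))
  cs <- boxplot_summary(rep(4.2, 7))
  expect_true(all(unlist(cs[c("median", "mean", "q25", "q75", "p5", "p95")]) == 4.2))
  s1 <- boxplot_summary(3)
  expect_equal(s1$median, 3)
  expect_equal(s1$p95, 3)
})

test_that("compare_groups ties the tree together consistently", {
  set.seed(76)
  tab <- list(MED = rnorm(8, 0.96, 0.01), ISO_MED = rnorm(8, 0.94, 0.01),
              ISO = rnorm(8, 0.9, 0.01))
  cmp <- compare_groups(tab)
  branch <- if (cmp$normality$normal) "t-test" else "Mann-Whitney"
  expect_true(all(cmp$pairwise$test == branch))
  expected_omnibus <- if (cmp$normality$normal) "ANOVA" else "Kruskal-Wallis"
  expect_equal(cmp$omnibus$method, expected_omnibus)
  expect_named(cmp$summaries, names(tab))
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 5e-4)),
               c("", "*", "**", "***"))
})
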