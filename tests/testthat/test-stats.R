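# Statistical kernels: factorial ANOVA against a brute-force SS oracle and
# classical identities, Tukey-Kramer against the HSD formula, rank tests
# against full enumeration, proportion tests and Clopper-Pearson intervals
# against closed forms.

balanced_design <- function(levels_list, n_per_cell, seed = 1, effect = NULL) {
  cells <- expand.grid(levels_list, stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), , drop = FALSE]
  d$unit_id <- rep(seq_len(n_per_cell), times = nrow(cells))
  withr::with_seed(seed, d$value <- rnorm(nrow(d)))
  if (!is.null(effect)) d$value <- d$value + effect(d)
  rownames(d) <- NULL
  d
}

test_that("one-factor two-level ANOVA F equals the squared pooled t statistic", {
  d <- balanced_design(list(g = c("a", "b")), 15, seed = 3)
  fit <- fit_factorial_anova(d, "value", "g")
  tt <- t.test(value ~ g, data = d, var.equal = TRUE)
  expect_equal(fit$table$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$table$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("balanced factorial sums of squares match the direct decomposition oracle", {
  d <- balanced_design(list(f1 = c("x", "y", "z"), f2 = c("lo", "hi"),
                            f3 = c("p", "q")), 4, seed = 11)
  fit <- fit_factorial_anova(d, "value", c("f1", "f2", "f3"))
  orc <- oracle_anova_ss(d, "value", c("f1", "f2", "f3"))
  for (term in setdiff(fit$table$term, "Residuals")) {
    expect_equal(fit$table$sum_sq[fit$table$term == term], orc[[term]],
                 tolerance = 1e-8)
  }
  expect_equal(fit$table$sum_sq[fit$table$term == "Residuals"], orc$error,
               tolerance = 1e-8)
  expect_equal(sum(fit$table$sum_sq), orc$total, tolerance = 1e-8)
  # factor-order invariance of the SS on balanced data
  fit2 <- fit_factorial_anova(d, "value", c("f3", "f1", "f2"))
  expect_equal(sort(fit2$table$sum_sq), sort(fit$table$sum_sq), tolerance = 1e-10)
})

test_that("degrees-of-freedom identities hold for every fitted design", {
  for (spec in list(list(l = list(a = c("1", "2"), b = c("u", "v", "w")), n = 3),
                    list(l = list(a = c("1", "2", "3", "4")), n = 5))) {
    d <- balanced_design(spec$l, spec$n, seed = 7)
    fit <- fit_factorial_anova(d, "value", names(spec$l))
    expect_equal(fit$total_df, nrow(d) - 1)
    expect_equal(sum(fit$table$df), fit$total_df)
    expect_equal(fit$error_df,
                 fit$total_df - sum(fit$table$df[fit$table$term != "Residuals"]))
  }
})

test_that("empty cells and unbalanced designs are rejected with names", {
  d <- balanced_design(list(a = c("1", "2"), b = c("u", "v")), 3)
  expect_error(fit_factorial_anova(d[d$a != "1" | d$b != "u", ], "value",
                                   c("a", "b")), "empty design cells: 1:u")
  d2 <- d[-1, ]
  expect_error(fit_factorial_anova(d2, "value", c("a", "b")), "unbalanced")
  expect_s3_class(fit_factorial_anova(d2, "value", c("a", "b"),
                                      allow_unbalanced = TRUE)$table,
                  "data.frame")
})

test_that("Tukey-Kramer reduces to Tukey HSD at equal cell sizes", {
  d <- balanced_design(list(g = c("a", "b", "c", "d")), 8, seed = 21,
                       effect = function(d) (d$g == "c") * 1.2)
  fit <- fit_factorial_anova(d, "value", "g")
  tk <- tukey_kramer(fit)
  hsd <- TukeyHSD(aov(value ~ g, data = d))$g
  key <- paste(tk$cell2, tk$cell1, sep = "-")
  expect_equal(tk$p_adj, unname(hsd[key, "p adj"]), tolerance = 1e-8)
  expect_equal(-tk$diff, unname(hsd[key, "diff"]), tolerance = 1e-12)
})

test_that("Tukey-Kramer handles degenerate and monotone cases", {
  d <- balanced_design(list(g = c("a", "b")), 6, seed = 2)
  d$value <- rep(1:6, 2)  # identical cell means
  fit <- fit_factorial_anova(d, "value", "g")
  tk <- tukey_kramer(fit)
  expect_equal(tk$q, 0)
  expect_equal(tk$p_adj, 1)
  # adjusted p decreases monotonically in |mean difference| at fixed MSE, n
  q <- seq(0.1, 6, by = 0.1)
  p <- ptukey(q, nmeans = 4, df = 30, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("rank tests match full-enumeration p-values for small samples", {
  withr::with_seed(14, {
    for (i in 1:10) {
      x <- rnorm(6)
      y <- rnorm(7) + 0.5
      got <- rank_tests(x, y)
      expect_equal(got$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
      xp <- rnorm(8)
      yp <- xp + rnorm(8, 0.3)
      gotp <- rank_tests(xp, yp, paired = TRUE)
      expect_equal(gotp$p_value, oracle_signedrank_p(xp, yp), tolerance = 1e-12)
    }
  })
})

test_that("rank tests handle ties and degenerate inputs", {
  expect_warning(r <- rank_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE), "zero")
  expect_equal(r$p_value, 1)
  expect_warning(r2 <- rank_tests(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(r2$p_value, 1)
  expect_error(rank_tests(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("rank-sum rejection rate tracks a Monte-Carlo power oracle", {
  withr::with_seed(9, {
    shift <- 1
    n <- 25
    reps <- 400
    rej <- mean(replicate(reps, {
      rank_tests(rnorm(n), rnorm(n) + shift)$p_value < 0.05
    }))
    # independent oracle: same design through wilcox.test on fresh draws
    rej_oracle <- mean(replicate(reps, {
      suppressWarnings(stats::wilcox.test(rnorm(n), rnorm(n) + shift)$p.value) < 0.05
    }))
    se <- sqrt(rej_oracle * (1 - rej_oracle) / reps)
    expect_lt(abs(rej - rej_oracle), 4 * max(se, 0.01))
  })
})

test_that("proportion test and Clopper-Pearson interval match closed forms", {
  # equal proportions give a null statistic
  pt <- proportion_test(20, 100, 10, 50)
  expect_equal(pt$statistic, 0, tolerance = 1e-12)
  expect_equal(pt$p_value, 1, tolerance = 1e-12)
  expect_error(proportion_test(11, 10, 1, 10), "k <= n")
  # degenerate pooled proportion
  expect_equal(proportion_test(0, 10, 0, 20)$p_value, 1)
  # boundary CI
  expect_equal(unname(binomial_ci(10, 10)["upper"]), 1)
  # beta-quantile oracle for (8, 10)
  ci <- binomial_ci(8, 10)
  expect_equal(unname(ci["lower"]), qbeta(0.025, 8, 3), tolerance = 1e-10)
  expect_equal(unname(ci["upper"]), qbeta(0.975, 9, 2), tolerance = 1e-10)
  expect_error(binomial_ci(11, 10), "k <= n")
  # chi-square value against the textbook formula on a generic table
  k1 <- 30; n1 <- 90; k2 <- 45; n2 <- 100
  p <- (k1 + k2) / (n1 + n2)
  want <- (k1 - n1 * p)^2 / (n1 * p) + (n1 - k1 - n1 * (1 - p))^2 / (n1 * (1 - p)) +
    (k2 - n2 * p)^2 / (n2 * p) + (n2 - k2 - n2 * (1 - p))^2 / (n2 * (1 - p))
  expect_equal(proportion_test(k1, n1, k2, n2)$statistic, want, tolerance = 1e-10)
})
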