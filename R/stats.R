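# Statistical machinery: balanced fixed-effects full-factorial ANOVA with
# Tukey-Kramer post hoc comparisons (studentized-range adjustment), rank
# tests, a 2x2 proportion test, and Clopper-Pearson binomial intervals.

#' Fit a full-factorial fixed-effects ANOVA
#'
#' Observations are unit-level cell means (neuron identity is not a factor,
#' which reproduces the degrees-of-freedom arithmetic of population analyses
#' in which each neuron contributes one value per cell). All main effects
#' and interactions are fitted. The design must be balanced (equal cell
#' counts, none empty) unless `allow_unbalanced = TRUE`; on balanced data the
#' sequential sums of squares coincide with the marginal ones, so the
#' decomposition is unambiguous.
#'
#' @param data Data frame of observations.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (each with at
#'   least two levels).
#' @param allow_unbalanced If `TRUE`, unbalanced (but non-empty-cell)
#'   designs are fitted by least squares with sequential sums of squares.
#' @return A list of class `anova_fit` with `table` (term, df, sum_sq,
#'   mean_sq, statistic, p_value, plus Residuals), `total_df`, `error_df`,
#'   `mse`, `cell_means` (per-cell mean and n), `factors`, and the fitted
#'   `aov` object.
#' @export
fit_factorial_anova <- function(data, response = "value", factors,
                                allow_unbalanced = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), length(factors) >= 1)
  for (f in factors) data[[f]] <- factor(data[[f]])
  for (f in factors) {
    if (nlevels(data[[f]]) < 2) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
    }
  }
  cell <- interaction(data[factors], drop = FALSE, sep = ":")
  counts <- table(cell)
  if (any(counts == 0)) {
    stop(sprintf("empty design cells: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")),
         call. = FALSE)
  }
  balanced <- length(unique(counts)) == 1
  if (!balanced && !allow_unbalanced) {
    stop("design is unbalanced; set allow_unbalanced = TRUE to fit anyway",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)[[1]]
  term <- trimws(rownames(sm))
  tab <- data.frame(term = term, df = sm$Df, sum_sq = sm$`Sum Sq`,
                    mean_sq = sm$`Mean Sq`, statistic = sm$`F value`,
                    p_value = sm$`Pr(>F)`, row.names = NULL)
  err <- tab[tab$term == "Residuals", ]
  total_df <- nrow(data) - 1L
  if (sum(tab$df) != total_df) {
    stop("degrees-of-freedom identity violated; design is degenerate",
         call. = FALSE)
  }
  cm <- stats::aggregate(data[[response]], by = list(cell = cell),
                         FUN = function(v) c(mean = mean(v), n = length(v)))
  cell_means <- data.frame(cell = as.character(cm$cell),
                           mean = cm$x[, "mean"], n = cm$x[, "n"])
  lv <- do.call(rbind, strsplit(cell_means$cell, ":", fixed = TRUE))
  colnames(lv) <- factors
  cell_means <- cbind(cell_means, as.data.frame(lv))
  structure(list(table = tab, total_df = total_df, error_df = err$df,
                 mse = err$mean_sq, cell_means = cell_means,
                 factors = factors, balanced = balanced, fit = fit),
            class = "anova_fit")
}

#' Tukey-Kramer post hoc comparisons on ANOVA cell means
#'
#' For each requested pair of design cells, the standard error is
#' `sqrt(MSE / 2 * (1 / n1 + 1 / n2))`, the studentized-range statistic is
#' `q = |mean1 - mean2| / SE`, and the adjusted p-value comes from the
#' studentized-range distribution with the family's group count (all cells
#' of the full interaction) and the error degrees of freedom. With equal
#' cell sizes this reduces to Tukey's HSD.
#'
#' @param anova An `anova_fit` from [fit_factorial_anova()].
#' @param comparisons Either `NULL` (all cell pairs) or a two-column matrix /
#'   data frame of cell labels (as in `anova$cell_means$cell`).
#' @return Data frame of class `posthoc_result` with one row per comparison:
#'   `cell1`, `cell2`, `diff` (mean1 - mean2), `se`, `q`, `p_adj`.
#' @export
tukey_kramer <- function(anova, comparisons = NULL) {
  stopifnot(inherits(anova, "anova_fit"))
  cm <- anova$cell_means
  k <- nrow(cm)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(cm$cell, 2))
  }
  comparisons <- as.matrix(comparisons)
  i1 <- match(comparisons[, 1], cm$cell)
  i2 <- match(comparisons[, 2], cm$cell)
  if (any(is.na(i1)) || any(is.na(i2))) {
    stop("unknown cell label in comparisons", call. = FALSE)
  }
  skip <- cm$n[i1] == 0 | cm$n[i2] == 0
  diff <- cm$mean[i1] - cm$mean[i2]
  se <- sqrt(anova$mse / 2 * (1 / cm$n[i1] + 1 / cm$n[i2]))
  q <- abs(diff) / se
  p <- stats::ptukey(q, nmeans = k, df = anova$error_df, lower.tail = FALSE)
  out <- data.frame(cell1 = comparisons[, 1], cell2 = comparisons[, 2],
                    diff = diff, se = se, q = q, p_adj = p)
  if (any(skip)) {
    out$diff[skip] <- NA_real_
    out$p_adj[skip] <- NA_real_
    attr(out, "skipped") <- sum(skip)
  }
  class(out) <- c("posthoc_result", "data.frame")
  out
}

# Helper: all comparisons that vary `vary` while holding the other factors
# fixed, returned as a two-column matrix of cell labels.
contrast_pairs <- function(anova, vary) {
  cm <- anova$cell_means
  others <- setdiff(anova$factors, vary)
  if (length(others) == 0) return(t(utils::combn(cm$cell, 2)))
  grp <- interaction(cm[others], drop = TRUE)
  out <- list()
  for (g in levels(grp)) {
    cells <- cm$cell[grp == g]
    if (length(cells) >= 2) out[[g]] <- t(utils::combn(cells, 2))
  }
  do.call(rbind, out)
}

#' Wilcoxon rank tests
#'
#' Two-sided Wilcoxon signed-rank (paired) or rank-sum (unpaired) test.
#' P-value policy: the exact distribution when there are no ties and fewer
#' than 50 values (the signed-rank test additionally requires no zero
#' differences); otherwise the normal approximation with continuity
#' correction. All-tied data return p = 1 with a warning.
#'
#' @param x,y Numeric samples (equal length when `paired = TRUE`).
#' @param paired Logical.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
rank_tests <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y)) {
    stop("paired test requires equal lengths", call. = FALSE)
  }
  if (paired && all(x == y)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, method = "Wilcoxon signed-rank (degenerate)"))
  }
  if (!paired && length(unique(c(x, y))) == 1) {
    warning("all values tied; p = 1")
    return(list(statistic = 0, p_value = 1, method = "Wilcoxon rank-sum (degenerate)"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, method = wt$method)
}

#' Chi-square test for two proportions
#'
#' 2x2 chi-square test without continuity correction. When the pooled
#' proportion is degenerate (0 or 1) the statistic is 0 and p = 1.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return List with `statistic`, `p_value`.
#' @export
proportion_test <- function(k1, n1, k2, n2) {
  if (k1 > n1 || k2 > n2 || any(c(k1, k2) < 0) || any(c(n1, n2) < 1)) {
    stop("require 0 <= k <= n and n >= 1", call. = FALSE)
  }
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) return(list(statistic = 0, p_value = 1))
  pt <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  list(statistic = unname(pt$statistic), p_value = pt$p.value)
}

#' Clopper-Pearson binomial confidence interval
#'
#' @param k Number of successes.
#' @param n Number of trials (`k <= n`).
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, level = 0.95) {
  if (k > n || k < 0 || n < 1) stop("require 0 <= k <= n and n >= 1", call. = FALSE)
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' @export
print.anova_fit <- function(x, ...) {
  cat(sprintf("Full-factorial ANOVA: %s | total d.o.f. = %d, error d.o.f. = %d\n",
              paste(x$factors, collapse = " x "), x$total_df, x$error_df))
  print(x$table, row.names = FALSE)
  invisible(x)
}
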