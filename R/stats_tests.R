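# Statistical procedures for the cohort analyses: 2x2 contingency analysis
# with sample odds ratio and Woolf interval, two-way absolute-agreement ICC,
# Kruskal-Wallis / Mann-Whitney group comparisons with Bonferroni
# correction, per-ear variance comparisons, and Pearson correlation.

#' Fisher's exact test on a 2x2 table with the sample odds ratio
#'
#' Rows are exposure (e.g. hydrops present/absent), columns outcome (e.g.
#' unstable/stable hearing). Reports the sample (cross-product) odds ratio
#' `a*d / (b*c)` together with the two-sided exact p-value computed by
#' hypergeometric probability-mass summation (all tables with the observed
#' margins whose probability does not exceed the observed table's).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `odds_ratio`, `p`, and `zero_cell` (logical flag; the
#'   odds ratio is `Inf` or 0 when a cell is empty, no continuity correction
#'   is applied).
#' @export
#' @examples
#' fisher_exact(matrix(c(15, 7, 23, 69), 2))  # OR 6.43, p < 0.001
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: a row or column of the table is empty", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  zero_cell <- any(tab == 0)
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  if (a * d == 0 && b * c_ > 0) or <- 0
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p = p, zero_cell = zero_cell)
}

#' Woolf confidence interval for an odds ratio
#'
#' Normal interval on the log odds ratio with standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param tab 2x2 matrix with strictly positive cells.
#' @param level confidence level in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
#' @examples
#' or_confidence_interval(matrix(c(15, 7, 23, 69), 2))  # about (2.3, 17.7)
or_confidence_interval <- function(tab, level = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), level > 0, level < 1)
  if (any(tab <= 0)) {
    stop("zero cell: add an explicit continuity correction before calling",
         call. = FALSE)
  }
  lor <- log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

#' Intraclass correlation: two-way random effects, absolute agreement,
#' single rater
#'
#' ICC(A,1) from the two-way mean-squares decomposition: with `n` subjects
#' and `k` raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC, MSE are the subject, rater, and residual mean squares.
#' This is the agreement variant appropriate for interchangeable independent
#' operators measuring the same instances.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   complete.
#' @return ICC estimate.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 raters", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must be complete", call. = FALSE)
  grand <- mean(ratings)
  if (all(ratings == grand)) stop("zero total variance", call. = FALSE)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- ratings - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Kruskal-Wallis H test across groups
#'
#' Tie-corrected H statistic and p-value (via [stats::kruskal.test()]).
#'
#' @param groups list of numeric vectors, one per group (>= 2 nonempty
#'   groups).
#' @return data frame row: `statistic` ("H"), `value`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, integer(1)) > 0))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) stop("degenerate: all observations identical",
                                    call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  data.frame(statistic = "H", value = unname(kt$statistic),
             df = unname(kt$parameter), p = kt$p.value)
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test for each requested pair
#' of groups; adjusted p-values are `min(1, p * family)` where `family`
#' defaults to the number of comparisons.
#'
#' @param groups named list of numeric vectors.
#' @param pairs list of length-2 character vectors naming the comparisons;
#'   defaults to all pairs.
#' @param family Bonferroni family size; defaults to `length(pairs)`.
#' @return data frame: `group1`, `group2`, `U`, `p`, `p_adj`, `family`.
#' @export
mann_whitney_posthoc <- function(groups, pairs = NULL, family = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(pairs)) {
    nm <- names(groups)
    pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  family <- family %||% length(pairs)
  out <- lapply(pairs, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                                              exact = NULL))
    data.frame(group1 = pr[1], group2 = pr[2], U = unname(wt$statistic),
               p = wt$p.value, p_adj = bonferroni(wt$p.value, family),
               family = family)
  })
  do.call(rbind, out)
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param family number of comparisons in the family.
#' @return `min(1, p * family)`, elementwise.
#' @export
bonferroni <- function(p, family) pmin(1, p * family)

#' Per-ear longitudinal variances
#'
#' Sample variance of a value column across each ear's visits. Ears with a
#' single visit have no defined variance and are dropped with a warning.
#'
#' @param cohort cohort data frame with `patient_id`, `ear` columns.
#' @param value name of the numeric column (default `"vest_ep"`).
#' @return data frame: `patient_id`, `ear`, `n_visits`, `variance`, plus any
#'   ear-level grouping columns requested via `carry`.
#' @param carry character vector of ear-level columns to aggregate with
#'   `any()` (logical) or first value.
#' @export
per_ear_variance <- function(cohort, value = "vest_ep", carry = character()) {
  stopifnot(value %in% names(cohort))
  key <- interaction(cohort$patient_id, cohort$ear, drop = TRUE)
  res <- lapply(levels(key), function(k) {
    sub <- cohort[key == k, , drop = FALSE]
    row <- data.frame(patient_id = sub$patient_id[1], ear = sub$ear[1],
                      n_visits = nrow(sub),
                      variance = if (nrow(sub) >= 2) stats::var(sub[[value]])
                                 else NA_real_)
    for (cc in carry) {
      v <- sub[[cc]]
      row[[cc]] <- if (is.logical(v)) any(v, na.rm = TRUE) else v[1]
    }
    row
  })
  res <- do.call(rbind, res)
  n_single <- sum(is.na(res$variance))
  if (n_single > 0) {
    warning(sprintf("%d single-visit ears excluded (variance undefined)",
                    n_single), call. = FALSE)
    res <- res[!is.na(res$variance), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Compare per-ear variances between two ear groups
#'
#' Mann-Whitney U test of the per-ear variances between ears flagged by a
#' logical grouping column (e.g. at least one hydrops visit, or at least one
#' unstable visit) and the rest.
#'
#' @param variances output of [per_ear_variance()] with the grouping column
#'   carried.
#' @param grouping name of the logical column splitting the ears.
#' @return data frame: `grouping`, `n_flagged`, `n_other`, `median_flagged`,
#'   `median_other`, `U`, `p`.
#' @export
variance_group_compare <- function(variances, grouping) {
  stopifnot(grouping %in% names(variances))
  flag <- as.logical(variances[[grouping]])
  v1 <- variances$variance[flag]
  v0 <- variances$variance[!flag]
  if (length(v1) == 0 || length(v0) == 0) {
    stop(sprintf("a variance group is empty under '%s'", grouping), call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(v1, v0))
  data.frame(grouping = grouping, n_flagged = length(v1), n_other = length(v0),
             median_flagged = stats::median(v1), median_other = stats::median(v0),
             U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with a two-sided test
#'
#' @param x,y numeric vectors, length >= 3, nonconstant.
#' @return data frame row: `r`, `n`, `p`.
#' @export
pearson_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  data.frame(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}
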