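# Statistical procedures: contingency analysis, ICC, rank tests, variance
# comparisons, correlation, and the Gamma log-link GLMM.

test_that("sample odds ratio and Fisher p reproduce the hydrops contingency analysis", {
  tab <- matrix(c(15, 7, 23, 69), 2)  # rows EH/no-EH, cols unstable/stable
  res <- fisher_exact(tab)
  expect_equal(round(res$odds_ratio, 2), 6.43)
  expect_lt(res$p, 0.001)
  ci <- or_confidence_interval(tab)
  expect_equal(round(ci, 1), c(2.3, 17.7))
})

test_that("degenerate and boundary contingency tables behave as specified", {
  flat <- matrix(1, 2, 2)
  res <- fisher_exact(flat)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  ci <- or_confidence_interval(flat)
  expect_equal(log(ci[1]), -log(ci[2]), tolerance = 1e-10)  # symmetric about 1
  # level -> 0 collapses onto the OR
  tab <- matrix(c(15, 7, 23, 69), 2)
  tiny <- or_confidence_interval(tab, level = 1e-9)
  expect_equal(unname(tiny[1]), unname(tiny[2]), tolerance = 1e-3)
  # zero cells
  zc <- fisher_exact(matrix(c(3, 0, 1, 5), 2))
  expect_true(zc$zero_cell)
  expect_equal(zc$odds_ratio, Inf)
  expect_error(or_confidence_interval(matrix(c(3, 0, 1, 5), 2)), "zero cell")
  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2)), "marginal")
})

test_that("Fisher p matches exhaustive enumeration on small tables", {
  set.seed(19)
  for (i in 1:80) {
    n <- sample(4:12, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, oracle_fisher_p(tab), tolerance = 1e-9,
                 label = paste(cells, collapse = ","))
  }
})

test_that("ICC(A,1) has the expected exact and invariance properties", {
  x <- rnorm(20, 50, 8)
  expect_equal(icc_agreement(cbind(x, x)), 1)
  set.seed(23)
  truth <- rnorm(200, 0, 10)
  m <- cbind(truth + rnorm(200, 0, 5), truth + rnorm(200, 0, 5))
  icc <- icc_agreement(m)
  expect_lt(abs(icc - 0.8), 0.1)
  # shift and positive scaling invariance
  expect_equal(icc_agreement(m + 100), icc, tolerance = 1e-12)
  expect_equal(icc_agreement(m * 3.7), icc, tolerance = 1e-12)
  # degenerate inputs
  expect_error(icc_agreement(matrix(5, 4, 2)), "zero total variance")
  expect_error(icc_agreement(matrix(rnorm(4), 1, 4)), ">= 2 subjects")
})

test_that("rank tests reproduce exact small-sample results and Bonferroni caps", {
  mw <- mann_whitney_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)), family = 1)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # exact two-sided p for full separation at n = (3,3)
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_true(all(bonferroni(c(0.01, 0.2), 3) <= 1))
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, "H")
  expect_lt(kw$p, 0.1)
  expect_error(kruskal_wallis(list(rep(1, 5), rep(1, 5))), "degenerate")
  # two-group KW agrees in direction with MW on the same data
  set.seed(31)
  g1 <- rnorm(20); g2 <- rnorm(20, 1)
  kw2 <- kruskal_wallis(list(g1, g2))
  mw2 <- mann_whitney_posthoc(list(a = g1, b = g2), family = 1)
  expect_equal(kw2$p < 0.05, mw2$p < 0.05)
})

test_that("Kruskal-Wallis and Pearson hold their nominal size under the null", {
  set.seed(37)
  rej_kw <- mean(replicate(500, {
    kruskal_wallis(list(rnorm(30), rnorm(30), rnorm(30)))$p < 0.05
  }))
  expect_gte(rej_kw, 0.02); expect_lte(rej_kw, 0.09)
  rej_r <- mean(replicate(500, {
    pearson_cor(rnorm(100), rnorm(100))$p < 0.05
  }))
  expect_gte(rej_r, 0.02); expect_lte(rej_r, 0.09)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x)$r, 1)
  expect_equal(pearson_cor(x, -x + 5)$r, -1)
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("per-ear variances and the group comparison behave as specified", {
  co <- data.frame(patient_id = rep(c("a", "b", "c"), c(3, 2, 1)),
                   ear = "L",
                   vest_ep = c(0.3, 0.3, 0.3, 0.2, 0.4, 0.5),
                   flag = rep(c(TRUE, FALSE, FALSE), c(3, 2, 1)))
  expect_warning(pv <- per_ear_variance(co, "vest_ep", carry = "flag"),
                 "single-visit")
  expect_equal(nrow(pv), 2)
  expect_equal(pv$variance[pv$patient_id == "a"], 0)
  expect_equal(pv$variance[pv$patient_id == "b"], 0.02)
  res <- variance_group_compare(pv, "flag")
  expect_true(is.finite(res$p))
  pv_one <- pv[pv$flag, , drop = FALSE]
  expect_error(variance_group_compare(pv_one, "flag"), "empty")
})

test_that("the variance comparison detects a 5x innovation-SD difference", {
  # focused power check at matched group sizes (14 ears each, 5 visits)
  set.seed(41)
  p_once <- function() {
    mk <- function(n_ears, sd) {
      do.call(rbind, lapply(seq_len(n_ears), function(i) {
        data.frame(patient_id = sprintf("e%02d_%g", i, sd), ear = "L",
                   vest_ep = 0.4 + cumsum(rnorm(5, 0, sd)), eh = sd > 0.02)
      }))
    }
    co <- rbind(mk(14, 0.015), mk(14, 0.075))
    pv <- per_ear_variance(co, "vest_ep", carry = "eh")
    variance_group_compare(pv, "eh")$p
  }
  power <- mean(replicate(100, p_once()) < 0.05)
  expect_gte(power, 0.8)
})

test_that("the Gamma GLMM recovers known parameters in a single large fit", {
  sim <- simulate_glmm_data(n_patients = 100, visits = 5, beta0 = log(40),
                            beta_ep = 1.5, shape = 20, seed = 13)
  fit <- fit_gamma_glmm(sim, fixed = "vest_ep")
  cf <- coef(fit)
  expect_lt(abs(cf[["(Intercept)"]] - log(40)), 0.15)
  expect_lt(abs(cf[["vest_ep"]] - 1.5), 0.3)
  expect_lt(abs(fit$shape - 20) / 20, 0.35)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_true(is.finite(fit$aic))
  ci <- confint(fit)
  expect_true(ci["vest_ep", "lower"] < 1.5 && 1.5 < ci["vest_ep", "upper"])
})

test_that("standardizing predictors changes coefficients but not the fit", {
  sim <- simulate_glmm_data(n_patients = 40, seed = 17)
  fit <- fit_gamma_glmm(sim, fixed = "vest_ep")
  aic_sc <- stats::AIC(fit$fit_scaled)
  expect_lt(abs(fit$aic - aic_sc), 1e-3)
  expect_false(isTRUE(all.equal(fit$coefficients$estimate,
                                fit$coefficients_scaled$estimate)))
  expect_equal(stats::fitted(fit$fit), stats::fitted(fit$fit_scaled),
               tolerance = 1e-4)
})

test_that("R-squared decomposition honours its structural identities", {
  expect_error(nakagawa_r2(list(var_fixed = 1)), "missing variance components")
  # zero random variance: marginal equals conditional
  r2 <- nakagawa_r2(list(var_fixed = 0.4, re_var = c(p = 0, e = 0), shape = 20))
  expect_equal(unname(r2["marginal"]), unname(r2["conditional"]))
  # intercept-only: marginal 0
  r0 <- nakagawa_r2(list(var_fixed = 0, re_var = c(p = 0.1, e = 0.05), shape = 20))
  expect_equal(unname(r0["marginal"]), 0)
  expect_gt(unname(r0["conditional"]), 0)
  # known variance partition recovered from a fit
  sim <- simulate_glmm_data(n_patients = 250, visits = 4, beta0 = log(40),
                            beta_ep = 1.5, shape = 20,
                            re_sd_patient = 0.2, re_sd_ear = 0.1, seed = 19)
  fit <- fit_gamma_glmm(sim, fixed = "vest_ep")
  truth_ep <- sim$vest_ep
  var_f_true <- stats::var(1.5 * truth_ep)
  denom <- var_f_true + 0.2^2 + 0.1^2 + trigamma(20)
  expect_lt(abs(fit$r2_marginal - var_f_true / denom), 0.05)
  expect_lt(abs(fit$r2_conditional - (var_f_true + 0.05) / denom), 0.05)
  # the lognormal observation-variance option is exposed and close
  r2l <- nakagawa_r2(fit, obs_var = "lognormal")
  expect_lt(abs(r2l["marginal"] - fit$r2_marginal), 0.02)
})

test_that("fixed effects agree with an independent Gamma GLMM fitter", {
  sim <- simulate_glmm_data(n_patients = 60, visits = 4, seed = 29)
  fit <- fit_gamma_glmm(sim, fixed = "vest_ep")
  ref <- lme4::glmer(pta4 ~ vest_ep + (1 | patient_id) + (1 | patient_id:ear),
                     data = sim, family = Gamma(link = "log"))
  expect_equal(unname(coef(fit)[c("(Intercept)", "vest_ep")]),
               unname(lme4::fixef(ref)[c("(Intercept)", "vest_ep")]),
               tolerance = 0.05)
})

test_that("non-positive responses are rejected", {
  sim <- simulate_glmm_data(n_patients = 10, seed = 1)
  sim$pta4[1] <- 0
  expect_error(fit_gamma_glmm(sim), "strictly positive")
})
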