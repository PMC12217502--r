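# Gamma log-link generalized linear mixed model for hearing level, with
# nested random intercepts (patient, and ear within patient), Wald
# inference, and Nakagawa marginal/conditional R-squared.

#' Fit a Gamma log-link GLMM for hearing level
#'
#' Models a positive hearing outcome (by default the 4-frequency pure tone
#' average) as Gamma-distributed with a log link in the fixed effects, with
#' random intercepts for patient and for ear within patient, fitted by
#' Laplace-approximation maximum likelihood via [glmmTMB::glmmTMB()].
#' Coefficients are reported on the log (linear-predictor) scale both raw
#' and with continuous predictors standardized (z-scored), the latter for
#' coefficient-plot comparability across predictors.
#'
#' @param data data frame of instances.
#' @param fixed character vector of fixed-effect column names; the vestibular
#'   E/P ratio (`"vest_ep"`) is the predictor of primary interest.
#' @param response name of the positive response column.
#' @param patient,ear names of the grouping columns.
#' @param obs_var observation-level variance used in the R-squared
#'   decomposition on the log scale: `"trigamma"` (default,
#'   `trigamma(shape)`) or `"lognormal"` (`log(1 + 1/shape)`).
#' @return object of class `earfluid_glmm`: the underlying fits plus
#'   coefficient tables (`coefficients`, `coefficients_scaled` with columns
#'   estimate / se / t / p), `shape` (Gamma shape, the reciprocal of the
#'   squared residual scale), random-intercept variances `re_var`, `aic`,
#'   `r2_marginal`, `r2_conditional`, and a `singular` flag (a singular fit
#'   reports the offending variance as 0 with a warning).
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_glmm_data(n_patients = 30, seed = 2)
#' fit <- fit_gamma_glmm(sim, fixed = "vest_ep")
#' summary(fit)
#' }
fit_gamma_glmm <- function(data, fixed = "vest_ep", response = "pta4",
                           patient = "patient_id", ear = "ear",
                           obs_var = c("trigamma", "lognormal")) {
  obs_var <- match.arg(obs_var)
  stopifnot(is.data.frame(data), all(c(fixed, response, patient, ear) %in% names(data)))
  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("response must be strictly positive and finite for a Gamma model",
         call. = FALSE)
  }
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s) + (1 | %s:%s)",
                                   response, paste(fixed, collapse = " + "),
                                   patient, patient, ear))
  fit <- glmmTMB::glmmTMB(fml, data = data, family = stats::Gamma(link = "log"))
  # standardized refit: z-score continuous predictors only
  data_sc <- data
  scaled_any <- FALSE
  for (f in fixed) {
    v <- data_sc[[f]]
    if (is.numeric(v) && length(unique(v)) > 2L) {
      data_sc[[f]] <- (v - mean(v)) / stats::sd(v)
      scaled_any <- TRUE
    }
  }
  fit_sc <- if (scaled_any) {
    glmmTMB::glmmTMB(fml, data = data_sc, family = stats::Gamma(link = "log"))
  } else fit
  coef_table <- function(f) {
    cf <- summary(f)$coefficients$cond
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               t = cf[, 3], p = cf[, 4], row.names = NULL)
  }
  shape <- 1 / stats::sigma(fit)^2
  vc <- glmmTMB::VarCorr(fit)$cond
  re_var <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  names(re_var) <- names(vc)
  singular <- any(re_var < 1e-8)
  if (singular) {
    warning("singular fit: a random-intercept variance is estimated as 0",
            call. = FALSE)
    re_var[re_var < 1e-8] <- 0
  }
  var_fixed <- stats::var(stats::predict(fit, re.form = NA, type = "link"))
  var_obs <- switch(obs_var, trigamma = trigamma(shape),
                    lognormal = log1p(1 / shape))
  denom <- var_fixed + sum(re_var) + var_obs
  out <- structure(list(
    fit = fit, fit_scaled = fit_sc,
    coefficients = coef_table(fit),
    coefficients_scaled = coef_table(fit_sc),
    formula = fml, shape = shape, re_var = re_var,
    var_fixed = var_fixed, var_obs = var_obs, obs_var_method = obs_var,
    aic = stats::AIC(fit),
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + sum(re_var)) / denom,
    singular = singular,
    n = nrow(data)
  ), class = "earfluid_glmm")
  out
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance decomposition on the link (log) scale: the marginal R-squared is
#' the fixed-effect variance over the total (fixed + random intercepts +
#' observation-level) variance; the conditional R-squared adds the random
#' intercept variances to the numerator. For the log-link Gamma model the
#' observation-level variance is `trigamma(shape)` (or `log(1 + 1/shape)`
#' with `obs_var = "lognormal"`).
#'
#' @param fit an `earfluid_glmm`, or a list with components `var_fixed`,
#'   `re_var` (numeric vector), and `shape`.
#' @param obs_var `"trigamma"` or `"lognormal"`.
#' @return named numeric `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit, obs_var = c("trigamma", "lognormal")) {
  obs_var <- match.arg(obs_var)
  comp <- if (inherits(fit, "earfluid_glmm")) fit else as.list(fit)
  needed <- c("var_fixed", "re_var", "shape")
  if (!all(needed %in% names(comp)) ||
      any(vapply(comp[needed], function(x) is.null(x) || anyNA(x), logical(1)))) {
    stop("missing variance components (need var_fixed, re_var, shape)",
         call. = FALSE)
  }
  vo <- switch(obs_var, trigamma = trigamma(comp$shape),
               lognormal = log1p(1 / comp$shape))
  denom <- comp$var_fixed + sum(comp$re_var) + vo
  c(marginal = comp$var_fixed / denom,
    conditional = (comp$var_fixed + sum(comp$re_var)) / denom)
}

#' @export
print.earfluid_glmm <- function(x, ...) {
  cat("Gamma log-link GLMM (patient and ear-within-patient intercepts)\n")
  cat(sprintf("  n = %d instances; AIC = %.1f; shape = %.2f%s\n", x$n, x$aic,
              x$shape, if (x$singular) " [singular]" else ""))
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  cf <- x$coefficients
  cat("  Fixed effects (log scale):\n")
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("    %-14s %8.4f (se %.4f), p = %.3g\n",
                cf$term[i], cf$estimate[i], cf$se[i], cf$p[i]))
  }
  invisible(x)
}

#' @export
summary.earfluid_glmm <- function(object, ...) {
  print(object)
  cat("  Random-intercept variances:\n")
  for (nm in names(object$re_var)) {
    cat(sprintf("    %-20s %.5f\n", nm, object$re_var[[nm]]))
  }
  cat("  Scaled coefficients (continuous predictors z-scored):\n")
  cs <- object$coefficients_scaled
  for (i in seq_len(nrow(cs))) {
    cat(sprintf("    %-14s %8.4f (se %.4f)\n", cs$term[i], cs$estimate[i],
                cs$se[i]))
  }
  invisible(object)
}

#' @export
coef.earfluid_glmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Wald confidence intervals for the fixed effects
#'
#' @param object an `earfluid_glmm`.
#' @param parm optional term names.
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns `lower`, `upper`.
#' @export
confint.earfluid_glmm <- function(object, parm = NULL, level = 0.95, ...) {
  cf <- object$coefficients
  if (!is.null(parm)) cf <- cf[cf$term %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(lower = cf$estimate - z * cf$se, upper = cf$estimate + z * cf$se)
  rownames(out) <- cf$term
  out
}
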