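# Stage/sex inference over the TFA metric table: linear mixed-effects
# models with a participant random intercept, likelihood-ratio tests
# against the fixed-effects-free null, and the a-priori sample-size
# computation.

#' Fit the stage + sex mixed model for one TFA metric cell
#'
#' Fits `value ~ stage + sex + (1 | participant)` by maximum likelihood
#' (ML, not REML, so the likelihood-ratio test against the null is valid),
#' with eucapnia and female as the reference levels. The null model
#' `value ~ 1 + (1 | participant)` supplies the LR test, whose statistic is
#' referred to a chi-squared distribution with 3 degrees of freedom (two
#' stage contrasts plus one sex contrast). Coefficient confidence intervals
#' and p-values are Wald (normal approximation).
#'
#' @param table Long metric table with columns participant, sex, stage,
#'   ssm_frequency_hz, vessel, component, metric_name, value.
#' @param metric_name,vessel,component,ssm_frequency Cell selectors; leave
#'   `NULL` to skip that filter (e.g. for a pre-filtered table).
#' @return An `lme_result` list: `coefficients` (term, estimate, se,
#'   ci_lo, ci_hi, p_value), `lr_p`, `loglik_full`, `loglik_null`,
#'   `n_participants`, `converged`.
#' @export
fit_stage_sex_lme <- function(table, metric_name = NULL, vessel = NULL,
                              component = NULL, ssm_frequency = NULL) {
  d <- table
  if (!is.null(metric_name)) d <- d[d$metric_name == metric_name, ]
  if (!is.null(vessel)) d <- d[d$vessel == vessel, ]
  if (!is.null(component)) d <- d[d$component == component, ]
  if (!is.null(ssm_frequency))
    d <- d[abs(d$ssm_frequency_hz - ssm_frequency) < 1e-9, ]
  if (nrow(d) == 0L)
    stop_dcatfa("no rows match the requested cell", "dcatfa_invalid_argument")
  if (length(unique(d$participant)) < 2L)
    stop_dcatfa("random intercept unidentifiable with a single participant",
                "dcatfa_invalid_argument")
  stages_per <- tapply(d$stage, d$participant,
                       function(s) length(unique(s)))
  if (sum(stages_per >= 2) < 2L)
    stop_dcatfa("need at least 2 participants observed in at least 2 stages",
                "dcatfa_invalid_argument")
  if (var(d$value) == 0)
    stop_dcatfa("zero-variance outcome", "dcatfa_invalid_argument")

  d$stage <- factor(d$stage,
                    levels = c("eucapnia", "hypocapnia", "hypercapnia"))
  d$stage <- droplevels(d$stage)
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$sex <- droplevels(d$sex)

  rhs <- c(if (nlevels(d$stage) > 1L) "stage",
           if (nlevels(d$sex) > 1L) "sex")
  if (length(rhs) == 0L)
    stop_dcatfa("no fixed-effect contrasts identifiable",
                "dcatfa_invalid_argument")
  form <- stats::as.formula(
    paste("value ~", paste(rhs, collapse = " + "), "+ (1 | participant)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  full <- suppressWarnings(
    lme4::lmer(form, data = d, REML = FALSE, control = ctrl))
  null <- suppressWarnings(
    lme4::lmer(value ~ 1 + (1 | participant), data = d, REML = FALSE,
               control = ctrl))
  df <- length(lme4::fixef(full)) - 1L
  lr_p <- lr_test(as.numeric(logLik(full)), as.numeric(logLik(null)), df)

  b <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(stats::vcov(full))))
  z <- qnorm(0.975)
  coefs <- data.frame(term = names(b), estimate = unname(b),
                      se = unname(se),
                      ci_lo = unname(b - z * se), ci_hi = unname(b + z * se),
                      p_value = 2 * pnorm(-abs(unname(b) / unname(se))))
  conv_msgs <- full@optinfo$conv$lme4$messages
  structure(list(coefficients = coefs, lr_p = lr_p,
                 loglik_full = as.numeric(logLik(full)),
                 loglik_null = as.numeric(logLik(null)),
                 n_participants = length(unique(d$participant)),
                 converged = is.null(conv_msgs)),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> LR p =", format.pval(x$lr_p), "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested models
#'
#' `p = P(chisq_df >= 2 * (loglik_full - loglik_null))`, with the statistic
#' clipped at zero (optimizer noise can leave the full fit a hair below the
#' null).
#'
#' @param loglik_full,loglik_null Maximized log-likelihoods (ML).
#' @param df Degrees of freedom (>= 1).
#' @param tol Allowed numeric deficit of the full fit. Default 1e-3.
#' @return The LR p-value.
#' @export
lr_test <- function(loglik_full, loglik_null, df, tol = 1e-3) {
  if (df < 1) stop_dcatfa("df must be >= 1", "dcatfa_invalid_argument")
  if (loglik_full < loglik_null - tol)
    stop_dcatfa("full model log-likelihood below the null: models not nested?",
                "dcatfa_invalid_argument")
  stat <- max(0, 2 * (loglik_full - loglik_null))
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' A-priori sample size for a single regression coefficient
#'
#' Large-sample normal approximation for detecting a Cohen's f-squared
#' effect: `ceil((z_{1-alpha} + z_{power})^2 / f_squared)` for a one-tailed
#' test (`z_{1-alpha/2}` for two tails). With f^2 = 0.35, alpha = 0.05 and
#' power = 0.80 (one-tailed) this returns 18.
#'
#' @param f_squared Cohen's f-squared effect size (> 0).
#' @param alpha Type-I error rate, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return Required sample size (integer).
#' @export
required_sample_size <- function(f_squared, alpha = 0.05, power = 0.80,
                                 tails = c("one", "two")) {
  tails <- match.arg(tails)
  check_scalar(f_squared, "f_squared", 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(power, "power", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  za <- if (tails == "one") qnorm(1 - alpha) else qnorm(1 - alpha / 2)
  as.integer(ceiling((za + qnorm(power))^2 / f_squared))
}
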