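.NEGATIVE_EMOTIONS <- c("anger", "disgust", "sadness")

#' Transform bounded 0-100 emotion ratings for two-part modelling
#'
#' Negative emotions (anger, disgust, sadness) are reflected and
#' log-transformed, `t = ln(101 - raw)`, so that the most intense possible
#' response (raw 100) lands exactly at `t = 0` and lower transformed values
#' mean more intense emotion. Joy uses `t = ln(raw + 1)`, so zero joy lands at
#' `t = 0`. The extreme flag is exactly `t == 0`. Fear passes through
#' untransformed (its distribution is neither skewed nor
#' boundary-inflated). The transform is a bijection on `[0, 100]`; see
#' [inverse_transform_ratings()].
#'
#' @param table ratings data.frame with at least `emotion` and `value`
#'   columns (raw 0-100).
#' @param emotion which emotion to keep and transform.
#' @return the filtered table with added columns `t` (transformed value) and
#'   `extreme` (logical).
#' @export
transform_ratings <- function(table, emotion = c("anger", "disgust", "sadness",
                                                 "joy", "fear")) {
  emotion <- match.arg(emotion)
  tab <- table[table$emotion == emotion, , drop = FALSE]
  .assert(nrow(tab) > 0, "no rows for this emotion")
  .assert(all(tab$value >= 0 & tab$value <= 100),
          "raw ratings must lie in [0, 100]")
  if (emotion %in% .NEGATIVE_EMOTIONS) {
    tab$t <- log(101 - tab$value)
    tab$extreme <- tab$value == 100
  } else if (emotion == "joy") {
    tab$t <- log(tab$value + 1)
    tab$extreme <- tab$value == 0
  } else {
    tab$t <- tab$value
    tab$extreme <- FALSE
  }
  tab
}

#' Invert the rating transformation
#'
#' @param t transformed values.
#' @param emotion emotion the transform was applied for.
#' @return raw 0-100 values.
#' @export
inverse_transform_ratings <- function(t, emotion) {
  if (emotion %in% .NEGATIVE_EMOTIONS) 101 - exp(t)
  else if (emotion == "joy") exp(t) - 1
  else t
}

#' Intraclass correlation of a Gaussian mixed model
#'
#' `ICC = tau00 / (tau00 + sigma2)`: the share of total variance attributable
#' to between-subject random intercepts.
#'
#' @param tau00 random-intercept variance (>= 0).
#' @param sigma2 residual variance (> 0).
#' @return scalar ICC in `[0, 1)`.
#' @export
icc_gaussian <- function(tau00, sigma2) {
  .assert(tau00 >= 0, "tau00 must be >= 0")
  .assert(sigma2 > 0, "sigma2 must be > 0")
  tau00 / (tau00 + sigma2)
}

#' Intraclass correlation of a logistic mixed model
#'
#' On the latent logistic scale the residual variance is fixed at
#' `pi^2 / 3 = 3.29`, so `ICC = tau00 / (tau00 + pi^2/3)`.
#'
#' @param tau00 random-intercept variance (>= 0).
#' @return scalar ICC.
#' @export
icc_logistic <- function(tau00) {
  .assert(tau00 >= 0, "tau00 must be >= 0")
  tau00 / (tau00 + pi^2 / 3)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-partition R-squared for random-intercept models:
#' `R2_marginal = var_fixed / (var_fixed + tau00 + sigma2)` (fixed effects
#' only) and `R2_conditional = (var_fixed + tau00) / (var_fixed + tau00 +
#' sigma2)` (fixed plus random). `var_fixed` is the variance of the fixed-
#' effect linear predictor over the estimation sample. The two satisfy
#' `conditional = marginal + (1 - marginal) * ICC` exactly.
#'
#' @param var_fixed variance of the fixed-effect linear predictor (>= 0).
#' @param tau00 random-intercept variance (>= 0).
#' @param sigma2 residual variance (>= 0; `pi^2/3` on the logistic latent
#'   scale).
#' @return named numeric: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(var_fixed, tau00, sigma2) {
  .assert(var_fixed >= 0 && tau00 >= 0 && sigma2 >= 0, "inputs must be >= 0")
  tot <- var_fixed + tau00 + sigma2
  .assert(tot > 0, "zero total variance")
  c(r2_marginal = var_fixed / tot, r2_conditional = (var_fixed + tau00) / tot)
}

# Wald fixed-effect table from an lme4 fit: estimate, 95% CI, p
.fixef_table <- function(fit, exponentiate = FALSE) {
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                    ci_lower = unname(b - qnorm(0.975) * se),
                    ci_upper = unname(b + qnorm(0.975) * se),
                    p = unname(p), row.names = NULL)
  if (exponentiate) {
    tab$odds_ratio <- exp(tab$estimate)
    tab$or_ci_lower <- exp(tab$ci_lower)
    tab$or_ci_upper <- exp(tab$ci_upper)
  }
  tab
}

.var_fixed <- function(fit) {
  eta <- as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  mean((eta - mean(eta))^2)  # population variance of the linear predictor
}

.subject_var <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  unname(vc$vcov[vc$grp == "subject" & vc$var1 == "(Intercept)"][1])
}

#' Fit the two-part zero-inflated Gaussian mixed model
#'
#' Splits transformed ratings into extreme (`t == 0`) and non-extreme
#' (`t > 0`) parts. The logistic mixed submodel predicts the indicator
#' "non-extreme" from `time * group` with a subject random intercept; its
#' coefficients are reported as odds ratios, so an OR below 1 on the
#' time-by-group term reads as "more extreme responses in the treated group
#' after training". The Gaussian linear mixed submodel fits `t` on the
#' non-extreme rows by maximum likelihood with the same fixed and random
#' structure. Variance components, submodel ICCs, and the Gaussian submodel's
#' marginal/conditional R-squared are reported. With no extreme responses the
#' logistic part is skipped (flagged) and the Gaussian part equals a plain
#' linear mixed model on all rows.
#'
#' @param table output of [transform_ratings()]: columns `subject`, `session`,
#'   `group`, `t`, `extreme`.
#' @param nAGQ adaptive Gauss-Hermite quadrature points for the logistic
#'   submodel (1 = Laplace). With a single scalar random effect, a generous
#'   default is cheap and gives noticeably better-calibrated Wald intervals
#'   than the Laplace approximation when the intercept variance is large.
#' @return list of class `"two_part_fit"`: `logistic` (coefficient table,
#'   `tau00`, `icc`, `converged`, `skipped`), `gaussian` (coefficient table,
#'   `sigma2`, `tau00`, `icc`, `r2_marginal`, `r2_conditional`, `converged`),
#'   `n_subjects`, `n_observations`.
#' @export
fit_two_part_zig <- function(table, nAGQ = 25) {
  .assert(all(c("subject", "session", "group", "t", "extreme") %in%
                names(table)), "table must come from transform_ratings()")
  .assert(length(unique(table$subject)) >= 2, "need >= 2 subjects")
  df <- data.frame(subject = factor(table$subject),
                   time = as.numeric(table$session),
                   group = as.numeric(table$group),
                   t = table$t, nonextreme = as.numeric(!table$extreme))
  .assert(length(unique(df$group)) > 1,
          "group indicator is constant: group terms are not estimable")
  .assert(length(unique(df$time)) > 1,
          "time indicator is constant: time terms are not estimable")
  out <- list(n_subjects = length(unique(df$subject)),
              n_observations = nrow(df))

  if (any(table$extreme)) {
    lfit <- suppressMessages(lme4::glmer(
      nonextreme ~ time * group + (1 | subject), data = df,
      family = stats::binomial(), nAGQ = nAGQ))
    tau_l <- .subject_var(lfit)
    out$logistic <- list(
      coefficients = .fixef_table(lfit, exponentiate = TRUE),
      tau00 = tau_l, sigma2 = pi^2 / 3, icc = icc_logistic(tau_l),
      converged = length(lfit@optinfo$conv$lme4$messages) == 0,
      skipped = FALSE, fit = lfit)
  } else {
    out$logistic <- list(skipped = TRUE)
  }

  pos <- df[df$nonextreme == 1, , drop = FALSE]
  .assert(nrow(pos) > 8, "too few non-extreme observations")
  gfit <- lme4::lmer(t ~ time * group + (1 | subject), data = pos,
                     REML = FALSE)
  tau_g <- .subject_var(gfit)
  sig_g <- stats::sigma(gfit)^2
  r2 <- r2_nakagawa(.var_fixed(gfit), tau_g, sig_g)
  out$gaussian <- list(
    coefficients = .fixef_table(gfit),
    sigma2 = sig_g, tau00 = tau_g, icc = icc_gaussian(tau_g, sig_g),
    r2_marginal = unname(r2["r2_marginal"]),
    r2_conditional = unname(r2["r2_conditional"]),
    converged = length(gfit@optinfo$conv$lme4$messages) == 0, fit = gfit)
  class(out) <- "two_part_fit"
  out
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat("Two-part zero-inflated Gaussian mixed model\n")
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects,
              x$n_observations))
  if (isTRUE(x$logistic$skipped)) {
    cat("  logistic submodel: skipped (no extreme responses)\n")
  } else {
    cat(sprintf("  logistic submodel: tau00 = %.3f, ICC = %.3f\n",
                x$logistic$tau00, x$logistic$icc))
    print(x$logistic$coefficients[, c("term", "odds_ratio", "or_ci_lower",
                                      "or_ci_upper", "p")], digits = 3)
  }
  cat(sprintf("  Gaussian submodel: sigma2 = %.3f, tau00 = %.3f, ICC = %.3f, R2 = %.3f / %.3f\n",
              x$gaussian$sigma2, x$gaussian$tau00, x$gaussian$icc,
              x$gaussian$r2_marginal, x$gaussian$r2_conditional))
  print(x$gaussian$coefficients[, c("term", "estimate", "ci_lower",
                                    "ci_upper", "p")], digits = 3)
  invisible(x)
}

#' Fit a plain Gaussian linear mixed model (fear-style outcomes)
#'
#' REML linear mixed model of a rating on `time * group` with a subject
#' random intercept, for outcomes with no boundary inflation, on the raw
#' 0-100 scale.
#'
#' @param table ratings data.frame with `subject`, `session`, `group`,
#'   `value` columns.
#' @param reml logical; REML (default) or ML.
#' @return list of class `"gaussian_lmm_fit"`: coefficient table, `sigma2`,
#'   `tau00`, `icc`, `r2_marginal`, `r2_conditional`, `identifiable`,
#'   `converged`, `n_subjects`, `n_observations`.
#' @export
fit_gaussian_lmm <- function(table, reml = TRUE) {
  .assert(all(c("subject", "session", "group", "value") %in% names(table)),
          "table needs subject, session, group, value columns")
  df <- data.frame(subject = factor(table$subject),
                   time = as.numeric(table$session),
                   group = as.numeric(table$group), value = table$value)
  .assert(length(unique(df$group)) > 1, "group indicator is constant")
  per_subject <- table(df$subject)
  identifiable <- any(per_subject > 1)
  if (!identifiable) {
    warning("single observation per subject: tau00 and sigma2 are not separately identifiable")
  }
  ctrl <- if (identifiable) lme4::lmerControl() else
    lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore")
  fit <- lme4::lmer(value ~ time * group + (1 | subject), data = df,
                    REML = reml, control = ctrl)
  tau <- .subject_var(fit)
  sig <- stats::sigma(fit)^2
  r2 <- r2_nakagawa(.var_fixed(fit), tau, sig)
  structure(list(coefficients = .fixef_table(fit), sigma2 = sig, tau00 = tau,
                 icc = icc_gaussian(tau, sig),
                 r2_marginal = unname(r2["r2_marginal"]),
                 r2_conditional = unname(r2["r2_conditional"]),
                 identifiable = identifiable,
                 converged = length(fit@optinfo$conv$lme4$messages) == 0,
                 n_subjects = length(unique(df$subject)),
                 n_observations = nrow(df), fit = fit),
            class = "gaussian_lmm_fit")
}

#' Mann-Whitney U test
#'
#' Rank-sum two-sample test. The U statistic is computed from rank sums with
#' average-rank tie handling; the p-value is exact (full enumeration) when
#' `n_a * n_b <= 400` and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @return list with `U` (for sample `a`), `p`, `exact` flag.
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  .assert(length(a) > 0 && length(b) > 0, "samples must be non-empty")
  r <- rank(c(a, b))
  na <- length(a); nb <- length(b)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (na * nb <= 400) && !has_ties
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = use_exact, correct = TRUE))
  list(U = U, p = wt$p.value, exact = use_exact)
}
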