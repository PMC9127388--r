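#' Dependence-adjusted correlation via a random-intercept model
#'
#' Fits the linear mixed-effects model
#' `y_ij = beta0 + beta1 * x_ij + b_j + eps_ij` with a patient-level
#' random intercept `b_j` (maximum likelihood, via [lme4::lmer()]) and
#' reports the dependence-adjusted correlation coefficient
#' `r = beta1_hat * sqrt(var(x) / var(y))` with sample variances
#' computed ignoring the grouping. The p-value is a Wald test on
#' `beta1_hat`. With fewer than two groups the model degenerates to
#' ordinary least squares and `r` equals the Pearson correlation.
#'
#' @param x,y numeric vectors (factor values and response).
#' @param groups patient identifiers, same length.
#' @param factorName label carried into the result.
#' @return one-row data.frame: `factor`, `beta0`, `beta1`, `sigma_b`,
#'   `sigma_eps`, `r`, `p_value`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 2 * x + rnorm(50, 0, 0.1)
#' fitRandomIntercept(x, y, rep(1, 50))$r  # ~ Pearson correlation
#' @export
fitRandomIntercept <- function(x, y, groups, factorName = "x") {
  stopifnot(length(x) == length(y), length(x) == length(groups),
            length(x) >= 3)
  if (stats::var(x) == 0) stop("zero variance in x: singular fit")
  if (stats::var(y) == 0) stop("zero variance in y: singular fit")
  g <- factor(groups)
  if (nlevels(g) < 2L) {
    fit <- stats::lm(y ~ x)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))[2]
    sigmaB <- 0
    sigmaE <- summary(fit)$sigma
  } else {
    fit <- lme4::lmer(y ~ x + (1 | g), REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular =
                        lme4::.makeCC(action = "ignore", tol = 1e-4)))
    beta <- lme4::fixef(fit)
    # a degenerate fit (zero residual variance on an exact linear
    # relation) can break the mixed-model vcov; the OLS standard error
    # is the correct limit there
    se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit))))[2],
                   error = function(e) sqrt(diag(stats::vcov(stats::lm(y ~ x))))[2])
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigmaB <- vc$sdcor[vc$grp == "g"]
    sigmaE <- vc$sdcor[vc$grp == "Residual"]
  }
  b1 <- unname(beta[2])
  r <- b1 * sqrt(stats::var(x) / stats::var(y))
  if (abs(r) > 1) {
    warning("dependence-adjusted r exceeded 1 numerically; clipped")
    r <- sign(r)
  }
  z <- b1 / se
  p <- if (is.nan(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  data.frame(factor = factorName, beta0 = unname(beta[1]), beta1 = b1,
             sigma_b = sigmaB, sigma_eps = sigmaE, r = r,
             p_value = p)
}

#' Screen all factors against a response
#'
#' Runs [fitRandomIntercept()] for each factor column against the
#' response, flagging significance at p < 0.05 per factor with no
#' multiplicity correction (each factor is screened on its own terms; a
#' caveat worth remembering when reading the flags).
#'
#' @param table cohort feature data.frame (see
#'   [computeCohortFeatures()]).
#' @param response response column name (default `"dla"`).
#' @param factors factor column names (default [featureNames()]).
#' @param groups grouping column name (default `"patient_id"`).
#' @return data.frame, one row per factor, with `significant` logical.
#' @export
correlationScreen <- function(table, response = "dla",
                              factors = featureNames(),
                              groups = "patient_id") {
  stopifnot(response %in% names(table), groups %in% names(table),
            all(factors %in% names(table)), !anyNA(table[factors]))
  res <- do.call(rbind, lapply(factors, function(f)
    tryCatch(
      fitRandomIntercept(table[[f]], table[[response]], table[[groups]], f),
      error = function(e) {
        warning(sprintf("factor '%s': %s", f, conditionMessage(e)))
        data.frame(factor = f, beta0 = NA_real_, beta1 = NA_real_,
                   sigma_b = NA_real_, sigma_eps = NA_real_, r = NA_real_,
                   p_value = NA_real_)
      })))
  res$significant <- !is.na(res$p_value) & res$p_value < 0.05
  res
}

#' Write the correlation screen as CSV
#' @param screen output of [correlationScreen()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCorrelations <- function(screen, file) {
  utils::write.csv(screen, file, row.names = FALSE)
  invisible(file)
}
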