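#' Polygenic risk score model
#'
#' @param label Cluster name or `"overall"`.
#' @param weights Named numeric vector of per-variant effect sizes
#'   (effect-increasing orientation of the index trait).
#' @return A list of class `prs_model`.
#' @export
prs_model <- function(label, weights) {
  stopifnot(all(is.finite(weights)), !anyDuplicated(names(weights)),
            !is.null(names(weights)))
  structure(list(label = label, weights = weights,
                 variants = names(weights)), class = "prs_model")
}

#' Compute a standardized polygenic risk score
#'
#' Raw score per individual is the dosage-weighted sum over the model's
#' variants; the score is then centered and scaled to SD 1 over the scored
#' sample. Missing dosages are mean-imputed (with a logged count).
#'
#' @param cohort A `cohort` (from [simulate_cohort()] or equivalent, with
#'   a `dosages` matrix whose columns are variant ids).
#' @param model A [prs_model()].
#' @return Numeric standardized score vector with attributes `raw` (the
#'   unstandardized dosage-weighted sums) and `n_imputed`.
#' @export
build_prs <- function(cohort, model) {
  missing_v <- setdiff(model$variants, colnames(cohort$dosages))
  if (length(missing_v)) {
    stop("model variant(s) absent from dosages: ",
         paste(missing_v, collapse = ", "))
  }
  d <- cohort$dosages[, model$variants, drop = FALSE]
  n_imputed <- sum(is.na(d))
  if (n_imputed > 0) {
    message("build_prs: mean-imputing ", n_imputed, " missing dosage(s)")
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
    }
  }
  raw <- as.vector(d %*% model$weights)
  if (sd(raw) == 0) stop("degenerate model: zero variance in raw scores")
  score <- as.vector(scale(raw))
  attr(score, "raw") <- raw
  attr(score, "n_imputed") <- n_imputed
  score
}

#' Association testing configuration
#'
#' @param covariates Covariate names used in the regressions (default
#'   `age, sex, bmi, cohort`; drop `bmi` when BMI is the outcome).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m_tests Bonferroni correction count (default 6; the corrected
#'   threshold is `alpha / m_tests`).
#' @param top_q,bottom_q Quantiles defining the score tails for
#'   [decile_contrast()] (defaults 0.9 and 0.1).
#' @return A list of class `assoc_config`.
#' @export
assoc_config <- function(covariates = c("age", "sex", "bmi", "cohort"),
                         alpha = 0.05, m_tests = 6L,
                         top_q = 0.9, bottom_q = 0.1) {
  stopifnot(top_q > bottom_q, top_q > 0, top_q < 1, bottom_q > 0,
            bottom_q < 1, alpha > 0, m_tests >= 1)
  structure(list(covariates = covariates, alpha = alpha,
                 m_tests = as.integer(m_tests), top_q = top_q,
                 bottom_q = bottom_q), class = "assoc_config")
}

# design-matrix collinearity check; errors naming an offending pair
check_collinear <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("collinear covariate(s): ", paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Test association between a PRS and an outcome
#'
#' Continuous outcomes: ordinary least squares of the outcome on the score
#' plus covariates, Wald 95% CI, estimate in outcome-SD units when the
#' outcome is standardized. Binary outcomes: logistic regression, estimate
#' reported as an odds ratio with Wald CI. The Bonferroni flag compares
#' the p-value with `alpha / m_tests`.
#'
#' @param score Standardized score vector.
#' @param outcome Outcome vector (numeric, or 0/1 when `binary`).
#' @param covariates `data.frame` of covariates (columns named as in
#'   `cfg$covariates`; others ignored).
#' @param cfg An [assoc_config()].
#' @param binary Logical; fit logistic instead of linear regression.
#' @return An `assoc_result`: one-row `data.table` with
#'   `estimate, ci_low, ci_high, se, p, n, significant_after_bonferroni`
#'   (odds-ratio scale when binary).
#' @export
test_association <- function(score, outcome, covariates,
                             cfg = assoc_config(), binary = FALSE) {
  covariates <- as.data.frame(covariates)
  covs <- intersect(cfg$covariates, names(covariates))
  df <- data.frame(.y = outcome, .score = score,
                   covariates[, covs, drop = FALSE])
  stopifnot(nrow(df) > length(covs) + 2)
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  check_collinear(X)
  form <- stats::as.formula(".y ~ .")
  if (binary) {
    fit <- glm(form, data = df, family = binomial())
    if (!fit$converged || any(abs(predict(fit, type = "link")) > 30)) {
      stop("possible perfect separation in logistic model (fitted ",
           "probabilities pinned at 0/1)")
    }
  } else {
    fit <- lm(form, data = df)
  }
  sm <- summary(fit)$coefficients[".score", ]
  est <- sm[1]; se <- sm[2]; p <- sm[4]
  zq <- qnorm(0.975)
  out <- data.table::data.table(
    estimate = if (binary) exp(est) else est,
    ci_low = if (binary) exp(est - zq * se) else est - zq * se,
    ci_high = if (binary) exp(est + zq * se) else est + zq * se,
    se = se,
    p = p,
    n = nrow(df),
    significant_after_bonferroni = p < cfg$alpha / cfg$m_tests
  )
  class(out) <- c("assoc_result", class(out))
  out
}

#' Top-versus-bottom score-tail contrast
#'
#' Restricts to individuals at or above the `top_q` quantile versus at or
#' below the `bottom_q` quantile of the score and regresses the outcome on
#' tail membership (1 = top) with covariates.
#'
#' @inheritParams test_association
#' @param min_tail Minimum individuals required in each tail (default 30).
#' @return An `assoc_result` for the tail-membership indicator.
#' @export
decile_contrast <- function(score, outcome, covariates,
                            cfg = assoc_config(), binary = FALSE,
                            min_tail = 30L) {
  if (cfg$top_q <= cfg$bottom_q) stop("top_q must exceed bottom_q")
  covariates <- as.data.frame(covariates)
  qs <- quantile(score, c(cfg$bottom_q, cfg$top_q))
  bottom <- score <= qs[1]
  top <- score >= qs[2]
  if (sum(top) < min_tail || sum(bottom) < min_tail) {
    stop("tail too small: top = ", sum(top), ", bottom = ", sum(bottom),
         " (need >= ", min_tail, ")")
  }
  keep <- top | bottom
  test_association(as.numeric(top[keep]), outcome[keep],
                   covariates[keep, , drop = FALSE], cfg, binary)
}
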