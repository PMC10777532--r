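#' Construct an instrument set for two-sample Mendelian randomization
#'
#' Variants are oriented to the exposure-increasing allele: rows with
#' negative exposure effects have both effect signs flipped.
#'
#' @param beta_exposure,se_exposure Per-variant exposure effects and SEs.
#' @param beta_outcome,se_outcome Per-variant outcome effects and SEs.
#' @param n_exposure,n_outcome GWAS sample sizes (scalar or per-variant).
#' @param snp Optional variant ids.
#' @return A `data.table` of class `instrument_set`.
#' @export
instrument_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, n_exposure, n_outcome,
                           snp = NULL) {
  k <- length(beta_exposure)
  se_exposure <- rep_len(se_exposure, k)
  se_outcome <- rep_len(se_outcome, k)
  stopifnot(all(se_exposure > 0), all(se_outcome > 0),
            length(beta_outcome) == k)
  flip <- beta_exposure < 0
  out <- data.table::data.table(
    snp = snp %||% paste0("iv", seq_len(k)),
    beta_exposure = ifelse(flip, -beta_exposure, beta_exposure),
    se_exposure = se_exposure,
    beta_outcome = ifelse(flip, -beta_outcome, beta_outcome),
    se_outcome = se_outcome,
    n_exposure = rep_len(n_exposure, k),
    n_outcome = rep_len(n_outcome, k)
  )
  class(out) <- c("instrument_set", class(out))
  out
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_outcome^2` (fixed-effects by default). With a
#' single instrument this reduces to the Wald ratio.
#'
#' @param ins An [instrument_set()].
#' @param random_effects If `TRUE`, inflate the SE multiplicatively by the
#'   residual dispersion when it exceeds 1.
#' @return List with `beta`, `se`, `p`.
#' @export
ivw <- function(ins, random_effects = FALSE) {
  if (nrow(ins) < 1) stop("at least one instrument required")
  w <- 1 / ins$se_outcome^2
  bx <- ins$beta_exposure; by <- ins$beta_outcome
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se <- sqrt(1 / denom)
  if (random_effects && nrow(ins) > 1) {
    disp <- sum(w * (by - beta * bx)^2) / (nrow(ins) - 1)
    se <- se * max(1, sqrt(disp))
  }
  list(beta = beta, se = se, p = z_to_p(beta / se))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept, after orienting instruments to the exposure-increasing
#' allele; the intercept tests directional pleiotropy.
#'
#' @param ins An [instrument_set()] (already exposure-oriented).
#' @return List with `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
egger <- function(ins) {
  if (nrow(ins) < 3) stop("Egger regression requires >= 3 instruments")
  fit <- lm(beta_outcome ~ beta_exposure, data = ins,
            weights = 1 / ins$se_outcome^2)
  cf <- summary(fit)$coefficients
  list(slope = cf["beta_exposure", 1], slope_se = cf["beta_exposure", 2],
       slope_p = cf["beta_exposure", 4],
       intercept = cf["(Intercept)", 1],
       intercept_se = cf["(Intercept)", 2],
       intercept_p = cf["(Intercept)", 4])
}

#' Steiger directionality test
#'
#' Per-variant variance explained is obtained from summary statistics via
#' the regression identity `r2 = z^2 / (z^2 + n - 2)`, summed over
#' instruments for exposure and outcome separately (capped at 1 with a
#' warning). The two multiple correlations are Fisher-transformed and
#' compared: positive `steiger_z` means the instruments explain more of
#' the exposure, i.e. causality runs exposure to outcome.
#'
#' @param ins An [instrument_set()].
#' @return List with `rsq_exposure`, `rsq_outcome`, `steiger_z`, `p`,
#'   `direction` (`"exposure->outcome"` or `"outcome->exposure"`).
#' @export
steiger <- function(ins) {
  nx <- mean(ins$n_exposure); ny <- mean(ins$n_outcome)
  stopifnot(nx > 3, ny > 3)
  zx <- ins$beta_exposure / ins$se_exposure
  zy <- ins$beta_outcome / ins$se_outcome
  r2x <- sum(zx^2 / (zx^2 + ins$n_exposure - 2))
  r2y <- sum(zy^2 / (zy^2 + ins$n_outcome - 2))
  if (r2x > 1 || r2y > 1) {
    warning("summed r2 exceeds 1; capped")
    r2x <- min(r2x, 1); r2y <- min(r2y, 1)
  }
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  list(rsq_exposure = r2x, rsq_outcome = r2y, steiger_z = z,
       p = z_to_p(z),
       direction = if (z > 0) "exposure->outcome" else
         "outcome->exposure")
}

#' Pearson correlation of exposure and outcome effect sizes
#'
#' A dose-response relationship between per-variant effects on the two
#' traits supports a causal link.
#'
#' @param ins An [instrument_set()] with at least 3 instruments.
#' @return Pearson r, or `NA` (with a message) when either effect vector
#'   has zero variance.
#' @export
effect_correlation <- function(ins) {
  if (nrow(ins) < 3) stop("at least 3 instruments required")
  if (sd(ins$beta_exposure) == 0 || sd(ins$beta_outcome) == 0) {
    message("effect_correlation: zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(ins$beta_exposure, ins$beta_outcome)
}

#' Full MR report for one exposure-outcome pair
#'
#' Runs [ivw()], [egger()] (when at least 3 instruments), [steiger()],
#' and [effect_correlation()].
#'
#' @param ins An [instrument_set()].
#' @return A list of class `mr_report`.
#' @export
mr_report <- function(ins) {
  iv <- ivw(ins)
  eg <- if (nrow(ins) >= 3) egger(ins) else NULL
  st <- steiger(ins)
  structure(list(
    ivw_beta = iv$beta, ivw_se = iv$se, ivw_p = iv$p,
    egger_beta = eg$slope %||% NA_real_,
    egger_intercept = eg$intercept %||% NA_real_,
    egger_p = eg$slope_p %||% NA_real_,
    rsq_gx = st$rsq_exposure, rsq_gy = st$rsq_outcome,
    steiger_z = st$steiger_z, steiger_p = st$p,
    inferred_direction = st$direction,
    pearson_r = if (nrow(ins) >= 3) effect_correlation(ins) else NA_real_,
    n_instruments = nrow(ins)
  ), class = "mr_report")
}
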