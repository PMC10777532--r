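#' Sum-of-single-effects fine-mapping from z-scores and LD
#'
#' Fits an L-effect sum-of-single-effects model on the z scale: for each
#' effect `l`, the residual z-vector removes the LD-propagated contribution
#' of all other effects, per-variant log Bayes factors come from
#' [wakefield_labf()] with unit standard error and prior variance
#' `prior_w`, and the posterior inclusion vector `alpha[l, ]` is their
#' normalized exponential. Iterated until the largest change in any
#' inclusion probability falls below `tol`.
#'
#' A credible set is reported per effect: the smallest variant set by
#' descending inclusion probability reaching `coverage`, kept only if its
#' purity (minimum absolute pairwise LD among members) is at least
#' `purity_min` and the effect's Bayes factor against the null exceeds 1.
#'
#' @param z Numeric z-score vector.
#' @param ld An [ld_matrix()] of matching dimension.
#' @param L Maximum number of effects (default 10).
#' @param prior_w Prior variance of a single effect on the z scale
#'   (default 25, i.e. effects detectable at |z| around 5).
#' @param coverage Target credible-set coverage (default 0.95).
#' @param purity_min Minimum credible-set purity (default 0.5).
#' @param tol Convergence tolerance on `max |delta alpha|` (default 1e-4).
#' @param max_iter Iteration cap (default 200).
#' @return A `susie_fit`: list with `alpha` (L x M), `lbf` (L x M
#'   per-variant log Bayes factors at convergence), `lbf_effect`
#'   (per-effect log Bayes factor), `sets` (list of credible sets with
#'   `idx`, `coverage`, `purity`, `effect`), `converged`, `iterations`,
#'   and `variants`.
#' @export
susie_rss <- function(z, ld, L = 10L, prior_w = 25, coverage = 0.95,
                      purity_min = 0.5, tol = 1e-4, max_iter = 200L) {
  if (any(!is.finite(z))) {
    stop("non-finite z at variant(s): ",
         paste(ld$variants[!is.finite(z)], collapse = ", "))
  }
  m <- length(z)
  stopifnot(m == length(ld$variants), L >= 1)
  r <- ld$r
  shrink <- prior_w / (prior_w + 1)   # posterior mean factor, unit SE
  alpha <- matrix(1 / m, L, m)
  b <- matrix(0, L, m)                # alpha-weighted posterior means
  lbf <- matrix(0, L, m)
  lbf_effect <- numeric(L)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    alpha_old <- alpha
    for (l in seq_len(L)) {
      resid <- z - as.vector(r %*% (colSums(b) - b[l, ]))
      lab <- wakefield_labf(resid, 1, prior_w)
      alpha[l, ] <- softmax(lab)
      b[l, ] <- alpha[l, ] * shrink * resid
      lbf[l, ] <- lab
      lbf_effect[l] <- logsumexp(lab) - log(m)
    }
    if (max(abs(alpha - alpha_old)) < tol) {
      converged <- TRUE
      break
    }
  }

  sets <- list()
  for (l in seq_len(L)) {
    if (lbf_effect[l] <= 0) next
    ord <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, ord])
    idx <- ord[seq_len(which(csum >= coverage)[1])]
    purity <- if (length(idx) == 1L) 1 else
      min(abs(r[idx, idx][upper.tri(matrix(0, length(idx),
                                           length(idx)))]))
    if (purity < purity_min) next
    sets <- c(sets, list(list(idx = idx, coverage = csum[length(idx)],
                              purity = purity, effect = l)))
  }
  structure(list(alpha = alpha, lbf = lbf, lbf_effect = lbf_effect,
                 sets = sets, converged = converged, iterations = it,
                 variants = ld$variants),
            class = "susie_fit")
}

#' Credible-set-pair colocalization between two fine-mapping fits
#'
#' For every pair of credible sets (one from each fit), runs the H0-H4
#' enumeration of [coloc_abf()] on the pair's effect-specific log Bayes
#' factor vectors and emits an event when `PP.H4` exceeds the threshold.
#' The event lead is the first fit's highest-inclusion variant within its
#' credible set.
#'
#' @param fit1,fit2 `susie_fit`s over the same variant ordering (`fit1` is
#'   the index trait).
#' @param priors A [coloc_priors()].
#' @param variants Optional variant ids (default `fit1$variants`).
#' @param pp_threshold `PP.H4` acceptance threshold (default 0.6).
#' @return List of `coloc_event`s (possibly empty), `method = "susie"`.
#' @export
coloc_susie <- function(fit1, fit2, priors = coloc_priors(),
                        variants = NULL, pp_threshold = 0.6) {
  variants <- variants %||% fit1$variants
  events <- list()
  if (length(fit1$sets) == 0L || length(fit2$sets) == 0L) return(events)
  for (sa in fit1$sets) {
    for (sb in fit2$sets) {
      en <- coloc_enumerate(fit1$lbf[sa$effect, ], fit2$lbf[sb$effect, ],
                            priors)
      if (en$pp[["PP.H4"]] <= pp_threshold) next
      lead_i <- sa$idx[which.max(fit1$alpha[sa$effect, sa$idx])]
      events <- c(events, list(structure(list(
        pp = en$pp,
        lead = variants[lead_i],
        method = "susie",
        set_pair = c(sa$effect, sb$effect)
      ), class = "coloc_event")))
    }
  }
  events
}
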