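#' Colocalization priors
#'
#' Per-variant prior probabilities for the single-causal-variant
#' enumeration: `p1`/`p2` (associated with one trait only), `p12`
#' (associated with both), and the prior effect variance `W` of the
#' Wakefield approximate Bayes factor on the standardized-beta scale. For
#' the multi-trait posterior, `prior_c` is the per-configuration prior that
#' all traits share one causal variant and `prior_d` the prior that they
#' are causal at independent variants; by default `prior_c = p12` and
#' `prior_d = p1^n_traits`, evaluated at run time.
#'
#' @param p1,p2,p12 Per-variant association priors (defaults 1e-4, 1e-4,
#'   1e-5).
#' @param W Prior effect variance (default 0.04).
#' @param prior_c,prior_d Optional overrides for the multi-trait priors.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.04,
                         prior_c = NULL, prior_d = NULL) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p12 <= min(p1, p2), W > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W = W,
                 prior_c = prior_c, prior_d = prior_d),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2` and `z = beta/se`,
#' `lABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))`: the log Bayes factor for
#' association of one variant under a `N(0, W)` effect prior. Vectorized.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param W Prior effect variance (`> 0`).
#' @return Log approximate Bayes factor(s).
#' @export
wakefield_labf <- function(beta, se, W = 0.04) {
  if (any(se <= 0)) stop("se must be > 0")
  if (W <= 0) stop("W must be > 0")
  V <- se^2
  z2 <- (beta / se)^2
  0.5 * (log(V / (V + W)) + z2 * W / (V + W))
}

# H0-H4 enumeration from two per-variant lABF vectors (single causal
# variant per trait). Returns posteriors, per-variant H4 contribution, and
# the log evidence sums.
coloc_enumerate <- function(l1, l2, priors) {
  stopifnot(length(l1) == length(l2))
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    H0 = 0,
    H1 = log(priors$p1) + s1,
    H2 = log(priors$p2) + s2,
    H3 = log(priors$p1) + log(priors$p2) + logdiffexp(s1 + s2, s12),
    H4 = log(priors$p12) + s12
  )
  pp <- softmax(lh)
  names(pp) <- paste0("PP.", names(lh))
  list(pp = pp, h4_by_variant = l1 + l2, log_s1 = s1, log_s2 = s2)
}

#' Pairwise colocalization from approximate Bayes factors
#'
#' Enumerates all single-causal-variant configurations for two traits over
#' a shared variant ordering, combining per-variant Wakefield Bayes factors
#' with the priors into posterior probabilities of the five global
#' hypotheses (H0: neither trait associated; H1/H2: one trait only; H3:
#' both, distinct variants; H4: both, shared variant). All sums are
#' computed in log space.
#'
#' @param t1,t2 Summary-statistic tables ([read_sumstats()] layout) with
#'   identical variant ordering.
#' @param priors A [coloc_priors()].
#' @param traits Optional pair of trait labels for reporting.
#' @return A `coloc_event`: list with `pp` (named posteriors summing to 1),
#'   `lead` (variant id maximizing the per-variant H4 contribution),
#'   `min_trait_p` (smaller association p at the lead), `method = "abf"`,
#'   and `traits`. `NULL` (with a message) when fewer than 2 variants.
#' @export
coloc_abf <- function(t1, t2, priors = coloc_priors(),
                      traits = c("trait1", "trait2")) {
  if (nrow(t1) < 2) {
    message("coloc_abf: fewer than 2 variants; region skipped")
    return(NULL)
  }
  stopifnot(nrow(t1) == nrow(t2), all(t1$snp == t2$snp))
  l1 <- wakefield_labf(t1$beta, t1$se, priors$W)
  l2 <- wakefield_labf(t2$beta, t2$se, priors$W)
  en <- coloc_enumerate(l1, l2, priors)
  lead_i <- which.max(en$h4_by_variant)
  structure(list(
    pp = en$pp,
    lead = t1$snp[lead_i],
    min_trait_p = min(z_to_p(t1$z[lead_i]), z_to_p(t2$z[lead_i])),
    method = "abf",
    traits = traits
  ), class = "coloc_event")
}

# per-trait lABF matrix (variants x traits) for a region panel
panel_labf <- function(panel, priors) {
  vapply(panel$stats,
         function(dt) wakefield_labf(dt$beta, dt$se, priors$W),
         numeric(nrow(panel$stats[[1]])))
}

# regional/alignment posterior for one trait subset
multitrait_posterior <- function(L, priors) {
  n_tr <- ncol(L)
  s_t <- apply(L, 2, logsumexp)                 # log evidence per trait
  log_c <- logsumexp(rowSums(L))                # log shared evidence
  prior_c <- priors$prior_c %||% priors$p12
  prior_d <- priors$prior_d %||% priors$p1^n_tr
  pa <- plogis(log(prior_c) + log_c - log(prior_d) - sum(s_t))
  pi1 <- priors$p1 + priors$p12
  pr <- exp(sum(plogis(log(pi1) + s_t, log.p = TRUE)))
  list(pr = pr, pa = pa, shared_by_variant = rowSums(L))
}

#' Multi-trait colocalization with greedy trait dropping
#'
#' Computes a regional posterior `P_R` (every trait has a causal variant in
#' the region) and an alignment posterior `P_A` (given so, it is the same
#' variant) from per-trait Wakefield Bayes factors. A trait set is accepted
#' when `P_R * P_A > 0.60` and every trait's association p-value at the
#' candidate shared variant is `< 1e-5`. If the full set fails, the
#' non-index trait whose removal maximally increases `P_R * P_A` is dropped
#' and the test repeated, until acceptance or only the index trait and one
#' other remain.
#'
#' @param panel A `region_panel`.
#' @param priors A [coloc_priors()].
#' @param pp_threshold Acceptance threshold on `P_R * P_A` (default 0.60).
#' @param p_gate Per-trait association p-value gate at the candidate
#'   (default 1e-5), applied to every trait in the accepted set.
#' @return A `coloc_event` with `pr`, `pa`, `accepted`, the retained
#'   `traits`, `lead` (argmax of the per-variant shared evidence),
#'   `min_trait_p`, and `method = "multitrait"`.
#' @export
multitrait_coloc <- function(panel, priors = coloc_priors(),
                             pp_threshold = 0.60, p_gate = 1e-5) {
  stopifnot(length(panel$traits) >= 2)
  L <- panel_labf(panel, priors)
  zmat <- vapply(panel$stats, function(dt) dt$z,
                 numeric(nrow(panel$stats[[1]])))
  current <- panel$traits
  index <- panel$index_trait %||% current[1]
  repeat {
    po <- multitrait_posterior(L[, current, drop = FALSE], priors)
    cand <- which.max(po$shared_by_variant)
    p_at_cand <- z_to_p(zmat[cand, current])
    ok <- (po$pr * po$pa > pp_threshold) && all(p_at_cand < p_gate)
    if (ok || length(current) <= 2) {
      return(structure(list(
        pr = po$pr, pa = po$pa, accepted = ok,
        traits = current,
        lead = panel$stats[[1]]$snp[cand],
        min_trait_p = min(p_at_cand),
        method = "multitrait",
        region_id = panel$region$region_id %||% NA_character_
      ), class = "coloc_event"))
    }
    droppable <- setdiff(current, index)
    gain <- vapply(droppable, function(tr) {
      sub <- setdiff(current, tr)
      po2 <- multitrait_posterior(L[, sub, drop = FALSE], priors)
      po2$pr * po2$pa
    }, numeric(1))
    current <- setdiff(current, droppable[which.max(gain)])
  }
}

#' Staged colocalization workflow for one region
#'
#' Stage A: single-signal regions are tested with [multitrait_coloc()]
#' across all traits simultaneously; an accepted set is emitted as one
#' event. Stage B: multi-signal regions (or regions with `P_R > 0.8` that
#' failed the `P_R * P_A` rule) are fine-mapped per trait with
#' [susie_rss()] and tested credible-set-by-credible-set with
#' [coloc_susie()] against the index trait. Stage C: when index-trait
#' fine-mapping yields no credible sets, pairwise [coloc_abf()] under the
#' single-causal-variant assumption is the fallback. Pairwise events
#' require `PP.H4 > 0.6`.
#'
#' The panel is expected to be harmonized and palindromic-resolved (see
#' [resolve_palindromic()]), so every emitted lead is already oriented and
#' unambiguous.
#'
#' @param panel A `region_panel`.
#' @param priors A [coloc_priors()].
#' @param susie_cfg List of arguments for [susie_rss()] (e.g. `L`).
#' @param pp_threshold,p_gate Acceptance thresholds (defaults 0.60, 1e-5).
#' @return A list with `events` (accepted `coloc_event`s) and `log`
#'   (character vector of stage decisions and non-emission reasons).
#' @export
run_region_workflow <- function(panel, priors = coloc_priors(),
                                susie_cfg = list(L = 10),
                                pp_threshold = 0.60, p_gate = 1e-5) {
  index <- panel$index_trait
  n_signals <- panel$region$n_signals %||% 1L
  rid <- panel$region$region_id %||% NA_character_
  log <- character(0)
  events <- list()

  stage_b <- n_signals > 1L
  if (!stage_b) {
    ev <- multitrait_coloc(panel, priors, pp_threshold, p_gate)
    if (ev$accepted) {
      log <- c(log, sprintf("region %s: stage A accepted (%s)", rid,
                            paste(ev$traits, collapse = ",")))
      return(list(events = list(ev), log = log))
    }
    if (ev$pr > 0.8) {
      stage_b <- TRUE
      log <- c(log, sprintf(
        "region %s: stage A P_R = %.2f without acceptance; to stage B",
        rid, ev$pr))
    } else {
      log <- c(log, sprintf(
        "region %s: stage A rejected (P_R = %.2g, P_A = %.2g)",
        rid, ev$pr, ev$pa))
      return(list(events = events, log = log))
    }
  } else {
    log <- c(log, sprintf("region %s: %d signals; to stage B", rid,
                          n_signals))
  }

  fits <- lapply(panel$stats, function(dt) {
    do.call(susie_rss, c(list(z = dt$z, ld = panel$ld), susie_cfg))
  })
  if (length(fits[[index]]$sets) == 0L) {
    # Stage C: single-causal-variant fallback
    log <- c(log, sprintf(
      "region %s: no index credible sets; stage C abf fallback", rid))
    for (tr in setdiff(panel$traits, index)) {
      ev <- coloc_abf(panel$stats[[index]], panel$stats[[tr]], priors,
                      traits = c(index, tr))
      if (!is.null(ev) && ev$pp[["PP.H4"]] > pp_threshold) {
        ev$method <- "abf-fallback"
        ev$region_id <- rid
        events <- c(events, list(ev))
      } else {
        log <- c(log, sprintf("region %s: stage C %s~%s not colocalized",
                              rid, index, tr))
      }
    }
    return(list(events = events, log = log))
  }

  for (tr in setdiff(panel$traits, index)) {
    evs <- coloc_susie(fits[[index]], fits[[tr]], priors,
                       variants = panel$stats[[index]]$snp,
                       pp_threshold = pp_threshold)
    if (length(evs) == 0L) {
      log <- c(log, sprintf("region %s: stage B %s~%s not colocalized",
                            rid, index, tr))
    }
    for (ev in evs) {
      ev$traits <- c(index, tr)
      ev$region_id <- rid
      lead_i <- match(ev$lead, panel$stats[[index]]$snp)
      ev$min_trait_p <- min(z_to_p(panel$stats[[index]]$z[lead_i]),
                            z_to_p(panel$stats[[tr]]$z[lead_i]))
      events <- c(events, list(ev))
    }
  }
  list(events = events, log = log)
}
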