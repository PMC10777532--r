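#' Adjusted Rand index between two partitions
#'
#' @param x,y Two label vectors of equal length.
#' @return The adjusted Rand index (1 = identical partitions, ~0 =
#'   chance agreement).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  choose2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- choose2(as.vector(tab))
  sum_i <- choose2(rowSums(tab))
  sum_j <- choose2(colSums(tab))
  expected <- sum_i * sum_j / choose2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Colocalization calibration experiment
#'
#' Simulates regions with a shared causal variant and null regions under
#' the package's z-scale generator, and measures how often pairwise
#' colocalization declares sharing (`PP.H4 > 0.6`) in each condition.
#'
#' @param n_reps Regions per condition (default 200).
#' @param m Variants per region (default 150).
#' @param rho AR(1) LD decay (default 0.8).
#' @param lambda Non-centrality of the shared causal variant (default 8).
#' @param n GWAS sample size per trait (default 50000).
#' @param seed Seed.
#' @return List with `h4_rate` (shared regions detected) and
#'   `null_event_rate` (null regions falsely declared).
#' @export
experiment_coloc_calibration <- function(n_reps = 200, m = 150,
                                         rho = 0.8, lambda = 8,
                                         n = 50000, seed = 1) {
  set.seed(seed)
  ld <- simulate_ld(m, rho)
  ch <- chol(ld$r)
  lam <- numeric(m); lam[m %/% 2] <- lambda
  run_one <- function(lam1, lam2) {
    t1 <- z_to_region_stats(draw_mvn_z(ch, ld$r, lam1), ld$variants, n)
    t2 <- z_to_region_stats(draw_mvn_z(ch, ld$r, lam2), ld$variants, n)
    coloc_abf(t1, t2)$pp[["PP.H4"]] > 0.6
  }
  shared <- vapply(seq_len(n_reps), function(i) run_one(lam, lam),
                   logical(1))
  null <- vapply(seq_len(n_reps), function(i)
    run_one(numeric(m), numeric(m)), logical(1))
  list(h4_rate = mean(shared), null_event_rate = mean(null))
}

#' Pairwise concordance between the multi-trait and ABF decisions
#'
#' Simulates two-trait regions, half with a shared causal variant and
#' half with distinct causal variants, and compares the multi-trait
#' accept/reject decision with `PP.H4 > 0.6` from the pairwise
#' enumeration.
#'
#' @inheritParams experiment_coloc_calibration
#' @return List with `agreement` rate and the two per-method accept
#'   rates.
#' @export
experiment_concordance <- function(n_reps = 200, m = 150, rho = 0.8,
                                   lambda = 8, n = 50000, seed = 1) {
  set.seed(seed)
  ld <- simulate_ld(m, rho)
  ch <- chol(ld$r)
  j1 <- m %/% 4; j2 <- (3 * m) %/% 4
  agree <- logical(n_reps)
  acc_multi <- logical(n_reps); acc_abf <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    shared <- i <= n_reps / 2
    lam1 <- numeric(m); lam1[j1] <- lambda
    lam2 <- numeric(m)
    lam2[if (shared) j1 else j2] <- lambda
    t1 <- z_to_region_stats(draw_mvn_z(ch, ld$r, lam1), ld$variants, n)
    t2 <- z_to_region_stats(draw_mvn_z(ch, ld$r, lam2), ld$variants, n)
    panel <- structure(list(region = NULL, traits = c("t1", "t2"),
                            index_trait = "t1",
                            stats = list(t1 = t1, t2 = t2), ld = ld),
                       class = "region_panel")
    mt <- multitrait_coloc(panel)
    ab <- coloc_abf(t1, t2)
    acc_multi[i] <- mt$accepted
    acc_abf[i] <- ab$pp[["PP.H4"]] > 0.6
    agree[i] <- acc_multi[i] == acc_abf[i]
  }
  list(agreement = mean(agree), multitrait_accept_rate = mean(acc_multi),
       abf_accept_rate = mean(acc_abf))
}

#' Fine-mapping signal-recovery experiment
#'
#' Simulates two LD-independent causal signals per region and measures
#' how often [susie_rss()] reports credible sets containing both true
#' variants. Also evaluates the analytic check that the `L = 1` inclusion
#' vector equals the normalized single-effect Bayes factors.
#'
#' @param n_reps Regions (default 100).
#' @param m Variants per region (default 100; two AR(1) blocks).
#' @param rho Within-block LD decay (default 0.8).
#' @param lambda Signal size (default 8).
#' @param seed Seed.
#' @return List with `recovery_rate` and `l1_max_abs_diff`.
#' @export
experiment_susie_recovery <- function(n_reps = 100, m = 100, rho = 0.8,
                                      lambda = 8, seed = 1) {
  set.seed(seed)
  ld <- simulate_ld(m, rho, blocks = 2)
  ch <- chol(ld$r)
  j1 <- m %/% 10; j2 <- m - m %/% 10
  lam <- numeric(m); lam[c(j1, j2)] <- lambda
  hits <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    z <- draw_mvn_z(ch, ld$r, lam)
    fit <- susie_rss(z, ld, L = 10)
    hits[i] <- all(vapply(c(j1, j2), function(j) {
      any(vapply(fit$sets, function(s) j %in% s$idx, logical(1)))
    }, logical(1)))
  }
  z1 <- draw_mvn_z(ch, ld$r, lam)
  fit1 <- susie_rss(z1, ld, L = 1)
  analytic <- softmax(wakefield_labf(z1, 1, 25))
  list(recovery_rate = mean(hits),
       l1_max_abs_diff = max(abs(fit1$alpha[1, ] - analytic)))
}

#' Planted-cluster recovery experiment
#'
#' Builds the default 3-cluster sparse z matrix, runs the correlation
#' network, minimum-degree cutoff, and spinglass clustering across
#' `n_seeds` restart seeds, and scores each solution against the planted
#' membership with the adjusted Rand index.
#'
#' @param n_seeds Number of clustering seeds (default 20).
#' @param n_per_cluster Variants per planted cluster (default 10).
#' @param seed Seed for the planted z matrix.
#' @return List with `mean_ari`, `min_ari`, and the per-seed `ari`
#'   vector.
#' @export
experiment_cluster_recovery <- function(n_seeds = 20, n_per_cluster = 10,
                                        seed = 1) {
  set.seed(seed)
  plan <- default_scenario()$cluster_plan
  sim <- simulate_zmatrix(plan, n_per_cluster = n_per_cluster)
  cc <- snp_correlation(sim$zmatrix)
  cut <- min_degree_threshold(cc)
  ari <- vapply(seq_len(n_seeds), function(s) {
    sol <- suppressMessages(spinglass_cluster(
      cc, cut, cluster_config(n_restarts = 5, seed = seed + s)))
    adjusted_rand_index(sol$membership, sim$membership)
  }, numeric(1))
  list(mean_ari = mean(ari), min_ari = min(ari), ari = ari)
}

#' Polygenic-score effect-recovery experiment
#'
#' Simulates cohorts with a planted per-SD effect of the true score on a
#' continuous outcome, scores individuals with [build_prs()] using the
#' true weights, and tests the association with covariates.
#'
#' @param n_cohorts Number of cohorts (default 50).
#' @param n_ind Individuals per cohort (default 20000).
#' @param effect Planted per-SD effect (default 0.08).
#' @param n_variants Score variants (default 30).
#' @param seed Seed.
#' @return List with `mean_beta`, `max_abs_err` of the per-cohort
#'   estimates, and `ci_coverage` of the planted effect by the 95% CIs.
#' @export
experiment_prs_recovery <- function(n_cohorts = 50, n_ind = 20000,
                                    effect = 0.08, n_variants = 30,
                                    seed = 1) {
  set.seed(seed)
  variants <- data.table::data.table(
    snp = sprintf("v%d", seq_len(n_variants)),
    eaf = runif(n_variants, 0.1, 0.9))
  w <- setNames(runif(n_variants, 0.01, 0.1), variants$snp)
  cfg <- assoc_config(covariates = c("age", "sex", "bmi", "cohort"))
  betas <- numeric(n_cohorts); covered <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    co <- simulate_cohort(n_ind, variants, w, effect_on_outcome = effect,
                          covariate_effects = c(age = 0.01, sex = 0.1))
    score <- build_prs(co, prs_model("truth", w))
    res <- test_association(score, co$phenotypes$y_cont, co$covariates,
                            cfg)
    betas[i] <- res$estimate
    covered[i] <- res$ci_low <= effect && effect <= res$ci_high
  }
  list(mean_beta = mean(betas), max_abs_err = max(abs(betas - effect)),
       ci_coverage = mean(covered))
}

#' Mendelian-randomization recovery and directionality experiment
#'
#' IVW slope recovery: repeated two-sample data sets with a planted
#' causal slope. Directionality: forward scenarios where instruments act
#' on the exposure (which then causes the outcome) and reverse scenarios
#' where the instruments act on the outcome, scored by the Steiger
#' inference.
#'
#' @param n_reps_ivw IVW replicates (default 500).
#' @param n_reps_steiger Steiger replicates per direction (default 200).
#' @param n_instruments Instruments per data set (default 50).
#' @param slope Planted causal slope (default 0.55).
#' @param seed Seed.
#' @return List with `ivw_mean`, `steiger_forward_rate`,
#'   `steiger_reverse_rate`, and `pearson_r` (dose-response correlation
#'   of per-variant effect sizes in the last IVW replicate).
#' @export
experiment_mr_recovery <- function(n_reps_ivw = 500,
                                   n_reps_steiger = 200,
                                   n_instruments = 50, slope = 0.55,
                                   seed = 1) {
  set.seed(seed)
  k <- n_instruments
  n_x <- 1e6; n_y <- 1e5
  se_x <- 1 / sqrt(n_x); se_y <- 1 / sqrt(n_y)
  bx_true <- runif(k, 0.01, 0.05)
  pearson_r <- NA_real_
  ivw_hat <- vapply(seq_len(n_reps_ivw), function(i) {
    bx <- bx_true + rnorm(k, 0, se_x)
    by <- slope * bx_true + rnorm(k, 0, se_y)
    ins <- instrument_set(bx, se_x, by, se_y, n_x, n_y)
    if (i == n_reps_ivw) {
      # dose-response correlation between per-variant effect sizes
      pearson_r <<- effect_correlation(ins)
    }
    ivw(ins)$beta
  }, numeric(1))

  # forward/reverse directionality at matched sample sizes
  n_s <- 1e5; se_s <- 1 / sqrt(n_s)
  gx <- sqrt(0.02 / k)    # instruments explain 2% of the upstream trait
  fwd <- logical(n_reps_steiger); rev <- logical(n_reps_steiger)
  for (i in seq_len(n_reps_steiger)) {
    b_up <- gx + rnorm(k, 0, se_s)          # effect on the upstream trait
    b_down <- 0.5 * gx + rnorm(k, 0, se_s)  # attenuated downstream effect
    ins_f <- instrument_set(b_up, se_s, b_down, se_s, n_s, n_s)
    fwd[i] <- steiger(ins_f)$direction == "exposure->outcome"
    ins_r <- instrument_set(b_down, se_s, b_up, se_s, n_s, n_s)
    rev[i] <- steiger(ins_r)$direction == "outcome->exposure"
  }
  list(ivw_mean = mean(ivw_hat),
       steiger_forward_rate = mean(fwd),
       steiger_reverse_rate = mean(rev),
       pearson_r = pearson_r)
}

#' End-to-end pipeline experiment on the default synthetic scenario
#'
#' Materializes the default scenario, runs [run_pipeline()], and scores
#' the result against the scenario truth table: sensitivity over planted
#' colocalized regions, false-region rate, adjusted Rand index of the
#' recovered clusters against the planted pathway labels, and the signs
#' of a partitioned-PRS association and of the MR analysis between the
#' most-shared trait and the index trait within the largest cluster.
#'
#' @param seed Scenario and analysis seed.
#' @param dir Optional scenario directory (default a fresh tempdir).
#' @return List of summary numbers (see source for fields).
#' @export
experiment_end_to_end <- function(seed = 1, dir = NULL) {
  dir <- dir %||% tempfile("coloclust_scenario_")
  spec <- default_scenario(seed = seed)
  truth <- make_scenario(spec, dir, force = TRUE)
  res <- suppressMessages(run_pipeline(
    dir, ccfg = cluster_config(n_restarts = 10, seed = seed)))
  et <- events_table(res$events)

  detected <- unique(et$region_id)
  coloc_regions <- truth[colocalized == TRUE, region_id]
  sensitivity <- mean(coloc_regions %in% detected)
  false_rate <- length(setdiff(detected, coloc_regions)) / nrow(truth)

  # planted cluster label of each clustered lead variant, via its region
  lead_region <- et[!duplicated(lead), setNames(region_id, lead)]
  vars <- names(res$solution$membership)
  truth_labels <- truth[match(lead_region[vars], region_id), cluster]
  cluster_ari <- adjusted_rand_index(res$solution$membership,
                                     truth_labels)

  # partitioned PRS for the largest cluster, validated in a simulated
  # cohort whose outcome depends on the true score
  sizes <- table(res$solution$membership)
  big <- names(sizes)[which.max(sizes)]
  members <- vars[res$solution$membership == big]
  idx_stats <- res$stats_lookup$t2d[snp %in% members]
  w <- setNames(idx_stats$beta, idx_stats$snp)
  set.seed(seed + 1000L)
  co <- simulate_cohort(8000, idx_stats[, .(snp, eaf)], w,
                        effect_on_outcome = 0.1)
  score <- build_prs(co, prs_model(big, w))
  prs_res <- test_association(score, co$phenotypes$y_cont, co$covariates,
                              assoc_config())

  # MR between the cluster's strongest shared trait (exposure) and the
  # index trait (outcome) using the cluster variants as instruments
  other <- setdiff(names(res$stats_lookup), "t2d")
  shared_counts <- vapply(other, function(tr) {
    sum(res$zmat$values[rownames(res$zmat$values) %in% members, tr] != 0)
  }, numeric(1))
  exp_tr <- names(which.max(shared_counts))
  ex <- res$stats_lookup[[exp_tr]][snp %in% members]
  out <- res$stats_lookup$t2d[match(ex$snp, snp)]
  mr <- mr_report(instrument_set(ex$beta, ex$se, out$beta, out$se,
                                 ex$n, out$n, snp = ex$snp))
  # planted sign of the exposure within this cluster (z aligned to the
  # index risk allele): the causal slope must carry the same sign
  exposure_mean_z <- mean(
    res$zmat$values[rownames(res$zmat$values) %in% members, exp_tr])
  list(sensitivity = sensitivity, false_rate = false_rate,
       cluster_ari = cluster_ari,
       n_events = nrow(et), k_clusters = res$solution$k,
       modularity = res$solution$modularity,
       cutoff = as.numeric(res$cutoff),
       prs_beta = prs_res$estimate, prs_p = prs_res$p,
       ivw_beta = mr$ivw_beta,
       steiger_direction = mr$inferred_direction,
       mr_exposure = exp_tr,
       exposure_mean_z = exposure_mean_z)
}

# internal: one z draw given a precomputed cholesky factor
draw_mvn_z <- function(chol_r, r, lambdas) {
  as.vector(r %*% lambdas) + as.vector(crossprod(chol_r, rnorm(nrow(r))))
}

# internal: wrap a z vector as a summary-statistic table
z_to_region_stats <- function(z, ids, n) {
  data.table::data.table(
    snp = ids, chr = "1", pos = seq_along(ids) * 1000L,
    ea = "A", oa = "G", eaf = 0.5,
    beta = z / sqrt(n), se = 1 / sqrt(n), p = z_to_p(z), n = n, z = z)
}
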