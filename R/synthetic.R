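#' Simulate a block-diagonal AR(1) LD matrix
#'
#' Within each block, `r[i, j] = rho^|i - j|`; blocks are independent. An
#' AR(1) correlation matrix with `0 <= rho < 1` is positive definite.
#'
#' @param m Number of variants.
#' @param rho AR(1) decay parameter in `[0, 1)`.
#' @param blocks Number of equal-sized independent blocks (default 1; the
#'   last block absorbs any remainder).
#' @param ids Optional variant ids (default `v1..vm`).
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(m, rho, blocks = 1L, ids = NULL) {
  stopifnot(m >= 1)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  ids <- ids %||% paste0("v", seq_len(m))
  sizes <- rep(m %/% blocks, blocks)
  sizes[blocks] <- sizes[blocks] + m %% blocks
  r <- matrix(0, m, m)
  at <- 0L
  for (s in sizes) {
    if (s == 0L) next
    i <- at + seq_len(s)
    r[i, i] <- rho^abs(outer(seq_len(s), seq_len(s), "-"))
    at <- at + s
  }
  ld_matrix(r, ids)
}

#' Simulate GWAS summary statistics for one region on the z scale
#'
#' Draws the region z-score vector from a multivariate normal with mean
#' `r %*% lambda` and covariance `r` (`lambda` is the vector of per-variant
#' non-centralities: the expected z of each causal variant). Effects are
#' reported on the standardized-trait scale: `beta = z / sqrt(n)`,
#' `se = 1 / sqrt(n)`, and `p` is the two-sided normal tail of `z`.
#'
#' @param ld An [ld_matrix()].
#' @param lambdas Numeric non-centrality vector, one entry per variant.
#' @param n GWAS sample size.
#' @param eafs Optional effect-allele frequencies (default Uniform(0.05,
#'   0.95)).
#' @param chrom,pos0 Chromosome label and start position for generated
#'   variant coordinates (spaced 1000 bp).
#' @param alleles Optional 2-column character matrix of (ea, oa); defaults
#'   to non-palindromic A/G pairs.
#' @return A `data.table` in [read_sumstats()] layout.
#' @export
simulate_region_sumstats <- function(ld, lambdas, n, eafs = NULL,
                                     chrom = "1", pos0 = 1e6L,
                                     alleles = NULL) {
  m <- length(ld$variants)
  stopifnot(length(lambdas) == m, n >= 2)
  ch <- tryCatch(chol(ld$r), error = function(e) {
    stop("LD matrix is not positive definite: ", conditionMessage(e))
  })
  z <- as.vector(ld$r %*% lambdas) + as.vector(crossprod(ch, rnorm(m)))
  eafs <- eafs %||% runif(m, 0.05, 0.95)
  if (is.null(alleles)) {
    alleles <- cbind(rep("A", m), rep("G", m))
  }
  data.table::data.table(
    snp = ld$variants,
    chr = as.character(chrom),
    pos = as.integer(pos0 + 1000L * (seq_len(m) - 1L)),
    ea = alleles[, 1], oa = alleles[, 2],
    eaf = eafs,
    beta = z / sqrt(n),
    se = 1 / sqrt(n),
    p = z_to_p(z),
    n = n,
    z = z
  )
}

#' Default synthetic scenario
#'
#' A toy-scale analogue of a T2D pleiotropy study: an index trait plus five
#' metabolic traits, twelve 1 Mbp regions of 150 variants with AR(1) LD,
#' and three planted pathway clusters defined by which traits share the
#' index trait's causal variant and with what sign:
#' adiposity (`bmi +, vat +`), lipid (`tg +, hdl -`), glycemic (`fg +`).
#' Regions 1-4 are adiposity, 5-7 lipid, 8-10 glycemic; region 4 carries a
#' second, trait-private index signal (a two-signal region); regions 11-12
#' are null. Trait sample sizes straddle the 60,000 significance-gate
#' threshold. 5% of non-causal variants are planted as ambiguous
#' palindromic (A/T, EAF near 0.5).
#'
#' @param seed Integer seed stored in the scenario (all scenario
#'   randomness derives from it).
#' @param n_regions,variants_per_region,ld_rho Scenario shape parameters.
#' @param lambda Non-centrality of planted causal variants on the z scale
#'   (default 8, a strong GWAS signal).
#' @return A `scenario_spec` list consumed by [make_scenario()].
#' @export
default_scenario <- function(seed = 42L, n_regions = 12L,
                             variants_per_region = 150L, ld_rho = 0.8,
                             lambda = 8) {
  traits <- data.table::data.table(
    label = c("t2d", "bmi", "vat", "tg", "hdl", "fg", "hba"),
    n = c(150000L, 100000L, 40000L, 120000L, 50000L, 80000L, 70000L),
    is_binary = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  # each planted pathway is defined by >= 2 traits, mirroring cluster
  # signatures seen in pleiotropy studies (adiposity-only positives,
  # lipid trade-off, glucose-trait positives)
  cluster_plan <- list(
    adiposity = c(bmi = 1, vat = 1, tg = 0, hdl = 0, fg = 0, hba = 0),
    lipid     = c(bmi = 0, vat = 0, tg = 1, hdl = -1, fg = 0, hba = 0),
    glycemic  = c(bmi = 0, vat = 0, tg = 0, hdl = 0, fg = 1, hba = 1)
  )
  region_cluster <- c(rep("adiposity", 4), rep("lipid", 3),
                      rep("glycemic", 3), rep("null", 2))
  length(region_cluster) <- n_regions
  region_cluster[is.na(region_cluster)] <- "null"
  # one region per pathway colocalizes with only the first signature
  # trait: loci supported by part of their pathway's signature are a
  # regular feature of sparse colocalization maps, and they give the
  # variant network its moderately-correlated periphery
  partial_regions <- c(1L, 5L, 8L)
  partial_regions <- partial_regions[partial_regions <= n_regions]
  causal_index <- as.integer(min(75L, variants_per_region %/% 2))
  second_signal_region <- 4L
  structure(list(
    n_regions = n_regions,
    variants_per_region = variants_per_region,
    ld_rho = ld_rho,
    traits = traits,
    index_trait = "t2d",
    lambda = lambda,
    causal_index = causal_index,
    region_cluster = region_cluster,
    cluster_plan = cluster_plan,
    partial_regions = partial_regions,
    second_signal_region = second_signal_region,
    second_signal_index = as.integer(max(1L, variants_per_region %/% 10)),
    palindromic_rate = 0.05,
    seed = as.integer(seed)
  ), class = "scenario_spec")
}

#' Materialize a synthetic scenario on disk
#'
#' Writes, under `out_dir`: one `sumstats_<trait>.tsv` per trait (canonical
#' [read_sumstats()] columns), `leads.tsv` (`SNP, CHR, POS, REGION_ID`),
#' `ld/region_<id>.tsv` LD matrices, and `truth.tsv` recording for each
#' region its planted cluster, causal variant, and which traits share it.
#' Byte-identical for a fixed `spec$seed`.
#'
#' @param spec A [default_scenario()]-style `scenario_spec`.
#' @param out_dir Output directory (created).
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, the scenario truth table (`data.table`).
#' @export
make_scenario <- function(spec = default_scenario(), out_dir,
                          force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory ", out_dir, " is non-empty; use force = TRUE")
  }
  dir.create(file.path(out_dir, "ld"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(spec$seed)
  m <- spec$variants_per_region
  traits <- spec$traits
  per_trait <- setNames(vector("list", nrow(traits)), traits$label)
  leads <- list(); truth <- list()

  for (rg in seq_len(spec$n_regions)) {
    chrom <- as.character(rg)
    ids <- sprintf("rs%d_%03d", rg, seq_len(m))
    ld <- simulate_ld(m, spec$ld_rho, ids = ids)
    write_ld_matrix(ld, file.path(out_dir, "ld",
                                  sprintf("region_%d.tsv", rg)))
    eafs <- runif(m, 0.05, 0.95)
    ea <- sample(c("A", "C"), m, replace = TRUE)
    alleles <- cbind(ea, ifelse(ea == "A", "G", "T"))  # A/G, C/T: unambiguous
    # plant ambiguous palindromic variants among non-causal positions
    protected <- c(spec$causal_index, spec$second_signal_index)
    pal <- which(runif(m) < spec$palindromic_rate &
                   !(seq_len(m) %in% protected))
    alleles[pal, ] <- cbind(rep("A", length(pal)), rep("T", length(pal)))
    eafs[pal] <- runif(length(pal), 0.42, 0.58)

    cl <- spec$region_cluster[rg]
    sig <- if (cl == "null") NULL else spec$cluster_plan[[cl]]
    if (!is.null(sig) && rg %in% (spec$partial_regions %||% integer(0))) {
      nz <- which(sig != 0)
      sig[nz[-1]] <- 0            # keep only the first signature trait
    }
    for (ti in seq_len(nrow(traits))) {
      lab <- traits$label[ti]
      lambdas <- numeric(m)
      if (!is.null(sig)) {
        if (lab == spec$index_trait) {
          lambdas[spec$causal_index] <- spec$lambda
        } else if (sig[lab] != 0) {
          lambdas[spec$causal_index] <- spec$lambda * sig[lab]
        }
      }
      if (!is.na(spec$second_signal_region) &&
          rg == spec$second_signal_region && lab == spec$index_trait) {
        lambdas[spec$second_signal_index] <- spec$lambda
      }
      ss <- simulate_region_sumstats(ld, lambdas, traits$n[ti],
                                     eafs = eafs, chrom = chrom,
                                     alleles = alleles)
      per_trait[[lab]] <- c(per_trait[[lab]], list(ss))
    }
    lead_row <- data.table::data.table(
      SNP = ids[spec$causal_index], CHR = chrom,
      POS = 1e6L + 1000L * (spec$causal_index - 1L),
      REGION_ID = as.character(rg))
    if (!is.na(spec$second_signal_region) &&
        rg == spec$second_signal_region) {
      lead_row <- rbind(lead_row, data.table::data.table(
        SNP = ids[spec$second_signal_index], CHR = chrom,
        POS = 1e6L + 1000L * (spec$second_signal_index - 1L),
        REGION_ID = as.character(rg)))
    }
    leads[[rg]] <- lead_row
    shared <- if (is.null(sig)) character(0) else names(sig)[sig != 0]
    truth[[rg]] <- data.table::data.table(
      region_id = as.character(rg),
      cluster = cl,
      causal_snp = ids[spec$causal_index],
      colocalized = cl != "null",
      shared_traits = paste(shared, collapse = ","),
      signature = if (is.null(sig)) "" else
        paste(sprintf("%s:%+d", names(sig)[sig != 0], sig[sig != 0]),
              collapse = ",")
    )
  }

  for (lab in names(per_trait)) {
    dt <- data.table::rbindlist(per_trait[[lab]])
    out <- dt[, .(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
                  EAF = round(eaf, 6), BETA = signif(beta, 8),
                  SE = signif(se, 8), P = signif(p, 8), N = n)]
    data.table::fwrite(out, file.path(out_dir,
                                      sprintf("sumstats_%s.tsv", lab)),
                       sep = "\t")
  }
  data.table::fwrite(data.table::rbindlist(leads),
                     file.path(out_dir, "leads.tsv"), sep = "\t")
  truth <- data.table::rbindlist(truth)
  data.table::fwrite(truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  invisible(truth)
}

#' Simulate a sparse variant-by-trait z matrix with planted clusters
#'
#' Each planted cluster has a trait-signature vector of mean z effects;
#' cluster members get `signature + noise` on the signature's nonzero
#' traits and exactly 0 elsewhere (emulating the significance-gated sparse
#' matrix the network stage consumes). The first `n_partial` members of
#' each cluster carry only part of the signature (all but its last
#' nonzero trait): in real data not every variant of a pathway
#' colocalizes with every signature trait, and these partially-supported
#' variants are what give the variant network its moderately-correlated
#' periphery.
#'
#' @param cluster_plan Named list of signature vectors (named by trait) of
#'   mean z values; see [default_scenario()] for shape.
#' @param n_per_cluster Variants per cluster (scalar or per-cluster).
#' @param effect Mean |z| of nonzero signature entries (default 8).
#' @param noise_sd Gaussian noise added to nonzero entries (default 1).
#' @param n_partial Partial-signature variants per cluster (default 1;
#'   ignored for single-trait signatures).
#' @return A list with the `zmatrix` (see [build_zmatrix()]) and the truth
#'   `membership` vector.
#' @export
simulate_zmatrix <- function(cluster_plan, n_per_cluster = 10L,
                             effect = 8, noise_sd = 1, n_partial = 1L) {
  k <- length(cluster_plan)
  sizes <- rep_len(n_per_cluster, k)
  traits <- names(cluster_plan[[1]])
  rows <- list(); membership <- character(0); ids <- character(0)
  for (ci in seq_len(k)) {
    sig <- cluster_plan[[ci]][traits]
    for (j in seq_len(sizes[ci])) {
      z <- numeric(length(traits))
      nz <- which(sig != 0)
      if (j <= n_partial && length(nz) > 1L) {
        nz <- nz[-length(nz)]
      }
      z[nz] <- effect * sig[nz] + rnorm(length(nz), sd = noise_sd)
      rows <- c(rows, list(z))
      membership <- c(membership, names(cluster_plan)[ci])
      ids <- c(ids, sprintf("%s_%d", names(cluster_plan)[ci], j))
    }
  }
  values <- do.call(rbind, rows)
  dimnames(values) <- list(ids, traits)
  zm <- structure(list(variants = ids, traits = traits, values = values),
                  class = "zmatrix")
  list(zmatrix = zm, membership = setNames(membership, ids))
}

#' Simulate an individual-level cohort scored by a planted genetic score
#'
#' Dosages are Binomial(2, eaf); the continuous outcome is
#' `effect_on_outcome * standardized_true_score + covariate terms + N(0,1)`;
#' the binary outcome uses a logistic link with an intercept set to the
#' requested prevalence.
#'
#' @param n_ind Number of individuals.
#' @param variants `data.table`/`data.frame` with columns `snp` and `eaf`.
#' @param true_weights Named (by snp) or positional weight vector defining
#'   the true score.
#' @param effect_on_outcome Effect of one SD of true score on the
#'   continuous outcome (outcome-SD units before noise).
#' @param covariate_effects Named vector of effects for covariates
#'   `age, sex, bmi, cohort2, cohort3` (missing names mean 0).
#' @param binary_prevalence Baseline prevalence of the binary outcome.
#' @return A `cohort`: list with `dosages` (matrix, columns named by snp),
#'   `phenotypes` (`y_cont`, `y_bin`), `covariates`
#'   (`age, sex, bmi, cohort`), and the latent standardized `true_score`.
#' @export
simulate_cohort <- function(n_ind, variants, true_weights,
                            effect_on_outcome = 0,
                            covariate_effects = c(age = 0.01, sex = 0.1),
                            binary_prevalence = 0.1) {
  variants <- data.table::as.data.table(variants)
  mvar <- nrow(variants)
  stopifnot(n_ind >= 8, length(true_weights) == mvar)
  dos <- matrix(rbinom(n_ind * mvar, 2L, rep(variants$eaf, each = n_ind)),
                nrow = n_ind, ncol = mvar,
                dimnames = list(NULL, variants$snp))
  raw <- as.vector(dos %*% as.numeric(true_weights))
  score <- if (sd(raw) > 0) as.vector(scale(raw)) else raw
  covariates <- data.table::data.table(
    age = rnorm(n_ind, 60, 10),
    sex = rbinom(n_ind, 1L, 0.5),
    bmi = rnorm(n_ind, 28, 4),
    cohort = factor(sample(1:3, n_ind, replace = TRUE))
  )
  getce <- function(nm) {
    v <- covariate_effects[nm]
    if (is.na(v)) 0 else unname(v)
  }
  lin_cov <- getce("age") * (covariates$age - 60) +
    getce("sex") * covariates$sex +
    getce("bmi") * (covariates$bmi - 28) +
    getce("cohort2") * (covariates$cohort == 2) +
    getce("cohort3") * (covariates$cohort == 3)
  y_cont <- effect_on_outcome * score + lin_cov + rnorm(n_ind)
  eta <- qlogis(binary_prevalence) + effect_on_outcome * score + lin_cov
  y_bin <- rbinom(n_ind, 1L, plogis(eta))
  structure(list(
    dosages = dos,
    phenotypes = data.table::data.table(y_cont = y_cont, y_bin = y_bin),
    covariates = covariates,
    true_score = score
  ), class = "cohort")
}
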