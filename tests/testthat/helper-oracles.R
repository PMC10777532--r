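# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# exhaustive scan over all candidate cutoffs: largest c such that the
# graph with edges {|corr| >= c} has minimum degree >= 1
brute_min_degree_threshold <- function(corr) {
  a <- abs(corr)
  diag(a) <- 0
  cands <- sort(unique(a[upper.tri(a)]), decreasing = TRUE)
  cands <- cands[cands > 0]
  for (c in cands) {
    adj <- a >= c
    diag(adj) <- FALSE
    if (all(rowSums(adj) >= 1)) return(c)
  }
  stop("no cutoff leaves all vertices connected")
}

# textbook double-sum modularity: (1/2W) * sum_ij (A_ij - d_i d_j / 2W)
# over pairs in the same community
brute_modularity <- function(adj, membership) {
  W2 <- sum(adj)
  if (W2 == 0) return(0)
  d <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + adj[i, j] - d[i] * d[j] / W2
      }
    }
  }
  q / W2
}

# textbook Pearson correlation from the sum formulas
brute_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# two unit-weight triangles joined by one bridge edge
two_triangle_adj <- function() {
  adj <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- 1
    adj[edges[k, 2], edges[k, 1]] <- 1
  }
  adj
}

# minimal summary-statistic table in read_sumstats() layout
make_stats <- function(snp, beta, se, ea = "A", oa = "G", eaf = 0.3,
                       chr = "1", pos = NULL, n = 50000) {
  m <- length(snp)
  data.table::data.table(
    snp = snp, chr = rep_len(chr, m),
    pos = pos %||% seq_len(m) * 1000L,
    ea = rep_len(ea, m), oa = rep_len(oa, m),
    eaf = rep_len(eaf, m),
    beta = beta, se = rep_len(se, m),
    p = 2 * stats::pnorm(-abs(beta / rep_len(se, m))),
    n = rep_len(n, m), z = beta / rep_len(se, m)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-assembled region panel (bypasses harmonize_region)
make_panel <- function(stats_list, ld, index_trait = names(stats_list)[1],
                       region = NULL) {
  structure(list(region = region, traits = names(stats_list),
                 index_trait = index_trait, stats = stats_list, ld = ld,
                 n_mismatched = 0L),
            class = "region_panel")
}

# z-scale region simulation for calibration experiments: one draw of z
# given an LD cholesky factor and non-centrality vector
draw_region_z <- function(chol_r, r, lambdas) {
  as.vector(r %*% lambdas) +
    as.vector(crossprod(chol_r, stats::rnorm(nrow(r))))
}

z_to_stats <- function(z, ids, n) {
  make_stats(ids, beta = z / sqrt(n), se = 1 / sqrt(n), n = n)
}
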