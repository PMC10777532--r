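#' Z-matrix gating configuration
#'
#' @param p_gate_large P-value gate for traits with GWAS sample size above
#'   `n_threshold` (default 5e-8, genome-wide significance).
#' @param p_gate_small Gate for smaller GWAS (default 1e-5).
#' @param n_threshold Sample-size threshold separating the two gates
#'   (default 60000).
#' @return A list of class `zmatrix_config`.
#' @export
zmatrix_config <- function(p_gate_large = 5e-8, p_gate_small = 1e-5,
                           n_threshold = 60000) {
  stopifnot(p_gate_large < p_gate_small, n_threshold > 0)
  structure(list(p_gate_large = p_gate_large, p_gate_small = p_gate_small,
                 n_threshold = n_threshold), class = "zmatrix_config")
}

#' Build the sparse variant-by-trait z matrix from colocalization events
#'
#' Rows are event lead variants, columns are (non-index) traits. An entry
#' holds the trait's z-score at the lead variant — aligned to the index
#' trait's effect-increasing allele by harmonization — only when that
#' variant colocalized with the trait and the association passes the
#' sample-size-dependent significance gate; all other entries are exactly
#' 0.
#'
#' @param events List of accepted `coloc_event`s carrying `lead` and
#'   `traits`.
#' @param stats_lookup Named (by trait) list of harmonized
#'   summary-statistic tables covering all event leads (columns
#'   `snp, z, p, n`).
#' @param cfg A [zmatrix_config()].
#' @param index_trait Trait excluded from the columns (the anchor trait).
#' @return A `zmatrix`: list with `variants`, `traits`, and the numeric
#'   `values` matrix.
#' @export
build_zmatrix <- function(events, stats_lookup, cfg = zmatrix_config(),
                          index_trait = NULL) {
  stopifnot(length(events) > 0)
  leads <- unique(vapply(events, function(e) e$lead, character(1)))
  traits <- setdiff(names(stats_lookup), index_trait)
  values <- matrix(0, length(leads), length(traits),
                   dimnames = list(leads, traits))
  for (ev in events) {
    for (tr in intersect(ev$traits, traits)) {
      dt <- stats_lookup[[tr]]
      i <- match(ev$lead, dt$snp)
      if (is.na(i)) {
        stop("lead variant ", ev$lead, " not found in trait ", tr)
      }
      gate <- if (dt$n[i] > cfg$n_threshold) cfg$p_gate_large
              else cfg$p_gate_small
      if (dt$p[i] < gate) values[ev$lead, tr] <- dt$z[i]
    }
  }
  structure(list(variants = leads, traits = traits, values = values),
            class = "zmatrix")
}

#' Pearson correlation between variant rows of a z matrix
#'
#' Zeros are treated as values (they carry the "not colocalized /
#' not significant" information). Variants whose row has zero variance get
#' correlation 0 to all others (logged).
#'
#' @param zmat A `zmatrix`.
#' @return Square correlation matrix over variants (unit diagonal).
#' @export
snp_correlation <- function(zmat) {
  stopifnot(length(zmat$traits) >= 2)
  v <- apply(zmat$values, 1, var)
  cc <- suppressWarnings(cor(t(zmat$values)))
  if (any(v == 0)) {
    message("snp_correlation: zero-variance row(s): ",
            paste(zmat$variants[v == 0], collapse = ", "))
    cc[v == 0, ] <- 0
    cc[, v == 0] <- 0
  }
  diag(cc) <- 1
  dimnames(cc) <- list(zmat$variants, zmat$variants)
  cc
}

#' Highest edge-weight cutoff preserving minimum degree 1
#'
#' Scans the unique absolute off-diagonal correlations and returns the
#' largest cutoff `c` such that the graph with edges `|corr| >= c` leaves
#' every vertex with at least one edge. Equivalently, the minimum over
#' vertices of each vertex's largest absolute off-diagonal correlation.
#' Vertices with all-zero correlations are reported and excluded before
#' the search.
#'
#' @param corr Square (symmetric) correlation matrix.
#' @return The cutoff, with attribute `excluded` naming any all-zero
#'   vertices.
#' @export
min_degree_threshold <- function(corr) {
  a <- abs(corr)
  diag(a) <- NA
  row_max <- apply(a, 1, max, na.rm = TRUE)
  excluded <- rownames(corr)[row_max == 0] %||% which(row_max == 0)
  if (length(excluded) && any(row_max == 0)) {
    message("min_degree_threshold: excluding isolated vertex(es): ",
            paste(excluded, collapse = ", "))
  }
  keep <- row_max > 0
  if (sum(keep) < 2) stop("fewer than 2 connectable vertices")
  cutoff <- min(row_max[keep])
  attr(cutoff, "excluded") <- if (any(!keep)) excluded else character(0)
  cutoff
}

#' Spinglass clustering configuration
#'
#' @param gamma Spinglass resolution parameter (default 1.0).
#' @param n_restarts Independent annealing runs; the maximum-modularity
#'   run wins (default 20).
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param start_temp,stop_temp,cool_fact Annealing temperature schedule.
#' @param min_cluster_size Smallest cluster retained for downstream
#'   scoring (default 4; smaller clusters stay in the membership but are
#'   flagged unretained).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(gamma = 1.0, n_restarts = 20L, seed = 1L,
                           start_temp = 1, stop_temp = 0.01,
                           cool_fact = 0.99, min_cluster_size = 4L) {
  stopifnot(min_cluster_size >= 1, cool_fact > 0, cool_fact < 1)
  structure(list(gamma = gamma, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), start_temp = start_temp,
                 stop_temp = stop_temp, cool_fact = cool_fact,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_config")
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ w_c / W - (d_c / 2W)^2 ]` with `W` the total edge weight,
#' `w_c` the weight inside community `c`, and `d_c` the summed weighted
#' degree of its members.
#'
#' @param adj Symmetric non-negative weighted adjacency matrix (zero
#'   diagonal).
#' @param membership Community labels, one per node.
#' @return Modularity `Q`.
#' @export
modularity_q <- function(adj, membership) {
  stopifnot(nrow(adj) == length(membership))
  W <- sum(adj) / 2
  if (W == 0) return(0)
  d <- rowSums(adj)
  q <- 0
  for (cl in unique(membership)) {
    i <- membership == cl
    w_c <- sum(adj[i, i, drop = FALSE]) / 2
    d_c <- sum(d[i])
    q <- q + w_c / W - (d_c / (2 * W))^2
  }
  q
}

#' Spinglass community detection on the pruned correlation network
#'
#' Prunes edges with `|corr| < cutoff`, clips surviving negative-weight
#' edges to 0 (the spinglass null model requires non-negative weights),
#' and minimizes the Reichardt-Bornholdt Hamiltonian by simulated
#' annealing (via igraph) with `n_restarts` independent seeded runs,
#' keeping the maximum-modularity partition. Disconnected components are
#' clustered independently with offset labels. The number of communities
#' is emergent.
#'
#' @param corr Square correlation matrix over variants.
#' @param cutoff Edge threshold (edges with `|corr| >= cutoff` kept), e.g.
#'   from [min_degree_threshold()].
#' @param cfg A [cluster_config()].
#' @return A `cluster_solution`: list with `membership` (named integer
#'   vector), `k`, `modularity` (Q on the pruned positive-weight graph),
#'   `cutoff`, `retained` (labels of clusters with at least
#'   `min_cluster_size` members), and `sizes`.
#' @export
spinglass_cluster <- function(corr, cutoff, cfg = cluster_config()) {
  n <- nrow(corr)
  ids <- rownames(corr) %||% paste0("n", seq_len(n))
  adj <- corr
  adj[abs(adj) < cutoff] <- 0
  diag(adj) <- 0
  adj[adj < 0] <- 0          # clip negative weights for the null model
  if (sum(adj) == 0) stop("pruned graph has no edges")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    message("spinglass_cluster: ", comp$no,
            " components clustered independently")
  }
  membership <- integer(n)
  offset <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1L || comp$csize[ci] < 2L) {
      membership[vs] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, vs)
    sub_adj <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                                     sparse = FALSE))
    best <- NULL
    best_q <- -Inf
    for (i in seq_len(cfg$n_restarts)) {
      set.seed(cfg$seed + i - 1L)
      cm <- tryCatch(
        igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                  gamma = cfg$gamma,
                                  start.temp = cfg$start_temp,
                                  stop.temp = cfg$stop_temp,
                                  cool.fact = cfg$cool_fact),
        error = function(e) NULL)
      if (is.null(cm)) next
      q <- modularity_q(sub_adj, igraph::membership(cm))
      if (q > best_q) {
        best_q <- q
        best <- igraph::membership(cm)
      }
    }
    if (is.null(best)) best <- rep(1L, length(vs))
    membership[vs] <- offset + as.integer(best)
    offset <- offset + max(as.integer(best))
  }
  # components are annealed with a component-local null model, which can
  # over-split relative to the whole-graph objective; accept merges that
  # improve global modularity
  membership <- merge_communities(adj, membership)
  names(membership) <- ids
  sizes <- table(membership)
  retained <- as.integer(names(sizes)[sizes >= cfg$min_cluster_size])
  structure(list(
    membership = membership,
    k = length(sizes),
    modularity = modularity_q(adj, membership),
    cutoff = as.numeric(cutoff),
    retained = retained,
    sizes = sizes
  ), class = "cluster_solution")
}

# greedy agglomeration: repeatedly merge the community pair whose merge
# most increases whole-graph modularity, until no merge improves it
merge_communities <- function(adj, membership) {
  repeat {
    labs <- unique(membership)
    if (length(labs) < 2L) return(membership)
    q0 <- modularity_q(adj, membership)
    best_gain <- 0
    best_pair <- NULL
    for (a in seq_along(labs)) {
      for (b in seq_len(a - 1L)) {
        trial <- membership
        trial[trial == labs[b]] <- labs[a]
        gain <- modularity_q(adj, trial) - q0
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_pair <- c(labs[a], labs[b])
        }
      }
    }
    if (is.null(best_pair)) return(membership)
    membership[membership == best_pair[2]] <- best_pair[1]
  }
}

#' Per-cluster trait signature table
#'
#' Mean z per (retained cluster, trait), sorted by cluster then trait.
#'
#' @param zmat A `zmatrix`.
#' @param solution A `cluster_solution` over the same variants.
#' @return A `data.table` with columns `cluster, trait, mean_z` (empty,
#'   with header, when no cluster is retained).
#' @export
summarize_clusters <- function(zmat, solution) {
  out <- data.table::data.table(cluster = integer(0), trait = character(0),
                                mean_z = numeric(0))
  for (cl in sort(solution$retained)) {
    vs <- names(solution$membership)[solution$membership == cl]
    sub <- zmat$values[zmat$variants %in% vs, , drop = FALSE]
    out <- rbind(out, data.table::data.table(
      cluster = cl, trait = zmat$traits, mean_z = colMeans(sub)))
  }
  data.table::setorder(out, cluster, trait)
  out[]
}
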