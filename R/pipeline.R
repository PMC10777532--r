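#' Run the colocalization-to-clusters pipeline on an on-disk scenario
#'
#' Reads a scenario directory in the layout written by [make_scenario()]
#' (per-trait `sumstats_<trait>.tsv`, `leads.tsv`, `ld/region_<id>.tsv`),
#' then for every lead: extracts the 1 Mbp region across traits,
#' harmonizes allele orientation to the index trait, removes ambiguous
#' palindromic variants, and runs the staged colocalization workflow.
#' Accepted events feed the sparse variant-by-trait z matrix, the
#' variant correlation network, the minimum-degree edge threshold, and
#' spinglass community detection.
#'
#' @param dir Scenario directory.
#' @param index_trait Anchor trait label (default `"t2d"`).
#' @param priors A [coloc_priors()].
#' @param zcfg A [zmatrix_config()].
#' @param ccfg A [cluster_config()].
#' @param susie_cfg List of [susie_rss()] arguments for stage B.
#' @param window Region flank in bp (default 500000).
#' @return A list with `events`, `zmat`, `corr`, `cutoff`, `solution`,
#'   `signatures`, `regions`, `stats_lookup` (harmonized per-trait stats
#'   at event leads), and `log`. Network elements are `NULL` when fewer
#'   than 2 event variants survive.
#' @export
run_pipeline <- function(dir, index_trait = "t2d",
                         priors = coloc_priors(),
                         zcfg = zmatrix_config(),
                         ccfg = cluster_config(),
                         susie_cfg = list(L = 10),
                         window = 5e5) {
  ss_files <- list.files(dir, pattern = "^sumstats_.*\\.tsv$",
                         full.names = TRUE)
  traits <- sub("^sumstats_(.*)\\.tsv$", "\\1", basename(ss_files))
  stopifnot(index_trait %in% traits)
  sumstats <- setNames(lapply(ss_files, read_sumstats), traits)

  leads_raw <- data.table::fread(file.path(dir, "leads.tsv"))
  data.table::setnames(leads_raw, tolower(names(leads_raw)))
  regions <- define_regions(leads_raw, window = window)

  events <- list()
  log <- character(0)
  harmonized <- list()  # per-trait stacks of harmonized records

  for (i in seq_len(nrow(regions))) {
    rg <- as.list(regions[i])
    ld <- read_ld_matrix(file.path(dir, "ld",
                                   sprintf("region_%s.tsv", rg$region_id)))
    per_trait <- lapply(sumstats, function(dt) {
      dt[chr == rg$chr & pos >= rg$start & pos <= rg$end]
    })
    panel <- harmonize_region(per_trait, index_trait, ld, region = rg)
    if (is.null(panel)) {
      log <- c(log, sprintf("region %s: empty harmonized panel",
                            rg$region_id))
      next
    }
    panel <- resolve_palindromic(panel)
    res <- run_region_workflow(panel, priors, susie_cfg)
    events <- c(events, res$events)
    log <- c(log, res$log)
    for (tr in panel$traits) {
      harmonized[[tr]] <- c(harmonized[[tr]], list(panel$stats[[tr]]))
    }
  }

  stats_lookup <- lapply(harmonized, function(lst) {
    unique(data.table::rbindlist(lst), by = "snp")
  })

  # overlapping region specs can rediscover the same event; keep one copy
  if (length(events) > 1L) {
    key <- vapply(events, function(e) {
      paste(e$region_id %||% "", e$lead,
            paste(sort(e$traits), collapse = ","), sep = "|")
    }, character(1))
    events <- events[!duplicated(key)]
  }

  out <- list(events = events, regions = regions,
              stats_lookup = stats_lookup, log = log,
              zmat = NULL, corr = NULL, cutoff = NULL, solution = NULL,
              signatures = NULL)
  if (length(events) == 0L) return(out)

  out$zmat <- build_zmatrix(events, stats_lookup, zcfg,
                            index_trait = index_trait)
  if (length(out$zmat$variants) >= 2L) {
    out$corr <- snp_correlation(out$zmat)
    out$cutoff <- min_degree_threshold(out$corr)
    keep <- setdiff(rownames(out$corr), attr(out$cutoff, "excluded"))
    out$solution <- spinglass_cluster(
      out$corr[keep, keep, drop = FALSE], out$cutoff, ccfg)
    out$signatures <- summarize_clusters(out$zmat, out$solution)
  }
  out
}

#' Tabulate accepted colocalization events
#'
#' @param events List of `coloc_event`s (e.g. `run_pipeline(...)$events`).
#' @return A `data.table` with one row per event: `region_id, method,
#'   traits` (comma-joined), `lead`, `pp_h4` (pairwise methods), `pr, pa`
#'   (multi-trait), `min_trait_p`.
#' @export
events_table <- function(events) {
  if (length(events) == 0L) {
    return(data.table::data.table(
      region_id = character(0), method = character(0),
      traits = character(0), lead = character(0), pp_h4 = numeric(0),
      pr = numeric(0), pa = numeric(0), min_trait_p = numeric(0)))
  }
  data.table::rbindlist(lapply(events, function(e) {
    data.table::data.table(
      region_id = e$region_id %||% NA_character_,
      method = e$method,
      traits = paste(e$traits, collapse = ","),
      lead = e$lead,
      pp_h4 = if (!is.null(e$pp)) unname(e$pp[["PP.H4"]]) else NA_real_,
      pr = e$pr %||% NA_real_,
      pa = e$pa %||% NA_real_,
      min_trait_p = e$min_trait_p %||% NA_real_)
  }))
}
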