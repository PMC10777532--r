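#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a per-trait summary-statistic table, maps column names to the
#' canonical set, validates rows, and computes the z statistic. Canonical
#' columns are `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (effect allele
#' `EA`, other allele `OA`, effect-allele frequency `EAF`).
#'
#' Rows with missing `BETA` or `SE`, or with `SE <= 0`, are dropped and
#' counted in the `n_rejected` attribute. Alleles are upper-cased.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(SNP = "rsid", BETA = "effect")`. Unmapped
#'   canonical names are assumed to be present verbatim.
#' @return A `data.table` with lower-case canonical columns
#'   (`snp, chr, pos, ea, oa, eaf, beta, se, p, n, z`), in file order, with
#'   attribute `n_rejected`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  canonical <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canonical)
    if (length(bad)) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- map[!map %in% names(dt)]
  if (length(missing_cols)) {
    stop("mapped column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- dt[, unname(map), with = FALSE]
  data.table::setnames(out, tolower(canonical))
  out[, `:=`(snp = as.character(snp), chr = as.character(chr),
             pos = as.integer(pos), ea = toupper(ea), oa = toupper(oa),
             beta = as.numeric(beta), se = as.numeric(se),
             eaf = as.numeric(eaf), p = as.numeric(p), n = as.numeric(n))]
  n_in <- nrow(out)
  out <- out[is.finite(beta) & is.finite(se) & se > 0]
  n_rejected <- n_in - nrow(out)
  if (n_rejected > 0) {
    message(n_rejected, " row(s) dropped (missing beta/se or se <= 0) in ",
            path)
  }
  out[, z := beta / se]
  data.table::setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Define analysis regions around lead variants
#'
#' Builds one closed 1-based interval `[start, end]` per lead variant,
#' extending `window` bp on either side (start clamped at 1), and counts how
#' many of the supplied leads fall inside each interval on the same
#' chromosome (`n_signals`, the number of conditionally independent signals
#' the region will be treated as containing).
#'
#' @param leads A `data.frame`/`data.table` with columns `snp, chr, pos` and
#'   optionally `region_id` (carried through; defaults to the lead SNP id).
#' @param window Flank size in bp on each side of the lead (default 500000,
#'   i.e. a 1 Mbp region).
#' @return A `data.table` with columns
#'   `region_id, snp, chr, pos, start, end, n_signals`.
#' @export
define_regions <- function(leads, window = 5e5) {
  leads <- data.table::as.data.table(leads)
  if (nrow(leads) == 0L) stop("leads must be non-empty")
  stopifnot(all(c("snp", "chr", "pos") %in% names(leads)))
  out <- data.table::data.table(
    region_id = if ("region_id" %in% names(leads))
      as.character(leads$region_id) else as.character(leads$snp),
    snp = as.character(leads$snp),
    chr = as.character(leads$chr),
    pos = as.integer(leads$pos)
  )
  out[, start := pmax(1L, pos - as.integer(window))]
  out[, end := pos + as.integer(window)]
  out[, n_signals := vapply(seq_len(.N), function(i) {
    sum(out$chr == out$chr[i] & out$pos >= out$start[i] &
          out$pos <= out$end[i])
  }, integer(1))]
  out[]
}

# flip a block of records to the opposite allele orientation
flip_records <- function(dt, idx) {
  if (!length(idx)) return(dt)
  tmp <- dt$ea[idx]
  dt$ea[idx] <- dt$oa[idx]
  dt$oa[idx] <- tmp
  dt$beta[idx] <- -dt$beta[idx]
  dt$z[idx] <- -dt$z[idx]
  dt$eaf[idx] <- 1 - dt$eaf[idx]
  dt
}

#' Harmonize multi-trait summary statistics into a region panel
#'
#' Restricts all traits to their shared variant set, reconciles allele
#' coding against the index trait (identity or effect/other swap only; no
#' strand flips — strand-ambiguous variants are handled separately by
#' [resolve_palindromic()]), and orients every variant to the index trait's
#' effect-increasing allele, flipping all traits consistently.
#'
#' @param per_trait_records Named list of summary-statistic tables (as from
#'   [read_sumstats()]), already restricted to the region.
#' @param index_trait Name of the anchor trait (must be in the list).
#' @param ld An LD matrix object from [ld_matrix()] covering (at least) the
#'   panel variants; panel variant order follows LD order.
#' @param region Optional region row from [define_regions()] (carried
#'   through for bookkeeping).
#' @return A `region_panel`: list with `region`, `traits`, `stats` (named
#'   list of aligned `data.table`s over a common ordered variant set), `ld`
#'   (subset to panel variants), and counters `n_mismatched` (irreconcilable
#'   allele pairs dropped). `NULL` (with a message) if the intersection is
#'   empty.
#' @export
harmonize_region <- function(per_trait_records, index_trait, ld,
                             region = NULL) {
  stopifnot(index_trait %in% names(per_trait_records))
  recs <- lapply(per_trait_records, function(x) {
    data.table::copy(data.table::as.data.table(x))
  })
  idx <- recs[[index_trait]]
  n_mismatched <- 0L

  # reconcile each non-index trait's alleles against the index coding
  for (tr in setdiff(names(recs), index_trait)) {
    dt <- recs[[tr]]
    m <- match(dt$snp, idx$snp)
    keep <- !is.na(m)
    dt <- dt[keep]; m <- m[keep]
    direct <- dt$ea == idx$ea[m] & dt$oa == idx$oa[m]
    swapped <- dt$ea == idx$oa[m] & dt$oa == idx$ea[m]
    n_mismatched <- n_mismatched + sum(!direct & !swapped)
    dt <- flip_records(dt, which(swapped & !direct))
    recs[[tr]] <- dt[direct | swapped]
  }

  common <- Reduce(intersect, lapply(recs, function(x) x$snp))
  if (!length(common)) {
    message("harmonize_region: empty variant intersection; region skipped")
    return(NULL)
  }
  # panel order follows the LD matrix order
  ordered <- ld$variants[ld$variants %in% common]
  if (!length(ordered)) {
    message("harmonize_region: no panel variant present in LD; region skipped")
    return(NULL)
  }
  recs <- lapply(recs, function(dt) dt[match(ordered, dt$snp)])

  # orient to the index trait's effect-increasing allele
  flip <- which(recs[[index_trait]]$beta < 0)
  recs <- lapply(recs, flip_records, idx = flip)

  keep_ld <- match(ordered, ld$variants)
  panel <- list(
    region = region,
    traits = names(recs),
    index_trait = index_trait,
    stats = recs,
    ld = ld_matrix(ld$r[keep_ld, keep_ld, drop = FALSE], ordered),
    n_mismatched = n_mismatched
  )
  class(panel) <- "region_panel"
  panel
}

#' Default harmonization configuration
#'
#' @param palindromic_maf_low,palindromic_maf_high Minor-allele-frequency
#'   band within which a palindromic (A/T or C/G) variant is considered
#'   strand-ambiguous and removed (defaults 0.40 and 0.60).
#' @param proxy_r2_min Minimum LD r-squared for substituting a proxy when a
#'   removed variant is a region lead (default 0.80).
#' @return A list of class `harmonize_config`.
#' @export
harmonize_config <- function(palindromic_maf_low = 0.40,
                             palindromic_maf_high = 0.60,
                             proxy_r2_min = 0.80) {
  stopifnot(palindromic_maf_low >= 0, palindromic_maf_high <= 1,
            palindromic_maf_low < palindromic_maf_high,
            proxy_r2_min > 0, proxy_r2_min <= 1)
  structure(list(palindromic_maf_low = palindromic_maf_low,
                 palindromic_maf_high = palindromic_maf_high,
                 proxy_r2_min = proxy_r2_min),
            class = "harmonize_config")
}

#' Remove ambiguous palindromic variants, substituting proxies for leads
#'
#' A/T and C/G variants whose minor-allele frequency (from the index trait)
#' lies strictly inside the ambiguity band are removed from the panel. If a
#' removed variant is the region lead, the non-palindromic variant with the
#' highest LD r-squared to it is substituted as lead provided
#' `r2 > proxy_r2_min`; otherwise the lead is flagged dropped. Variants with
#' missing frequency are exempt from the palindromic rule (retained).
#'
#' @param panel A `region_panel` from [harmonize_region()].
#' @param cfg A [harmonize_config()].
#' @return The filtered `region_panel`; `panel$region$snp` may have been
#'   replaced by a proxy, `panel$lead_dropped` set if no proxy qualified,
#'   and `panel$n_palindromic_removed` records the removal count.
#' @export
resolve_palindromic <- function(panel, cfg = harmonize_config()) {
  idx <- panel$stats[[panel$index_trait]]
  maf <- pmin(idx$eaf, 1 - idx$eaf)
  ambiguous <- is_palindromic(idx$ea, idx$oa) & !is.na(maf) &
    maf > cfg$palindromic_maf_low & maf < cfg$palindromic_maf_high
  panel$n_palindromic_removed <- sum(ambiguous)
  if (!any(ambiguous)) return(panel)

  removed_ids <- idx$snp[ambiguous]
  lead_snp <- panel$region$snp %||% NA_character_
  if (!is.na(lead_snp) && lead_snp %in% removed_ids) {
    r <- panel$ld$r[match(lead_snp, panel$ld$variants), ]
    r2 <- r^2
    r2[ambiguous] <- -Inf            # proxies must be non-palindromic
    r2[idx$snp == lead_snp] <- -Inf
    best <- which.max(r2)
    if (length(best) && r2[best] > cfg$proxy_r2_min) {
      panel$region$snp <- idx$snp[best]
      panel$region$pos <- idx$pos[best]
      message("resolve_palindromic: lead ", lead_snp,
              " replaced by proxy ", idx$snp[best],
              " (r2 = ", signif(r2[best], 3), ")")
    } else {
      panel$lead_dropped <- TRUE
      message("resolve_palindromic: lead ", lead_snp,
              " removed with no qualifying proxy")
    }
  }

  keep <- !ambiguous
  panel$stats <- lapply(panel$stats, function(dt) dt[keep])
  ki <- which(keep)
  panel$ld <- ld_matrix(panel$ld$r[ki, ki, drop = FALSE],
                        panel$ld$variants[ki])
  panel
}

#' Construct an LD matrix object
#'
#' @param r Square matrix of pairwise genotype correlations in `[-1, 1]`;
#'   must be symmetric with unit diagonal.
#' @param variants Character vector of variant ids in matrix order.
#' @return A list of class `ld_matrix` with elements `variants` and `r`.
#' @export
ld_matrix <- function(r, variants) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), length(variants) == nrow(r))
  if (nrow(r) > 0) {
    stopifnot(max(abs(r - t(r))) < 1e-8, max(abs(diag(r) - 1)) < 1e-8)
  }
  dimnames(r) <- list(variants, variants)
  structure(list(variants = as.character(variants), r = r),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV (first row and column are variant ids)
#'
#' @param path Path to a tab-delimited square matrix with variant ids as
#'   both header and first column.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1]])
  r <- as.matrix(dt[, -1, with = FALSE])
  ld_matrix(r, ids)
}

#' Write an LD matrix as TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  dt <- data.table::data.table(SNP = ld$variants)
  m <- data.table::as.data.table(ld$r)
  data.table::setnames(m, ld$variants)
  data.table::fwrite(cbind(dt, m), path, sep = "\t")
  invisible(path)
}
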