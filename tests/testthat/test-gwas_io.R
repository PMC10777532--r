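write_sumstats_file <- function(dt, path) {
  out <- data.table::data.table(
    SNP = dt$snp, CHR = dt$chr, POS = dt$pos, EA = dt$ea, OA = dt$oa,
    EAF = dt$eaf, BETA = dt$beta, SE = dt$se, P = dt$p, N = dt$n)
  data.table::fwrite(out, path, sep = "\t")
  path
}

test_that("read_sumstats computes z, preserves order, and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  dt <- make_stats(sprintf("rs%d", 1:10), beta = seq(0.05, 0.5, by = 0.05),
                   se = 0.1)
  write_sumstats_file(dt, f)
  got <- read_sumstats(f)
  expect_equal(nrow(got), 10)
  expect_equal(got$snp, dt$snp)                  # file order preserved
  expect_equal(got$z, dt$beta / 0.1, tolerance = 1e-12)
  expect_equal(attr(got, "n_rejected"), 0L)

  # se = 0 and missing beta rows are dropped and counted
  bad <- data.table::copy(dt)
  bad$se[3] <- 0
  bad$beta[7] <- NA
  write_sumstats_file(bad, f)
  expect_message(got2 <- read_sumstats(f), "2 row")
  expect_equal(nrow(got2), 8)
  expect_equal(attr(got2, "n_rejected"), 2L)

  # lower-case alleles are upper-cased
  lc <- data.table::copy(dt)
  lc$ea <- "a"; lc$oa <- "g"
  write_sumstats_file(lc, f)
  expect_equal(unique(read_sumstats(f)$ea), "A")
})

test_that("read_sumstats column_map aliases and errors on missing columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  dt <- data.table::data.table(rsid = "rs1", CHR = "1", POS = 100L,
                               EA = "A", OA = "G", EAF = 0.3,
                               effect = 0.1, SE = 0.02, P = 5e-7,
                               N = 50000)
  data.table::fwrite(dt, f, sep = "\t")
  got <- read_sumstats(f, column_map = c(SNP = "rsid", BETA = "effect"))
  expect_equal(got$z, 5)
  expect_error(read_sumstats(f), "not found")
  expect_error(read_sumstats(f, column_map = c(FOO = "bar")), "unknown")
})

test_that("define_regions builds 1 Mbp windows and counts co-lead signals", {
  leads <- data.table::data.table(
    snp = c("a", "b", "c"), chr = c("1", "1", "2"),
    pos = c(1000000L, 1300000L, 200000L))
  rg <- define_regions(leads, window = 500000)
  expect_equal(rg$start, c(500000L, 800000L, 1L))   # third clamped to 1
  expect_equal(rg$end, c(1500000L, 1800000L, 700000L))
  # a and b are 300 kb apart on the same chromosome: both see 2 signals
  expect_equal(rg$n_signals, c(2L, 2L, 1L))

  # brute-force interval membership on random leads
  set.seed(11)
  leads2 <- data.table::data.table(
    snp = sprintf("v%d", 1:40),
    chr = sample(c("1", "2"), 40, replace = TRUE),
    pos = sample.int(3e6, 40))
  rg2 <- define_regions(leads2, window = 400000)
  brute <- vapply(seq_len(40), function(i) {
    sum(leads2$chr == leads2$chr[i] &
          abs(leads2$pos - leads2$pos[i]) <= 400000 &
          leads2$pos >= max(1, leads2$pos[i] - 400000))
  }, integer(1))
  expect_equal(rg2$n_signals, brute)
  expect_error(define_regions(leads[0]), "non-empty")
})

test_that("harmonize_region intersects, reconciles alleles, and orients
           to the index effect-increasing allele", {
  ld <- ld_matrix(diag(4), c("a", "b", "c", "d"))
  idx <- make_stats(c("a", "b", "c"), beta = c(-0.1, 0.2, 0.3), se = 0.1,
                    eaf = 0.3)
  # trait2: variant b allele-swapped relative to the index; extra variant d
  t2 <- make_stats(c("a", "b", "d"), beta = c(0.05, 0.1, 0.2), se = 0.1,
                   eaf = 0.3)
  t2[snp == "b", `:=`(ea = "G", oa = "A", beta = -0.1, eaf = 0.7,
                      z = -1)]
  # trait3 has an irreconcilable allele pair at c
  t3 <- make_stats(c("a", "b", "c"), beta = c(0.1, 0.1, 0.1), se = 0.1,
                   eaf = 0.3)
  t3[snp == "c", `:=`(ea = "T", oa = "C")]

  panel <- harmonize_region(list(t2d = idx, t2 = t2, t3 = t3), "t2d", ld)
  # intersection: {a, b} (d not in index; c dropped from t3)
  expect_equal(panel$stats$t2d$snp, c("a", "b"))
  expect_equal(panel$n_mismatched, 1L)
  # index beta at a was -0.1 with A/G: emitted as G/A with +0.1, eaf 0.7
  a_idx <- panel$stats$t2d[snp == "a"]
  expect_equal(a_idx$beta, 0.1)
  expect_equal(c(a_idx$ea, a_idx$oa), c("G", "A"))
  expect_equal(a_idx$eaf, 0.7)
  # the same flip was applied to every trait at a
  expect_equal(panel$stats$t2[snp == "a"]$beta, -0.05)
  # t2's swapped record at b was reconciled back to index orientation
  expect_equal(panel$stats$t2[snp == "b"]$beta, 0.1)
  expect_equal(panel$stats$t2[snp == "b"]$ea, "A")
  # all index betas are non-negative after orientation
  expect_true(all(panel$stats$t2d$beta >= 0))
})

test_that("harmonization is idempotent and flip-consistent", {
  set.seed(21)
  m <- 20
  ld <- simulate_ld(m, 0.5, ids = sprintf("v%d", 1:m))
  t1 <- make_stats(ld$variants, beta = rnorm(m, 0, 0.05), se = 0.02,
                   eaf = runif(m, 0.1, 0.9))
  t2 <- make_stats(ld$variants, beta = rnorm(m, 0, 0.05), se = 0.02,
                   eaf = runif(m, 0.1, 0.9))
  p1 <- harmonize_region(list(x = t1, y = t2), "x", ld)
  # idempotent: harmonizing the harmonized panel changes nothing
  p2 <- harmonize_region(p1$stats, "x", p1$ld)
  expect_equal(p2$stats, p1$stats)
  # flip consistency: negating all betas and swapping alleles in the
  # input yields an identical panel
  flip_all <- function(dt) {
    out <- data.table::copy(dt)
    out[, `:=`(beta = -beta, z = -z, eaf = 1 - eaf, ea = dt$oa,
               oa = dt$ea)]
    out
  }
  p3 <- harmonize_region(list(x = flip_all(t1), y = flip_all(t2)), "x", ld)
  expect_equal(p3$stats, p1$stats)
  # panel variant order matches the LD matrix order by id
  expect_equal(p1$stats$x$snp, p1$ld$variants)
})

test_that("resolve_palindromic removes ambiguous variants and proxies leads", {
  r <- matrix(c(1, 0.9, 0.1,
                0.9, 1, 0.1,
                0.1, 0.1, 1), 3, 3)
  ld <- ld_matrix(r, c("lead", "proxy", "far"))
  idx <- make_stats(c("lead", "proxy", "far"), beta = c(0.3, 0.25, 0.1),
                    se = 0.05, eaf = c(0.50, 0.30, 0.10))
  idx[snp == "lead", `:=`(ea = "A", oa = "T")]   # palindromic, MAF 0.5
  region <- list(region_id = "r1", snp = "lead", pos = 1000L,
                 n_signals = 1L)
  panel <- harmonize_region(list(x = idx), "x", ld, region = region)
  out <- suppressMessages(resolve_palindromic(panel))
  expect_false("lead" %in% out$stats$x$snp)
  expect_equal(out$n_palindromic_removed, 1L)
  # best proxy has r2 = 0.81 > 0.8: substituted as region lead
  expect_equal(out$region$snp, "proxy")

  # ambiguity band is strict: A/T with MAF 0.10 is retained
  idx2 <- data.table::copy(idx)
  idx2[snp == "lead", eaf := 0.10]
  panel2 <- harmonize_region(list(x = idx2), "x", ld, region = region)
  out2 <- resolve_palindromic(panel2)
  expect_true("lead" %in% out2$stats$x$snp)

  # no qualifying proxy: lead dropped and flagged
  r3 <- diag(3); r3[1, 2] <- r3[2, 1] <- 0.5
  ld3 <- ld_matrix(r3, c("lead", "proxy", "far"))
  panel3 <- harmonize_region(list(x = idx), "x", ld3, region = region)
  out3 <- suppressMessages(resolve_palindromic(panel3))
  expect_true(isTRUE(out3$lead_dropped))
})
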