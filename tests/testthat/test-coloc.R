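test_that("wakefield_labf matches its closed form and is sign-symmetric", {
  # z = 0: lABF = 0.5 * log(V / (V + W))
  expect_equal(wakefield_labf(0, 0.1, 0.04), 0.5 * log(0.01 / 0.05))
  # direct evaluation at beta 0.1, se 0.02, W 0.04
  expect_equal(wakefield_labf(0.1, 0.02, 0.04),
               0.5 * (log(4e-4 / 0.0404) + 25 * 0.04 / 0.0404),
               tolerance = 1e-10)
  expect_equal(wakefield_labf(0.1, 0.02, 0.04), 10.0687, tolerance = 1e-4)
  expect_equal(wakefield_labf(-0.3, 0.05), wakefield_labf(0.3, 0.05))
  # strictly increasing in |z| at fixed V, W
  z <- seq(0, 10, by = 0.5)
  labf <- wakefield_labf(z * 0.1, 0.1, 0.04)
  expect_true(all(diff(labf) > 0))
  expect_error(wakefield_labf(0.1, 0), "se")
  expect_error(wakefield_labf(0.1, 0.1, W = -1), "W")
})

test_that("coloc_abf posteriors reduce to prior masses under flat data", {
  # choose beta so that each lABF is exactly 0 (Bayes factor 1)
  W <- 0.04
  z0 <- sqrt(log((1 + W) / 1) * (1 + W) / W)
  m <- 50
  t1 <- make_stats(sprintf("v%d", 1:m), beta = rep(z0, m), se = 1)
  pri <- coloc_priors()
  ev <- coloc_abf(t1, t1, pri)
  raw <- c(1, pri$p1 * m, pri$p2 * m, pri$p1 * pri$p2 * m * (m - 1),
           pri$p12 * m)
  expect_equal(unname(ev$pp), raw / sum(raw), tolerance = 1e-6)
})

test_that("coloc_abf is symmetric in trait order and sums to 1", {
  set.seed(61)
  m <- 40
  for (rep in 1:20) {
    t1 <- make_stats(sprintf("v%d", 1:m), beta = rnorm(m, 0, 0.03),
                     se = 0.01)
    t2 <- make_stats(sprintf("v%d", 1:m), beta = rnorm(m, 0, 0.03),
                     se = 0.01)
    ev12 <- coloc_abf(t1, t2)
    ev21 <- coloc_abf(t2, t1)
    expect_equal(sum(ev12$pp), 1, tolerance = 1e-8)
    expect_equal(ev12$pp[["PP.H1"]], ev21$pp[["PP.H2"]], tolerance = 1e-10)
    expect_equal(ev12$pp[["PP.H2"]], ev21$pp[["PP.H1"]], tolerance = 1e-10)
    expect_equal(ev12$pp[["PP.H0"]], ev21$pp[["PP.H0"]], tolerance = 1e-10)
    expect_equal(ev12$pp[["PP.H3"]], ev21$pp[["PP.H3"]], tolerance = 1e-10)
    expect_equal(ev12$pp[["PP.H4"]], ev21$pp[["PP.H4"]], tolerance = 1e-10)
  }
})

test_that("PP.H4 is non-decreasing in the shared prior p12", {
  set.seed(62)
  m <- 30
  t1 <- make_stats(sprintf("v%d", 1:m),
                   beta = c(rnorm(m - 1, 0, 0.01), 0.12), se = 0.02)
  t2 <- make_stats(sprintf("v%d", 1:m),
                   beta = c(rnorm(m - 1, 0, 0.01), 0.10), se = 0.02)
  h4 <- vapply(c(1e-7, 1e-6, 1e-5, 5e-5, 1e-4), function(p12) {
    coloc_abf(t1, t2, coloc_priors(p12 = p12))$pp[["PP.H4"]]
  }, numeric(1))
  expect_true(all(diff(h4) >= 0))
})

test_that("log-space enumeration matches naive summation on small input", {
  set.seed(63)
  m <- 12
  t1 <- make_stats(sprintf("v%d", 1:m), beta = rnorm(m, 0, 0.02),
                   se = 0.02)
  t2 <- make_stats(sprintf("v%d", 1:m), beta = rnorm(m, 0, 0.02),
                   se = 0.02)
  pri <- coloc_priors()
  ev <- coloc_abf(t1, t2, pri)
  a1 <- exp(wakefield_labf(t1$beta, t1$se, pri$W))
  a2 <- exp(wakefield_labf(t2$beta, t2$se, pri$W))
  raw <- c(1,
           pri$p1 * sum(a1),
           pri$p2 * sum(a2),
           pri$p1 * pri$p2 * (sum(a1) * sum(a2) - sum(a1 * a2)),
           pri$p12 * sum(a1 * a2))
  expect_equal(unname(ev$pp), raw / sum(raw), tolerance = 1e-10)
})

test_that("multitrait_coloc drops a null trait first and accepts planted
           sharing", {
  set.seed(64)
  m <- 100
  ld <- simulate_ld(m, 0.8)
  ch <- chol(ld$r)
  lam <- numeric(m); lam[50] <- 8
  stats <- list(
    t2d = z_to_stats(draw_region_z(ch, ld$r, lam), ld$variants, 150000),
    b = z_to_stats(draw_region_z(ch, ld$r, lam), ld$variants, 100000),
    c = z_to_stats(draw_region_z(ch, ld$r, lam), ld$variants, 80000),
    nullt = z_to_stats(draw_region_z(ch, ld$r, numeric(m)), ld$variants,
                       50000))
  panel <- make_panel(stats, ld, index_trait = "t2d")
  ev <- multitrait_coloc(panel)
  expect_true(ev$accepted)
  expect_setequal(ev$traits, c("t2d", "b", "c"))   # null trait dropped
  expect_gt(ev$pr * ev$pa, 0.60)
  expect_equal(ev$lead, "v50")
})

test_that("staged workflow routes single-signal, multi-signal, and
           no-credible-set regions correctly", {
  set.seed(65)
  m <- 100
  ld <- simulate_ld(m, 0.8, blocks = 2)
  ch <- chol(ld$r)
  region1 <- list(region_id = "r1", snp = "v50", n_signals = 1L)

  # all-null single-signal region: no events
  null_stats <- list(
    t2d = z_to_stats(draw_region_z(ch, ld$r, numeric(m)), ld$variants,
                     150000),
    b = z_to_stats(draw_region_z(ch, ld$r, numeric(m)), ld$variants,
                   100000))
  res0 <- run_region_workflow(make_panel(null_stats, ld, "t2d",
                                         region1))
  expect_length(res0$events, 0)
  expect_true(any(grepl("rejected", res0$log)))

  # two index signals, one shared with trait b: stage B, correct lead
  lam_idx <- numeric(m); lam_idx[25] <- 8; lam_idx[75] <- 8
  lam_b <- numeric(m); lam_b[25] <- 8
  region2 <- list(region_id = "r2", snp = "v25", n_signals = 2L)
  stats2 <- list(
    t2d = z_to_stats(draw_region_z(ch, ld$r, lam_idx), ld$variants,
                     150000),
    b = z_to_stats(draw_region_z(ch, ld$r, lam_b), ld$variants, 100000))
  res2 <- run_region_workflow(make_panel(stats2, ld, "t2d", region2))
  expect_length(res2$events, 1)
  expect_equal(res2$events[[1]]$method, "susie")
  # lead lies in the shared block (high LD with the true variant)
  lead_i <- match(res2$events[[1]]$lead, ld$variants)
  expect_gt(abs(ld$r[lead_i, 25]), 0.5)

  # index fine-mapping yields no credible sets: abf fallback
  lam_s <- numeric(m); lam_s[25] <- 8
  stats3 <- list(
    t2d = z_to_stats(draw_region_z(ch, ld$r, lam_s), ld$variants,
                     150000),
    b = z_to_stats(draw_region_z(ch, ld$r, lam_s), ld$variants, 100000))
  res3 <- run_region_workflow(
    make_panel(stats3, ld, "t2d", region2),
    susie_cfg = list(L = 5, purity_min = 1.01))  # no set can pass
  expect_length(res3$events, 1)
  expect_equal(res3$events[[1]]$method, "abf-fallback")
  expect_true(any(grepl("fallback", res3$log)))
})
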