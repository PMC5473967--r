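tz <- rep(seq(0, 22, 2), each = 2)   # 12 ZTs in duplicate

test_that("harmonic fit recovers noiseless planted cosines exactly", {
  y <- 5 + 0.5 * cos(2 * pi * (tz - 8) / 24)
  f <- fit_harmonic(tz, y)
  expect_equal(f$phase, 8)
  expect_equal(f$fold, 2)            # 2^(2 * 0.5)
  expect_true(f$rhythmic)
  expect_equal(unname(coef(f)["mesor"]), 5)
  expect_equal(predict(f, c(8, 20)), c(5.5, 4.5))

  # constant series: flat model selected, fold 1
  fc <- fit_harmonic(tz, rep(3, length(tz)))
  expect_false(fc$rhythmic)
  expect_equal(fc$fold, 1)
  expect_lt(fc$aic_flat, fc$aic_rhythmic)
  expect_error(fit_harmonic(c(0, 12), c(1, 2)), "3 distinct timepoints")
})

test_that("amplitude gate excludes sub-1.5-fold oscillations AIC would accept", {
  y <- 5 + 0.25 * cos(2 * pi * (tz - 8) / 24)
  f <- fit_harmonic(tz, y)
  expect_lt(f$aic_rhythmic, f$aic_flat)   # AIC prefers the cosine
  expect_equal(f$fold, 2^0.5)
  expect_false(f$rhythmic)                # gate at 1.5
})

test_that("phase and fold recovery holds at arbitrary phases (property)", {
  set.seed(101)
  for (i in 1:25) {
    phi <- runif(1, 0, 24)
    A <- runif(1, 0.3, 1.5)
    y <- runif(1, 2, 8) + A * cos(2 * pi * (tz - phi) / 24)
    f <- fit_harmonic(tz, y)
    dphi <- abs(((f$phase - phi + 12) %% 24) - 12)
    expect_lt(dphi, 0.25)
    expect_equal(f$fold, 2^(2 * A), tolerance = 1e-8)
  }
})

test_that("rhythm calling recovers planted rhythms with controlled errors", {
  cfg <- simulation_config(seed = 13, n_genes = 400, frac_rhythmic_rna = 0.1,
                           frac_rhythmic_te = 0,
                           amplitude_range_log2 = c(0.6, 1.0),
                           nb_dispersion = 0.02)
  sim <- simulate_dataset(cfg)
  calls <- call_rhythms(rpkm(sim$counts$kidney_RNA))
  truth <- sim$truth$genes
  planted <- truth$gene[truth$rna_rhythmic]
  called <- calls$gene[calls$rhythmic]
  expect_gte(length(intersect(called, planted)) / length(planted), 0.9)
  fpr <- length(setdiff(called, planted)) / sum(!truth$rna_rhythmic)
  expect_lte(fpr, 0.05)
  # both-assay planted rhythms appear in the overlap set
  calls_rpf <- call_rhythms(rpkm(sim$counts$kidney_RPF))
  ov <- rhythm_overlap(RNA = calls, RPF = calls_rpf)
  expect_gt(length(intersect(ov$pairwise[["RNA&RPF"]], planted)),
            0.7 * length(planted))
})

test_that("no-signal simulations stay mostly below the rhythmicity gate", {
  cfg <- simulation_config(seed = 14, n_genes = 300, frac_rhythmic_rna = 0,
                           frac_rhythmic_te = 0)
  sim <- simulate_dataset(cfg)
  calls <- call_rhythms(rpkm(sim$counts$liver_RNA))
  expect_lte(mean(calls$rhythmic), 0.05)
})

test_that("phase differences wrap into (-12, 12] with +12 at the boundary", {
  fits <- function(gene, phase, assay) {
    data.frame(gene = gene, organ = "kidney", assay = assay, mesor = 0,
               a = 1, b = 0, amp = 1, phase = phase, fold = 4,
               aic_rhythmic = -10, aic_flat = 0, rhythmic = TRUE)
  }
  pd <- phase_differences(fits(c("g1", "g2", "g3"), c(22, 5, 14), "RPF"),
                          fits(c("g1", "g2", "g3"), c(2, 5, 2), "RNA"))
  expect_equal(pd$delta, c(-4, 0, 12))
  # antisymmetry up to the boundary
  pd_swap <- phase_differences(fits(c("g1", "g2", "g3"), c(2, 5, 2), "RPF"),
                               fits(c("g1", "g2", "g3"), c(22, 5, 14), "RNA"))
  expect_equal(pd_swap$delta, c(4, 0, 12))   # +/-12 both map to +12
  expect_equal(pd_swap$delta[1:2], -pd$delta[1:2])
})

test_that("permutation test gives p = 1 for identical groups and is seeded", {
  d <- c(-3, -1, 0, 2, 5, 7)
  r <- permutation_test_distributions(d, d, n_perm = 200, seed = 4)
  expect_equal(r$p, 1)
  set.seed(3)
  a <- rnorm(150)
  b <- dualtrans:::wrap_phase_diff(rnorm(150, 6))
  r1 <- permutation_test_distributions(a, b, n_perm = 1999, seed = 3)
  r2 <- permutation_test_distributions(a, b, n_perm = 1999, seed = 3)
  expect_identical(r1$p, r2$p)
  expect_lte(r1$p, 0.001)
  expect_error(permutation_test_distributions(numeric(0), d, 200), "non-empty")
  expect_error(permutation_test_distributions(d, d, n_perm = 50), "at least 100")
})

test_that("Watson-Wheeler detects separated phase groups but not copies", {
  g <- c(1, 3, 5, 8, 9, 11, 14, 17, 19, 21, 22, 23)
  ww_same <- watson_wheeler(list(g, g))
  expect_lt(ww_same$W, 1e-10)
  expect_gt(ww_same$p, 0.99)
  expect_gte(ww_same$W, 0)

  set.seed(11)
  vm <- function(n, mu, kappa) {           # von Mises via rejection sampling
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(n, 0, 2 * pi)
      keep <- runif(n) < exp(kappa * (cos(x - mu) - 1))
      out <- c(out, x[keep])
    }
    out[1:n] * 24 / (2 * pi)
  }
  a <- vm(50, 0, 5)
  b <- vm(50, pi, 5)                       # concentrated 12 h apart
  ww <- watson_wheeler(list(a, b))
  expect_lt(ww$p, 0.01)
  expect_equal(ww$df, 2)
  expect_error(watson_wheeler(list(a, b[1:5])), "below the minimum")
})

test_that("cross-correlation follows its formula and lag convention", {
  t12 <- seq(0, 22, 2)
  x <- cos(2 * pi * (t12 - 4) / 24)
  expect_equal(attr(cross_correlate(x, x), "best_lag_h"), 0)
  expect_equal(cross_correlate(x, x)$r[cross_correlate(x, x)$lag_h == 0], 1)
  r_anti <- cross_correlate(x, -x)
  expect_equal(r_anti$r[r_anti$lag_h == 0], -1)

  y <- cos(2 * pi * (t12 - 8) / 24)        # RNA peaks 4 h after RPF
  cc <- cross_correlate(x, y)
  expect_equal(attr(cc, "best_lag_h"), -4)
  expect_true(all(abs(cc$r) <= 1 + 1e-12))
  expect_warning(cross_correlate(rep(1, 12), x), "constant profile")
})

test_that("planted RPF-RNA lags are recovered as the argmax lag", {
  t12 <- seq(0, 22, 2)
  for (lag in c(-2, -4, -6)) {
    rna <- cos(2 * pi * (t12 - 10) / 24)
    rpf <- cos(2 * pi * (t12 - 10 - lag) / 24)
    expect_equal(attr(cross_correlate(rpf, rna), "best_lag_h"), lag)
  }
})

test_that("translation-only screen needs rhythmic RPF, flat RNA and varying TE", {
  t24 <- rep(seq(0, 22, 2), each = 2)
  osc <- function(phi, A) 2^(5 + A * cos(2 * pi * (t24 - phi) / 24))
  set.seed(6)
  jitter <- function(x) x * 2^rnorm(length(x), 0, 0.03)
  rna <- rbind(g1 = jitter(rep(32, 24)),      # flat RNA
               g2 = jitter(osc(4, 0.6)),      # rhythmic RNA
               g3 = jitter(rep(32, 24)))      # fully flat
  rpf <- rbind(g1 = jitter(osc(8, 0.6)),      # rhythmic via TE
               g2 = jitter(osc(4, 0.6)),      # rhythmic, constant TE
               g3 = jitter(rep(32, 24)))
  rna_t <- toy_expression(rna, assay = "RNA", replicates = 1:2)
  rpf_t <- toy_expression(rpf, assay = "RPF", replicates = 1:2)
  te <- translation_efficiency(rpf_t, rna_t)
  # Kruskal-Wallis on 12 groups of 2 bottoms out near p ~ 0.02, so a lenient
  # alpha exercises the screen's logic rather than the test's resolution
  scr <- translation_only_screen(call_rhythms(rna_t), call_rhythms(rpf_t), te,
                                 alpha = 0.2)
  expect_true("g1" %in% attr(scr, "genes"))
  expect_false("g2" %in% attr(scr, "genes"))
  expect_false("g3" %in% attr(scr, "genes"))
})
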