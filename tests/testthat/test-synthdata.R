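test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(frac_rhythmic_rna = 1.2), "frac_rhythmic_rna")
  expect_error(simulation_config(timepoints = c(0, 2, 2)), "timepoints")
  expect_error(simulation_config(compensation_rho = 0.5), "compensation_rho")
  expect_error(simulation_config(library_size_range = c(10, 5)),
               "library_size_range")
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- simulation_config(seed = 5, n_genes = 60)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts$kidney_RPF$counts, s2$counts$kidney_RPF$counts)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(simulate_footprints(s1), simulate_footprints(s2))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1, simulate_footprints(s1))
  write_simulation(s2, d2, simulate_footprints(s2))
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("signal-free noise-free simulations give constant profiles", {
  cfg <- simulation_config(seed = 3, n_genes = 50, frac_rhythmic_rna = 0,
                           frac_rhythmic_te = 0, nb_dispersion = 0,
                           library_size_range = c(1e7, 1e7))
  sim <- simulate_dataset(cfg)
  for (cm in sim$counts) {
    rng <- apply(cm$counts, 1, function(x) diff(range(x)))
    expect_lte(max(rng / (rowMeans(cm$counts) + 1)), 0.01)  # rounding only
  }
})

test_that("planted compensation appears in the emitted truth table", {
  cfg <- simulation_config(seed = 7, n_genes = 2000, compensation_rho = -0.6)
  sim <- simulate_dataset(cfg)
  r <- cor(sim$truth$genes$rna_organ_log2ratio,
           sim$truth$genes$te_organ_log2ratio)
  expect_lt(abs(r - (-0.6)), 0.05)
  # truth covers exactly the emitted genes
  expect_setequal(sim$truth$genes$gene, rownames(sim$counts$liver_RNA$counts))
  # planted amplitudes stay inside the configured range
  amp <- sim$truth$genes$amp_rna[sim$truth$genes$rna_rhythmic]
  expect_true(all(amp >= cfg$amplitude_range_log2[1] &
                    amp <= cfg$amplitude_range_log2[2]))
})

test_that("counts follow the negative-binomial mean-variance relation", {
  cfg <- simulation_config(seed = 11, n_genes = 2000, baseline_log_sd = 0,
                           rna_organ_lfc_sd = 0, te_organ_lfc_sd = 0,
                           te_base_sd = 0, compensation_rho = 0,
                           frac_rhythmic_rna = 0, frac_rhythmic_te = 0,
                           nb_dispersion = 0.05,
                           cds_codon_range = c(200L, 200L),
                           library_size_range = c(1e7, 1e7))
  sim <- simulate_dataset(cfg)
  x <- sim$counts$kidney_RNA$counts[, 1]     # iid NB across genes
  mu <- mean(x)
  disp_hat <- (var(x) - mu) / mu^2
  expect_equal(disp_hat, 0.05, tolerance = 0.25)
})

test_that("footprint frame fractions track f_frame", {
  base <- simulation_config(seed = 13, n_genes = 30, frac_uorf_genes = 0)
  sim <- simulate_dataset(base)

  frame_frac <- function(sim, fps) {
    prof <- a_site_positions(fps)
    hits <- 0; tot <- 0
    for (i in seq_len(nrow(sim$annotation))) {
      a <- sim$annotation[i, ]
      fs <- frame_stats(prof, a$transcript_id, a$cds_start, a$cds_end)
      hits <- hits + fs$counts[["f0"]]; tot <- tot + fs$total
    }
    hits / tot
  }
  sim$config$f_frame <- 1
  expect_equal(frame_frac(sim, simulate_footprints(sim)), 1)
  sim$config$f_frame <- 1 / 3
  expect_equal(frame_frac(sim, simulate_footprints(sim)), 1 / 3,
               tolerance = 0.05)
  sim$config$f_frame <- 0.85
  expect_equal(frame_frac(sim, simulate_footprints(sim)), 0.85,
               tolerance = 0.03)
})

test_that("rhythm detection recovers planted rhythms from emitted counts", {
  cfg <- simulation_config(seed = 17, n_genes = 500, frac_rhythmic_rna = 0.2,
                           amplitude_range_log2 = c(0.5, 1.0),
                           nb_dispersion = 0.05)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$genes
  for (organ in c("kidney", "liver")) {
    calls <- call_rhythms(rpkm(sim$counts[[paste0(organ, "_RNA")]]))
    planted <- truth$gene[truth$rna_rhythmic]
    sens <- mean(planted %in% calls$gene[calls$rhythmic])
    expect_gte(sens, 0.9)
    # recovered phases match planted phases
    hit <- calls[calls$gene %in% planted & calls$rhythmic, ]
    dphi <- abs(dualtrans:::wrap_phase_diff(
      hit$phase - truth$phase_rna[match(hit$gene, truth$gene)]))
    expect_lt(median(dphi), 1)
  }
})

test_that("planted RPF-RNA lags shift the recovered RPF phases", {
  cfg <- simulation_config(seed = 19, n_genes = 400, frac_rhythmic_rna = 0.25,
                           amplitude_range_log2 = c(0.6, 1.0),
                           nb_dispersion = 0.01,
                           phase_lag_mean_h = c(kidney = -4, liver = 0))
  sim <- simulate_dataset(cfg)
  fits_rna <- call_rhythms(rpkm(sim$counts$kidney_RNA))
  fits_rpf <- call_rhythms(rpkm(sim$counts$kidney_RPF))
  pd <- phase_differences(fits_rpf, fits_rna)
  expect_gt(nrow(pd), 30)
  expect_equal(median(pd$delta), -4, tolerance = 0.15)
  expect_gt(attr(pd, "n_advance"), attr(pd, "n_delay"))
})
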