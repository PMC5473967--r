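test_that("uORF detection honours the AUG start and 18-nt length rule", {
  # AUG at 2, six coding codons (18 nt incl. AUG), then UAA
  utr_18 <- paste0("GG", "ATG", strrep("AAA", 5), "TAA", "GG")
  tx <- toy_transcript(utr_18)
  rec <- detect_uorfs(tx$seq, tx$ann)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$start, 2)
  expect_equal(rec$end, 20)                       # coding span 18 nt
  expect_equal(rec$cds_overlap, "none")

  utr_15 <- paste0("GG", "ATG", strrep("AAA", 4), "TAA", "GG")
  tx15 <- toy_transcript(utr_15)
  expect_equal(nrow(detect_uorfs(tx15$seq, tx15$ann)), 0)

  no_aug <- toy_transcript(strrep("GC", 20))
  expect_equal(nrow(detect_uorfs(no_aug$seq, no_aug$ann)), 0)

  expect_error(detect_uorfs(substr(tx$seq, 1, 50), tx$ann), "does not match")
})

test_that("uORFs running into the CDS are dropped in-frame, trimmed out-of-frame", {
  # AUG 9 nt before the CDS, no stop in the UTR; A-free filler upstream
  utr <- paste0(strrep("C", 21), "ATG", "CCCCCC")    # AUG at 21, UTR len 30
  # in-frame with CDS: (30 - 21) %% 3 == 0 -> dropped
  tx_in <- toy_transcript(utr)
  expect_equal(nrow(detect_uorfs(tx_in$seq, tx_in$ann)), 0)

  # out-of-frame: shift the AUG by one
  utr_oof <- paste0(strrep("C", 22), "ATG", "CCCCC") # AUG at 22, UTR len 30
  tx_oof <- toy_transcript(utr_oof)
  rec <- detect_uorfs(tx_oof$seq, tx_oof$ann)
  if (nrow(rec) == 1) {                 # a downstream out-of-frame stop exists
    expect_equal(rec$cds_overlap, "out-of-frame")
    expect_equal(rec$countable_end, 30)  # countable span ends at the CDS
  } else {
    expect_equal(nrow(rec), 0)           # no stop before the transcript end
  }
})

test_that("overlapping uORFs merge into composites matching an interval-union oracle", {
  r <- toy_uorf_records(c(2, 14), c(26, 44))
  m <- merge_composites(r)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(2, 44))
  expect_true(m$composite)

  r2 <- toy_uorf_records(c(2, 40), c(26, 70))
  m2 <- merge_composites(r2)
  expect_equal(nrow(m2), 2)
  expect_false(any(m2$composite))

  r3 <- toy_uorf_records(c(2, 14, 30), c(20, 44, 60))   # pairwise chain
  m3 <- merge_composites(r3)
  expect_equal(nrow(m3), 1)
  expect_equal(c(m3$start, m3$end), c(2, 60))

  # randomized: union via sorted sweep (oracle) equals merge output
  set.seed(47)
  for (i in 1:20) {
    s <- sort(sample(0:100, 6))
    e <- s + sample(5:30, 6, replace = TRUE)
    rr <- toy_uorf_records(s, e)
    mm <- merge_composites(rr)
    # oracle: reduce sorted intervals
    iv <- cbind(s, e)[order(s), , drop = FALSE]
    out <- iv[1, , drop = FALSE]
    for (j in 2:nrow(iv)) {
      if (iv[j, 1] < out[nrow(out), 2])
        out[nrow(out), 2] <- max(out[nrow(out), 2], iv[j, 2])
      else out <- rbind(out, iv[j, ])
    }
    expect_equal(cbind(mm$start, mm$end), unname(out))
  }
})

test_that("detection equals the brute-force AUG/stop enumerator on random UTRs", {
  set.seed(53)
  n_checked <- 0
  for (i in 1:400) {
    utr <- random_utr5(sample(25:90, 1))
    tx <- toy_transcript(utr, cds_codons = 20, utr3_len = 20, seed = i)
    rec <- detect_uorfs(tx$seq, tx$ann)
    ora <- oracle_uorfs(tx$seq, nchar(utr), nchar(utr))
    if (is.null(ora)) {
      expect_equal(nrow(rec), 0)
    } else {
      expect_equal(rec[, c("start", "end", "cds_overlap")],
                   ora[, c("start", "end", "cds_overlap")],
                   ignore_attr = TRUE)
    }
    # invariants: AUG start, >= 18 nt
    if (nrow(rec) > 0) {
      expect_true(all(substr(tx$seq, rec$start + 1, rec$start + 3) == "ATG"))
      expect_true(all(rec$end - rec$start >= 18))
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 400)
})

test_that("translation calling applies the exact binomial frame test and coverage gate", {
  rec <- toy_uorf_records(30, 120)      # countable span 90 nt

  r0 <- call_translated(rec, toy_profile(integer(0)))
  expect_false(r0$translated)
  expect_true(is.na(r0$frame_bias_p))

  # 30 reads, all frame 0, at 30 distinct positions (coverage 1/3)
  prof_f0 <- toy_profile(seq(30, 117, 3))
  r1 <- call_translated(rec, prof_f0)
  expect_equal(r1$frame_bias_p, (1 / 3)^30)
  expect_equal(r1$coverage, 1 / 3)
  expect_true(r1$translated)

  # 10/10/10 split: null-rate frame bias
  prof_split <- toy_profile(c(seq(30, 57, 3), seq(31, 58, 3), seq(32, 59, 3)))
  r2 <- call_translated(rec, prof_split)
  expect_equal(r2$frame_bias_p, pbinom(9, 30, 1 / 3, lower.tail = FALSE))
  expect_gt(r2$frame_bias_p, 0.3)
  expect_false(r2$translated)

  # high bias but thin coverage fails the 10% gate
  prof_thin <- toy_profile(rep(30, 50))
  r3 <- call_translated(rec, prof_thin)
  expect_lt(r3$frame_bias_p, 1e-10)
  expect_false(r3$translated)
})

test_that("adding frame-0 reads never revokes a translated call (monotonicity)", {
  set.seed(59)
  rec <- toy_uorf_records(30, 90)
  n_translated <- 0
  for (i in 1:30) {
    f0 <- runif(1, 1 / 3, 1)              # varying frame-0 enrichment
    n_reads <- sample(15:40, 1)
    n0 <- rbinom(1, n_reads, f0)
    pos <- c(seq(30, 87, 3)[sample.int(20, n0, replace = TRUE)],
             sample(30:89, n_reads - n0, replace = TRUE))
    r_before <- call_translated(rec, toy_profile(pos))
    extra <- seq(30, 87, 3)[sample.int(20, 10, replace = TRUE)]
    r_after <- call_translated(rec, toy_profile(c(pos, extra)))
    expect_lte(r_after$frame_bias_p, r_before$frame_bias_p)
    expect_gte(r_after$coverage, r_before$coverage)
    if (r_before$translated) {
      n_translated <- n_translated + 1
      expect_true(r_after$translated)
    }
  }
  expect_gt(n_translated, 0)
})

test_that("uORF TE mirrors the CDS normalization machinery", {
  expect_equal(unname(uorf_te(20, 10, 1e6, 1e6)), 2)
  expect_true(is.na(uorf_te(20, 0, 1e6, 1e6)))
  # joint depth doubling leaves TE unchanged
  expect_equal(uorf_te(c(20, 40), c(10, 20), c(1e6, 2e6), c(1e6, 2e6)),
               c(2, 2))
})

test_that("uORF/CDS ratio tables join genes and recover planted correlation", {
  tab <- uorf_vs_cds_ratio_table(c(gA = 0.5), c(gA = 2.0))
  expect_equal(unlist(tab[1, -1], use.names = FALSE), c(0.5, 2.0))

  same <- c(g1 = 0.5, g2 = 1, g3 = 2, g4 = 4)
  expect_equal(attr(uorf_vs_cds_ratio_table(same, same), "r"), 1)

  set.seed(61)
  z1 <- rnorm(400); z2 <- -0.5 * z1 + sqrt(1 - 0.25) * rnorm(400)
  u <- setNames(2^z1, paste0("g", 1:400))
  cds <- setNames(2^z2, paste0("g", 1:400))
  r <- attr(uorf_vs_cds_ratio_table(u, cds), "r")
  expect_equal(r, -0.5, tolerance = 0.2)
  expect_error(uorf_vs_cds_ratio_table(c(gA = 1), c(gB = 1)), "no gene")
})

test_that("planted translated uORFs in the simulation are called downstream", {
  cfg <- simulation_config(seed = 67, n_genes = 120, frac_uorf_genes = 0.4)
  sim <- simulate_dataset(cfg)
  prof <- a_site_positions(simulate_footprints(sim))
  tu <- sim$truth$uorfs
  agree <- logical(nrow(tu))
  for (i in seq_len(nrow(tu))) {
    tx <- tu$transcript_id[i]
    rec <- detect_uorfs(sim$sequences[[tx]], sim$annotation, tx)
    rec <- call_translated(merge_composites(rec), prof)
    hit <- which(rec$start == tu$start[i] & rec$end == tu$end[i])
    agree[i] <- length(hit) == 1 && rec$translated[hit] == tu$translated[i]
  }
  expect_gte(mean(agree), 0.95)
})
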