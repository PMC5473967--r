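test_that("Hellinger distance hits its endpoints and the closed-form middle case", {
  expect_equal(hellinger_distance(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)), 0)
  expect_equal(hellinger_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(hellinger_distance(c(1, 0), c(0.5, 0.5)),
               sqrt(2 - sqrt(2)) / sqrt(2), tolerance = 1e-12)
  expect_error(hellinger_distance(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(hellinger_distance(c(1, 0), c(1, 0, 0)), "length")
})

test_that("Hellinger distance is a bounded metric on proportion vectors", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    rnd <- function() { p <- rgamma(n, 0.7); p / sum(p) }
    p <- rnd(); q <- rnd(); r <- rnd()
    h_pq <- hellinger_distance(p, q)
    expect_gte(h_pq, 0); expect_lte(h_pq, 1)
    expect_equal(h_pq, hellinger_distance(q, p))
    expect_equal(hellinger_distance(p, p), 0)
    expect_lte(h_pq, hellinger_distance(p, r) + hellinger_distance(r, q) + 1e-12)
  }
})

test_that("per-gene Hellinger table aligns isoform universes across organs", {
  iso <- read_isoform_proportions(data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("t1", "t2", "t1", "t3", "t3"),
    organ = c("kidney", "kidney", "liver", "kidney", "liver"),
    proportion = c(0.5, 0.5, 1, 1, 1)))
  h <- hellinger_table(iso)
  # g1: kidney (0.5, 0.5) vs liver (1, 0); g2 identical single isoform
  expect_equal(h$hellinger[h$gene == "g1"],
               hellinger_distance(c(0.5, 0.5), c(1, 0)))
  expect_equal(h$hellinger[h$gene == "g2"], 0)
})

test_that("Kozak scoring follows the +3/+1 consensus scheme", {
  expect_equal(kozak_score("GCCACCAUGG"), 13)   # consensus, maximum
  expect_equal(kozak_score("TTTTTTAUGT"), 0)
  expect_equal(kozak_score("GCCGCCAUGA"), 10)
  expect_equal(kozak_score("gccaccatgg"), 13)   # case/alphabet insensitive
  expect_error(kozak_score("GCCACCAUG"), "exactly 10 nt")
  expect_error(kozak_score("GCCACCTTGG"), "start codon")
  # bounded, and 13 only for the full consensus
  set.seed(73)
  for (i in 1:100) {
    ctx <- paste0(paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                        collapse = ""), "ATG",
                  sample(c("A", "C", "G", "T"), 1))
    sc <- kozak_score(ctx)
    expect_gte(sc, 0); expect_lte(sc, 13)
    if (sc == 13) {
      expect_equal(substr(ctx, 1, 3), "GCC")
      expect_true(substr(ctx, 4, 4) %in% c("A", "G"))
      expect_equal(substr(ctx, 5, 6), "CC")
      expect_equal(substr(ctx, 10, 10), "G")
    }
  }
})

test_that("divergence classification attributes isoform diversity to features", {
  ann <- read_annotation(data.frame(
    transcript_id = c("t1", "t2"), gene_id = "g1",
    utr5_start = 0L, utr5_end = c(30L, 12L),
    cds_start = c(30L, 12L), cds_end = c(60L, 42L),
    utr3_start = c(60L, 42L), utr3_end = c(90L, 72L),
    protein_coding = TRUE))
  base <- paste(rep(c("C", "G", "T"), 30), collapse = "")
  seqs <- c(t1 = base, t2 = substr(base, 19, 90))  # t2: 18-nt shorter 5'UTR

  single <- data.frame(gene_id = "g1", transcript_id = "t1",
                       organ = c("kidney", "liver"), proportion = 1)
  expect_equal(classify_divergence(single, ann, seqs), "identical-set")

  swap <- data.frame(gene_id = "g1", transcript_id = c("t1", "t2"),
                     organ = c("kidney", "liver"), proportion = 1)
  expect_equal(classify_divergence(swap, ann, seqs), "5'UTR-only")

  # isoforms differing in 5'UTR and CDS
  ann_mix <- read_annotation(data.frame(
    transcript_id = c("t1", "t3"), gene_id = "g1",
    utr5_start = 0L, utr5_end = c(30L, 12L),
    cds_start = c(30L, 12L), cds_end = c(60L, 45L),
    utr3_start = c(60L, 45L), utr3_end = c(90L, 75L),
    protein_coding = TRUE))
  seqs_mix <- c(t1 = base, t3 = substr(base, 16, 90))
  mix <- data.frame(gene_id = "g1", transcript_id = c("t1", "t3"),
                    organ = c("kidney", "liver"), proportion = 1)
  expect_equal(classify_divergence(mix, ann_mix, seqs_mix), "mixed")
  expect_error(
    classify_divergence(swap, ann[ann$transcript_id == "t1", ], seqs),
    "unannotated")
})

test_that("feature tables report lengths, GC and Kozak deterministically", {
  # 5'UTR GCCACC (6 nt), CDS ATGGCGTAA, 3'UTR empty
  seq <- paste0("GCCACC", "ATGGCGTAA")
  ann <- toy_annotation(6L, 9L, 0L)
  ft <- feature_table(ann, c(tx1 = seq))
  expect_equal(ft$cds_len, 9)
  expect_equal(ft$cds_gc, 4 / 9)
  expect_true(is.na(ft$utr3_gc))
  expect_equal(ft$utr3_len, 0)
  expect_equal(ft$kozak, 13)   # GCCACC|ATG|G context

  set.seed(79)
  s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  ann2 <- toy_annotation(30L, 60L, 30L)
  s <- paste0(substr(s, 1, 30), "ATG", substr(s, 34, 120))  # valid start
  ft2 <- feature_table(ann2, c(tx1 = s))
  gc_oracle <- function(x) {
    n <- strsplit(x, "")[[1]]; mean(n %in% c("G", "C"))
  }
  expect_equal(ft2$tx_gc, gc_oracle(s))
  expect_equal(ft2$utr5_gc, gc_oracle(substr(s, 1, 30)))
  mfe <- c(tx1 = -12.3)
  expect_equal(feature_table(ann2, c(tx1 = s), mfe = mfe)$utr5_mfe, -12.3)
})

test_that("isoform divergence is higher for TE-shifted genes in the simulation", {
  cfg <- simulation_config(seed = 83, n_genes = 600, frac_multi_isoform = 0.5,
                           te_organ_lfc_sd = 0.2, frac_te_shift = 0.3,
                           te_shift_log2 = 1.5, isoform_te_coupling = 1)
  sim <- simulate_dataset(cfg)
  h <- hellinger_table(sim$isoforms)
  truth <- sim$truth$genes
  multi <- truth$gene[match(h$gene, truth$gene)]
  shifted <- truth$te_shifted[match(h$gene, truth$gene)]
  keep <- h$n_isoforms > 1
  ks <- suppressWarnings(
    ks.test(h$hellinger[keep & shifted], h$hellinger[keep & !shifted],
            alternative = "less"))
  expect_lt(ks$p.value, 0.01)
  expect_gt(mean(h$hellinger[keep & shifted]),
            mean(h$hellinger[keep & !shifted]))
})
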