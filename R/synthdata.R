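#' Configuration for the synthetic dual-organ study
#'
#' Defines the simulated study: 2 organs x 2 assays (RNA-seq, RPF-seq) x 12
#' timepoints (ZT0--ZT22, 2-h steps) x 2 replicates, negative-binomial
#' counts, planted rhythms, organ-specific TE shifts anticorrelated with RNA
#' shifts (translational compensation), RPF-leads-RNA phase lags, 3-periodic
#' footprints and planted 5'UTR uORFs. Scale defaults are derived from the
#' observed spread of real dual-organ data: a >500-fold within-organ mRNA
#' range (baseline log2 SD 2.25), a 114-fold 95% range of cross-organ mRNA
#' ratios (SD 1.75), a <3-fold 95% range of cross-organ TE ratios (SD 0.40)
#' and an about tenfold within-organ TE range (SD 0.85).
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (> 0).
#' @param timepoints ZT hours, strictly increasing within [0, 24).
#' @param n_replicates replicates per timepoint.
#' @param organs two organ labels.
#' @param baseline_log_mean,baseline_log_sd log2-RPKM distribution of gene
#'   baselines.
#' @param rna_organ_lfc_sd SD of cross-organ RNA log2 fold differences.
#' @param te_organ_lfc_sd SD of cross-organ TE log2 fold differences.
#' @param te_base_sd SD of the organ-shared log2 TE baseline.
#' @param compensation_rho target correlation (in [-1, 0]) between a gene's
#'   RNA organ log-ratio and its TE organ log-ratio.
#' @param frac_rhythmic_rna,frac_rhythmic_te fractions of genes with planted
#'   RNA rhythms / TE-only rhythms.
#' @param amplitude_range_log2 interval for planted log2 half-amplitudes.
#' @param phase_lag_mean_h named per-organ mean planted RPF-RNA lag (h;
#'   negative = footprints peak earlier).
#' @param nb_dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives deterministic rounded means.
#' @param frac_uorf_genes fraction of genes with a planted 5'UTR uORF.
#' @param frac_uorf_translated fraction of planted uORFs that are translated
#'   (3-periodic footprint coverage); the rest get sparse frame-uniform
#'   coverage.
#' @param frac_multi_isoform fraction of genes with >1 protein-coding
#'   isoform.
#' @param isoform_te_coupling strength of the link between a gene's TE organ
#'   shift and its isoform-usage divergence.
#' @param library_size_range interval of total counts per library.
#' @param frac_te_shift,te_shift_log2 optional deterministic cross-organ TE
#'   shifts of fixed size planted in a random gene subset (for power
#'   studies); default none.
#' @param f_frame fraction of CDS/uORF footprints whose A-site falls in
#'   frame 0.
#' @param footprint_reads_per_cds,footprint_reads_per_uorf footprints placed
#'   per CDS / per translated uORF.
#' @param utr5_len_range,cds_codon_range,utr3_len_range transcript geometry.
#' @return Validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 1000L,
                              timepoints = seq(0, 22, by = 2),
                              n_replicates = 2L,
                              organs = c("kidney", "liver"),
                              baseline_log_mean = 3,
                              baseline_log_sd = 2.25,
                              rna_organ_lfc_sd = 1.75,
                              te_organ_lfc_sd = 0.40,
                              te_base_sd = 0.85,
                              compensation_rho = -0.6,
                              frac_rhythmic_rna = 0.10,
                              frac_rhythmic_te = 0.02,
                              amplitude_range_log2 = c(0.3, 1.0),
                              phase_lag_mean_h = c(kidney = -2, liver = 0),
                              nb_dispersion = 0.02,
                              frac_uorf_genes = 0.2,
                              frac_uorf_translated = 0.6,
                              frac_multi_isoform = 0.2,
                              isoform_te_coupling = 1,
                              library_size_range = c(5e6, 15e6),
                              frac_te_shift = 0,
                              te_shift_log2 = log2(2),
                              f_frame = 0.85,
                              footprint_reads_per_cds = 200L,
                              footprint_reads_per_uorf = 150L,
                              utr5_len_range = c(60L, 240L),
                              cds_codon_range = c(100L, 500L),
                              utr3_len_range = c(50L, 250L)) {
  cfg <- as.list(environment())
  chk_frac <- function(nm) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) dt_config_stop(nm, "must be in [0, 1]")
  }
  for (nm in c("frac_rhythmic_rna", "frac_rhythmic_te", "frac_uorf_genes",
               "frac_uorf_translated", "frac_multi_isoform", "frac_te_shift",
               "f_frame")) chk_frac(nm)
  if (!is.numeric(cfg$n_genes) || cfg$n_genes <= 0)
    dt_config_stop("n_genes", "must be > 0")
  tp <- cfg$timepoints
  if (any(diff(tp) <= 0) || any(tp < 0) || any(tp >= 24))
    dt_config_stop("timepoints", "must be strictly increasing within [0, 24)")
  if (length(cfg$organs) != 2) dt_config_stop("organs", "exactly two labels")
  if (cfg$compensation_rho < -1 || cfg$compensation_rho > 0)
    dt_config_stop("compensation_rho", "must be in [-1, 0]")
  if (cfg$nb_dispersion < 0) dt_config_stop("nb_dispersion", "must be >= 0")
  if (diff(cfg$amplitude_range_log2) < 0 || any(cfg$amplitude_range_log2 < 0))
    dt_config_stop("amplitude_range_log2", "must be a non-negative interval")
  if (!all(cfg$organs %in% names(cfg$phase_lag_mean_h))) {
    if (length(cfg$phase_lag_mean_h) == 2 && is.null(names(cfg$phase_lag_mean_h)))
      names(cfg$phase_lag_mean_h) <- cfg$organs
    else dt_config_stop("phase_lag_mean_h", "needs one lag per organ")
  }
  if (diff(cfg$library_size_range) < 0 || any(cfg$library_size_range <= 0))
    dt_config_stop("library_size_range", "must be a positive interval")
  cfg$phase_lag_mean_h <- cfg$phase_lag_mean_h[cfg$organs]
  structure(cfg, class = "simulation_config")
}

# codons free of adenine can neither create an AUG nor a stop codon, in any
# frame, including across codon boundaries; used for uORF bodies and 5'UTR
# filler so planted uORFs are the only ones present
a_free_codons <- function() {
  nt <- c("C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(nt, nt, paste0)), nt, paste0))
  cod
}

all_sense_codons <- function() {
  nt <- c("A", "C", "G", "T")
  cod <- as.vector(outer(as.vector(outer(nt, nt, paste0)), nt, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

rand_string <- function(n, alphabet = c("C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# sample() semantics without the scalar-x surprise
sample_range <- function(rng, n) {
  v <- seq(rng[1], rng[2])
  v[sample.int(length(v), n, replace = TRUE)]
}

#' Simulate the full dual-organ study with ground truth
#'
#' Generates count tables for the four organ x assay strata, the transcript
#' annotation and sequences (with planted uORFs), isoform proportion tables
#' and the ground-truth tables, all reproducible from the seed. Per gene g,
#' organ o and time t the RNA log2 abundance is \code{baseline +/-
#' organ_lfc/2 + A*cos(2*pi*(t - phase)/24)}; the RPF log2 abundance adds the
#' log2 TE (organ-shared baseline, organ shift anticorrelated with the RNA
#' shift at \code{compensation_rho}, and for RNA-rhythmic genes the planted
#' oscillation phase-shifted by the organ's RPF-RNA lag). Mean counts are
#' scaled to the library size and drawn negative-binomial.
#'
#' @param config a [simulation_config()].
#' @return List of class \code{"translatome_simulation"}: \code{counts}
#'   (named list of four [count_matrix()]s, \code{kidney_RNA} ...),
#'   \code{truth} (list: \code{genes}, \code{uorfs} data.frames),
#'   \code{annotation}, \code{sequences}, \code{isoforms}, \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_genes)
  genes <- sprintf("gene_%05d", seq_len(n))
  organs <- config$organs
  tp <- config$timepoints
  reps <- seq_len(config$n_replicates)

  ## --- per-gene truth -----------------------------------------------------
  baseline <- stats::rnorm(n, config$baseline_log_mean, config$baseline_log_sd)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rna_lfc <- config$rna_organ_lfc_sd * z1
  rho <- config$compensation_rho
  te_lfc <- config$te_organ_lfc_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  te_base <- stats::rnorm(n, 0, config$te_base_sd)
  shift_genes <- sample(n, round(config$frac_te_shift * n))
  if (length(shift_genes) > 0)
    te_lfc[shift_genes] <- config$te_shift_log2 *
      sample(c(-1, 1), length(shift_genes), replace = TRUE)

  n_rna_rhy <- round(config$frac_rhythmic_rna * n)
  n_te_rhy <- round(config$frac_rhythmic_te * n)
  rhy_rna <- sample(n, n_rna_rhy)
  rhy_te <- sample(setdiff(seq_len(n), rhy_rna), n_te_rhy)
  amp_rna <- amp_te <- rep(0, n)
  phase_rna <- phase_te <- rep(NA_real_, n)
  amp_rna[rhy_rna] <- stats::runif(n_rna_rhy, config$amplitude_range_log2[1],
                                   config$amplitude_range_log2[2])
  phase_rna[rhy_rna] <- stats::runif(n_rna_rhy, 0, 24)
  amp_te[rhy_te] <- stats::runif(n_te_rhy, config$amplitude_range_log2[1],
                                 config$amplitude_range_log2[2])
  phase_te[rhy_te] <- stats::runif(n_te_rhy, 0, 24)
  lag <- config$phase_lag_mean_h

  ## --- transcript geometry and sequences ---------------------------------
  utr5_len <- sample_range(config$utr5_len_range, n)
  cds_cod <- sample_range(config$cds_codon_range, n)
  utr3_len <- sample_range(config$utr3_len_range, n)
  cds_len <- 3L * cds_cod
  uorf_genes <- sort(sample(n, round(config$frac_uorf_genes * n)))
  uorf_translated <- rep(FALSE, n)
  uorf_translated[sample(uorf_genes,
                         round(config$frac_uorf_translated * length(uorf_genes)))] <- TRUE
  safe <- a_free_codons()
  sense <- all_sense_codons()
  tx_id <- paste0("tx_", genes)
  sequences <- character(n)
  uorf_rows <- list()
  for (i in seq_len(n)) {
    if (i %in% uorf_genes) {
      k <- sample(5:19, 1)                       # coding span 18..60 nt
      span <- 3L * (k + 1L)
      # leave >= 15 nt upstream so A-site offsetting never clips 5' ends
      min_utr <- span + 3L + 24L
      if (utr5_len[i] < min_utr) utr5_len[i] <- min_utr
      u_start <- sample_range(c(15L, utr5_len[i] - span - 3L - 3L), 1)
      u_start <- u_start - (u_start %% 3L) + sample(0:2, 1)  # any frame
      pre <- rand_string(u_start)
      body <- paste(sample(safe, k, replace = TRUE), collapse = "")
      post <- rand_string(utr5_len[i] - u_start - span - 3L)
      # TAG terminator: no cross-junction AUG can arise from A-free flanks
      utr5 <- paste0(pre, "ATG", body, "TAG", post)
      uorf_rows[[length(uorf_rows) + 1]] <- data.frame(
        gene = genes[i], transcript_id = tx_id[i],
        start = u_start, end = u_start + span,
        translated = uorf_translated[i], stringsAsFactors = FALSE)
    } else {
      utr5 <- rand_string(utr5_len[i])
    }
    cds <- paste0("ATG",
                  paste(sample(sense, cds_cod[i] - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    utr3 <- rand_string(utr3_len[i], alphabet = c("A", "C", "G", "T"))
    sequences[i] <- paste0(utr5, cds, utr3)
  }
  names(sequences) <- tx_id
  annotation <- data.frame(
    transcript_id = tx_id, gene_id = genes,
    utr5_start = 0L, utr5_end = utr5_len,
    cds_start = utr5_len, cds_end = utr5_len + cds_len,
    utr3_start = utr5_len + cds_len, utr3_end = utr5_len + cds_len + utr3_len,
    protein_coding = TRUE, stringsAsFactors = FALSE
  )
  class(annotation) <- c("transcript_annotation", "data.frame")

  ## --- isoform proportions -----------------------------------------------
  multi <- sort(sample(n, round(config$frac_multi_isoform * n)))
  iso_rows <- list()
  iso_truth <- list()
  extra_ann <- list()
  for (i in seq_len(n)) {
    if (i %in% multi) {
      n_iso <- sample(2:3, 1)
      ids <- c(tx_id[i], paste0(tx_id[i], "_v", seq_len(n_iso - 1)))
      # variant isoforms share CDS and 3'UTR, differ in 5'UTR length
      for (v in seq_len(n_iso - 1)) {
        trim <- sample(seq(10L, max(11L, utr5_len[i] %/% 2)), 1)
        extra_ann[[length(extra_ann) + 1]] <- data.frame(
          transcript_id = ids[v + 1], gene_id = genes[i],
          utr5_start = 0L, utr5_end = utr5_len[i] - trim,
          cds_start = utr5_len[i] - trim, cds_end = utr5_len[i] - trim + cds_len[i],
          utr3_start = utr5_len[i] - trim + cds_len[i],
          utr3_end = utr5_len[i] - trim + cds_len[i] + utr3_len[i],
          protein_coding = TRUE, stringsAsFactors = FALSE)
        sequences[ids[v + 1]] <- substr(sequences[tx_id[i]], trim + 1,
                                        nchar(sequences[tx_id[i]]))
      }
      p0 <- stats::rgamma(n_iso, 1); p0 <- p0 / sum(p0)
      p1 <- stats::rgamma(n_iso, 1); p1 <- p1 / sum(p1)
      d <- min(1, abs(te_lfc[i]) * config$isoform_te_coupling)
      pk <- p0
      pl <- (1 - d) * p0 + d * p1
      for (o in organs) {
        p <- if (o == organs[1]) pk else pl
        iso_rows[[length(iso_rows) + 1]] <- data.frame(
          gene_id = genes[i], transcript_id = ids, organ = o, proportion = p,
          stringsAsFactors = FALSE)
      }
      iso_truth[[length(iso_truth) + 1]] <- data.frame(
        gene = genes[i], hellinger = hellinger_distance(pl, pk),
        stringsAsFactors = FALSE)
    } else {
      for (o in organs)
        iso_rows[[length(iso_rows) + 1]] <- data.frame(
          gene_id = genes[i], transcript_id = tx_id[i], organ = o,
          proportion = 1, stringsAsFactors = FALSE)
      iso_truth[[length(iso_truth) + 1]] <- data.frame(
        gene = genes[i], hellinger = 0, stringsAsFactors = FALSE)
    }
  }
  isoforms <- do.call(rbind, iso_rows)
  class(isoforms) <- c("isoform_proportions", "data.frame")
  if (length(extra_ann) > 0) {
    annotation <- rbind(annotation, do.call(rbind, extra_ann))
    annotation <- annotation[order(annotation$transcript_id), , drop = FALSE]
    rownames(annotation) <- NULL
    class(annotation) <- c("transcript_annotation", "data.frame")
  }

  ## --- expression surfaces and counts ------------------------------------
  t_vec <- rep(tp, each = length(reps))              # 24 libraries per stratum
  rep_vec <- rep(reps, times = length(tp))
  w <- 2 * pi / 24
  half <- c(0.5, -0.5); names(half) <- organs        # organ 1 = +lfc/2
  counts <- list()
  lengths_df <- data.frame(gene = genes, utr5_len = utr5_len,
                           cds_len = cds_len, utr3_len = utr3_len)
  for (o in organs) {
    osc_rna <- matrix(0, n, length(t_vec))
    idx <- which(amp_rna > 0)
    if (length(idx) > 0)
      osc_rna[idx, ] <- amp_rna[idx] *
        cos(w * outer(-phase_rna[idx], t_vec, "+"))
    osc_rpf <- matrix(0, n, length(t_vec))
    if (length(idx) > 0)
      osc_rpf[idx, ] <- amp_rna[idx] *
        cos(w * outer(-(phase_rna[idx] + lag[o]), t_vec, "+"))
    idx_te <- which(amp_te > 0)
    osc_te <- matrix(0, n, length(t_vec))
    if (length(idx_te) > 0)
      osc_te[idx_te, ] <- amp_te[idx_te] *
        cos(w * outer(-phase_te[idx_te], t_vec, "+"))
    log_rna <- baseline + half[o] * rna_lfc + osc_rna
    log_rpf <- baseline + half[o] * rna_lfc + te_base + half[o] * te_lfc +
      osc_rpf + osc_te
    for (assay in c("RNA", "RPF")) {
      lg <- if (assay == "RNA") log_rna else log_rpf
      wgt <- 2^lg * (cds_len / 1000)                 # counts proportional to
      lib <- stats::runif(length(t_vec), config$library_size_range[1],
                          config$library_size_range[2])
      mu <- sweep(wgt, 2, colSums(wgt), "/")
      mu <- sweep(mu, 2, lib, "*")
      cm <- if (config$nb_dispersion == 0) round(mu)
        else matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / config$nb_dispersion),
                    nrow = n)
      colnames(cm) <- format_sample_keys(o, assay, t_vec, rep_vec)
      rownames(cm) <- genes
      counts[[paste(o, assay, sep = "_")]] <- count_matrix(cm, lengths_df)
    }
  }

  truth_genes <- data.frame(
    gene = genes,
    baseline_log2 = baseline,
    rna_organ_log2ratio = rna_lfc,     # organ1 - organ2
    te_organ_log2ratio = te_lfc,
    te_base_log2 = te_base,
    rna_rhythmic = seq_len(n) %in% rhy_rna,
    te_rhythmic = seq_len(n) %in% rhy_te,
    amp_rna = amp_rna, phase_rna = phase_rna,
    amp_te = amp_te, phase_te = phase_te,
    has_uorf = seq_len(n) %in% uorf_genes,
    uorf_translated = uorf_translated,
    te_shifted = seq_len(n) %in% shift_genes,
    stringsAsFactors = FALSE
  )
  # the planted lag applies to RNA-rhythmic genes; one row per organ column
  for (o in organs)
    truth_genes[[paste0("lag_", o)]] <- ifelse(truth_genes$rna_rhythmic,
                                               lag[o], NA_real_)
  truth_uorfs <- if (length(uorf_rows) > 0) do.call(rbind, uorf_rows)
    else data.frame(gene = character(), transcript_id = character(),
                    start = integer(), end = integer(), translated = logical())
  truth_iso <- do.call(rbind, iso_truth)

  structure(list(
    counts = counts,
    truth = list(genes = truth_genes, uorfs = truth_uorfs,
                 isoforms = truth_iso),
    annotation = annotation,
    sequences = sequences,
    isoforms = isoforms,
    config = config
  ), class = "translatome_simulation")
}

#' @export
print.translatome_simulation <- function(x, ...) {
  cat(sprintf("translatome_simulation: %d genes, %d strata x %d libraries (seed %d)\n",
              nrow(x$truth$genes), length(x$counts),
              ncol(x$counts[[1]]$counts), x$config$seed))
  cat(sprintf("  planted: %d RNA-rhythmic, %d TE-rhythmic, %d uORF genes\n",
              sum(x$truth$genes$rna_rhythmic), sum(x$truth$genes$te_rhythmic),
              sum(x$truth$genes$has_uorf)))
  invisible(x)
}

#' Simulate transcript-coordinate ribosome footprints
#'
#' Places footprints of 26--35 nt on each primary transcript so that, after
#' A-site offsetting, a fraction \code{f_frame} of CDS A-sites falls in
#' frame 0 of the CDS (the rest uniform over the other frames), and likewise
#' for each planted translated uORF over its 5'UTR-specific span. Planted
#' non-translated uORFs receive sparse frame-uniform coverage.
#'
#' @param sim a [simulate_dataset()] result (or a list with
#'   \code{annotation}, \code{truth}, \code{config}).
#' @param offsets A-site offset table used to back-compute 5' ends
#'   (default [default_asite_offsets()]).
#' @return A \code{"footprint_alignment"} data.frame (\code{transcript_id},
#'   \code{five_prime_pos}, \code{read_length}).
#' @export
simulate_footprints <- function(sim, offsets = default_asite_offsets()) {
  config <- sim$config
  set.seed(config$seed + 1L)
  ann <- sim$annotation
  primary <- ann[!grepl("_v[0-9]+$", ann$transcript_id), , drop = FALSE]
  uorfs <- sim$truth$uorfs
  lens <- as.integer(names(offsets))
  rows <- list()
  place <- function(tx, n_reads, span_start, span_end, frame_origin, f_frame,
                    tx_len) {
    if (n_reads <= 0) return(NULL)
    pos_all <- seq(span_start, span_end - 1L)
    frame0 <- pos_all[(pos_all - frame_origin) %% 3L == 0L]
    other <- pos_all[(pos_all - frame_origin) %% 3L != 0L]
    n0 <- stats::rbinom(1, n_reads, f_frame)
    a_sites <- c(
      if (n0 > 0) frame0[sample.int(length(frame0), n0, replace = TRUE)],
      if (n_reads - n0 > 0)
        other[sample.int(length(other), n_reads - n0, replace = TRUE)]
    )
    rl <- sample(lens, length(a_sites), replace = TRUE)
    fp <- a_sites - as.integer(offsets[as.character(rl)])
    ok <- fp >= 0 & (fp + rl) <= tx_len
    data.frame(transcript_id = tx, five_prime_pos = fp[ok],
               read_length = rl[ok], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(primary))) {
    a <- primary[i, ]
    tx_len <- a$utr3_end
    rows[[length(rows) + 1]] <- place(
      a$transcript_id, config$footprint_reads_per_cds,
      a$cds_start, a$cds_end, a$cds_start, config$f_frame, tx_len)
  }
  if (nrow(uorfs) > 0) {
    ann_idx <- match(uorfs$transcript_id, primary$transcript_id)
    for (i in seq_len(nrow(uorfs))) {
      a <- primary[ann_idx[i], ]
      span_end <- min(uorfs$end[i], a$utr5_end)
      if (uorfs$translated[i]) {
        rows[[length(rows) + 1]] <- place(
          uorfs$transcript_id[i], config$footprint_reads_per_uorf,
          uorfs$start[i], span_end, uorfs$start[i], config$f_frame,
          a$utr3_end)
      } else if (stats::runif(1) < 0.5) {
        rows[[length(rows) + 1]] <- place(
          uorfs$transcript_id[i], max(3L, config$footprint_reads_per_uorf %/% 30L),
          uorfs$start[i], span_end, uorfs$start[i], 1 / 3, a$utr3_end)
      }                                     # else: zero coverage
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("footprint_alignment", "data.frame")
  out
}

#' Write all simulation outputs to a directory
#'
#' Emits the four count tables, annotation, sequences (FASTA), footprints,
#' isoform proportions and truth tables as plain-text files whose bytes are
#' a pure function of the configuration.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @param footprints optional [simulate_footprints()] table to include.
#' @return Named vector of written paths.
#' @export
write_simulation <- function(sim, dir, footprints = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(sim$counts)) {
    p <- file.path(dir, paste0("counts_", nm, ".tsv"))
    write_counts(sim$counts[[nm]], p)
    paths[paste0("counts_", nm)] <- p
  }
  p <- file.path(dir, "annotation.tsv")
  utils::write.table(as.data.frame(sim$annotation), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["annotation"] <- p
  p <- file.path(dir, "transcripts.fa")
  write_fasta(sim$sequences, p)
  paths["sequences"] <- p
  p <- file.path(dir, "isoform_proportions.tsv")
  utils::write.table(as.data.frame(sim$isoforms), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["isoforms"] <- p
  for (nm in names(sim$truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    utils::write.table(sim$truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[paste0("truth_", nm)] <- p
  }
  if (!is.null(footprints)) {
    p <- file.path(dir, "footprints.tsv")
    utils::write.table(as.data.frame(footprints), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["footprints"] <- p
  }
  paths
}
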