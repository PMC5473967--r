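#' Run the full analysis pipeline on a simulated or supplied dataset
#'
#' Executes the stages in dependency order — simulate, quantify,
#' differential TE, compensation, rhythms, phase lags, uORFs, isoform
#' divergence, clustering — and writes every declared output plus a run
#' manifest (configuration snapshot, seeds, file hashes, per-stage gene
#' counts) to \code{out_dir}. Any stage can be skipped; a stage whose inputs
#' are supplied externally through \code{config} paths runs on those instead
#' of the simulation.
#'
#' @param config a [simulation_config()] (for simulated input) or a
#'   [read_config()] list with file paths under \code{paths}
#'   (\code{counts_<organ>_<assay>}, \code{annotation}, \code{sequences},
#'   \code{footprints}, \code{isoforms}).
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all).
#' @return The run manifest (invisibly a list; also written as YAML).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "quantify", "dte",
                                    "compensation", "rhythms", "lags",
                                    "uorfs", "hellinger", "cluster")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = as.character(utils::packageVersion("dualtrans")),
                   stages = stages, files = list(), counts = list())
  thresholds <- read_config(list())
  need_file <- function(stage, nm, p) {
    if (is.null(p) || !file.exists(p))
      dt_stop("stage '", stage, "' is missing input file '", nm, "'")
    p
  }

  if (inherits(config, "simulation_config")) {
    manifest$config <- unclass(config)
    manifest$seed <- config$seed
    if ("simulate" %in% stages) {
      sim <- simulate_dataset(config)
      fps <- simulate_footprints(sim)
      paths <- write_simulation(sim, file.path(out_dir, "input"), fps)
      manifest$files <- as.list(paths)
      counts <- sim$counts
      annotation <- sim$annotation
      sequences <- sim$sequences
      isoforms <- sim$isoforms
      footprints <- fps
    } else dt_stop("a simulation_config requires the 'simulate' stage")
  } else {
    cfg <- read_config(config)
    manifest$config <- cfg
    manifest$seed <- cfg$seed
    thresholds <- cfg
    p <- cfg$paths
    if (is.null(names(p))) p <- stats::setNames(list(), character())
    counts <- list()
    for (nm in names(p)[startsWith(names(p), "counts_")])
      counts[[sub("^counts_", "", nm)]] <- read_counts(need_file("quantify", nm, p[[nm]]))
    if ("quantify" %in% stages && length(counts) == 0)
      dt_stop("stage 'quantify' is missing input file 'counts_<organ>_<assay>'")
    annotation <- if (!is.null(p$annotation))
      read_annotation(need_file("uorfs", "annotation", p$annotation)) else NULL
    sequences <- if (!is.null(p$sequences))
      read_fasta(need_file("uorfs", "sequences", p$sequences)) else NULL
    footprints <- if (!is.null(p$footprints))
      read_footprints(p$footprints, annotation) else NULL
    if ("uorfs" %in% stages && (is.null(annotation) || is.null(sequences) ||
                                is.null(footprints)))
      dt_stop("stage 'uorfs' is missing input file 'annotation', 'sequences' or 'footprints'")
    isoforms <- if (!is.null(p$isoforms))
      read_isoform_proportions(p$isoforms) else NULL
  }
  organs <- unique(unlist(lapply(counts, function(cm) cm$samples$organ)))

  ## quantify: RPKM and TE per organ
  rpkms <- te <- list()
  # externally supplied TE tables let 'dte' run without 'quantify'
  if (!inherits(config, "simulation_config")) {
    p <- manifest$config$paths
    for (nm in names(p)[startsWith(names(p), "te_")])
      te[[sub("^te_", "", nm)]] <- read_expression(p[[nm]], unit = "TE")
    if (length(te) > 0) organs <- unique(c(organs, names(te)))
  }
  if ("quantify" %in% stages) {
    all_counts <- do.call(cbind, lapply(counts, function(cm) cm$counts))
    eff <- upper_quartile_factors(count_matrix(all_counts, counts[[1]]$lengths))
    for (nm in names(counts)) {
      cm <- counts[[nm]]
      rpkms[[nm]] <- rpkm(cm, eff[colnames(cm$counts)])
      utils::write.table(
        data.frame(gene = rownames(rpkms[[nm]]), unclass(rpkms[[nm]]),
                   check.names = FALSE),
        file.path(out_dir, paste0("rpkm_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (o in organs) {
      te[[o]] <- translation_efficiency(rpkms[[paste0(o, "_RPF")]],
                                        rpkms[[paste0(o, "_RNA")]])
      utils::write.table(
        data.frame(gene = rownames(te[[o]]), unclass(te[[o]]),
                   check.names = FALSE),
        file.path(out_dir, paste0("te_", o, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    me <- measurement_error(count_matrix(all_counts, counts[[1]]$lengths), eff)
    utils::write.table(me, file.path(out_dir, "measurement_error.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$quantify <- nrow(all_counts)
  }

  if ("dte" %in% stages && length(te) == 2) {
    dte <- differential_te(te[[organs[1]]], te[[organs[2]]],
                           fdr = thresholds$fdr, fold = thresholds$te_fold)
    utils::write.table(dte, file.path(out_dir, "differential_te.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$dte <- sum(dte$differential)
  }

  if ("compensation" %in% stages && length(rpkms) == 4) {
    comp <- compensation_test(rpkms[[paste0(organs[1], "_RNA")]],
                              rpkms[[paste0(organs[2], "_RNA")]],
                              rpkms[[paste0(organs[1], "_RPF")]],
                              rpkms[[paste0(organs[2], "_RPF")]])
    utils::write.table(comp$rho, file.path(out_dir, "compensation_rho.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$compensation <- comp$n_genes
    manifest$compensation_p <- comp$p
  }

  fits <- list()
  if ("rhythms" %in% stages && length(rpkms) == 4) {
    for (nm in names(rpkms)) {
      fits[[nm]] <- call_rhythms(rpkms[[nm]],
                                 amplitude_cutoff = thresholds$amplitude_fold,
                                 pseudo = thresholds$pseudo_count)
      utils::write.table(fits[[nm]],
                         file.path(out_dir, paste0("rhythms_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$counts$rhythms <- vapply(fits, function(f) sum(f$rhythmic), 0)
  }

  if ("lags" %in% stages && length(fits) == 4) {
    for (o in organs) {
      pd <- phase_differences(fits[[paste0(o, "_RPF")]],
                              fits[[paste0(o, "_RNA")]])
      utils::write.table(pd, file.path(out_dir, paste0("phase_diff_", o, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$counts[[paste0("lags_", o)]] <- nrow(pd)
    }
  }

  if ("uorfs" %in% stages && !is.null(footprints)) {
    prof <- a_site_positions(footprints)
    primary <- annotation[!grepl("_v[0-9]+$", annotation$transcript_id), ,
                          drop = FALSE]
    recs <- list()
    for (i in seq_len(nrow(primary))) {
      r <- detect_uorfs(sequences[[primary$transcript_id[i]]], primary[i, ],
                        min_len = thresholds$uorf_min_len)
      if (nrow(r) > 0) recs[[length(recs) + 1]] <- merge_composites(r)
    }
    if (length(recs) > 0) {
      uorfs <- do.call(rbind, recs)
      uorfs <- call_translated(uorfs, prof, alpha = thresholds$uorf_alpha,
                               min_coverage = thresholds$uorf_coverage)
      utils::write.table(uorfs, file.path(out_dir, "uorfs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_uorf_bed(uorfs, file.path(out_dir, "uorfs.bed"))
      manifest$counts$uorfs <- c(candidates = nrow(uorfs),
                                 translated = sum(uorfs$translated))
    }
  }

  if ("hellinger" %in% stages && !is.null(isoforms)) {
    h <- hellinger_table(isoforms)
    utils::write.table(h, file.path(out_dir, "hellinger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$hellinger <- nrow(h)
  }

  if ("cluster" %in% stages && length(rpkms) == 4 && length(fits) == 4) {
    rhythmic <- Reduce(intersect, lapply(fits, function(f) f$gene[f$rhythmic]))
    if (length(rhythmic) >= 1) {
      mats <- lapply(rhythmic, function(g)
        profile_dissimilarity(gene_profiles(rpkms, g,
                                            pseudo = thresholds$pseudo_count)))
      fused <- fuse_dissimilarities(mats)
      tree <- hcluster(fused)
      write_newick(tree, file.path(out_dir, "cluster.nwk"))
      utils::write.table(as.data.frame(unclass(fused)),
                         file.path(out_dir, "cluster_dissimilarity.tsv"),
                         sep = "\t", quote = FALSE, row.names = TRUE)
      manifest$counts$cluster <- length(rhythmic)
    }
  }

  out_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(out_files))
  names(manifest$hashes) <- sub(paste0("^", out_dir, "/?"), "",
                                names(manifest$hashes))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
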