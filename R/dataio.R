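#' Read a transcript annotation table
#'
#' Minimal transcript-coordinate annotation: per transcript, the 5'UTR, CDS
#' and 3'UTR intervals in 0-based half-open transcript coordinates, plus the
#' gene mapping and a protein-coding flag. Intervals must be contiguous and
#' ordered 5'UTR < CDS < 3'UTR; transcripts whose CDS length is not divisible
#' by 3 are skipped with a warning.
#'
#' Expected tab-separated columns: \code{transcript_id}, \code{gene_id},
#' \code{utr5_start}, \code{utr5_end}, \code{cds_start}, \code{cds_end},
#' \code{utr3_start}, \code{utr3_end}, \code{protein_coding} (TRUE/FALSE).
#'
#' @param path file path, or a data.frame already in that layout.
#' @return data.frame of class \code{"transcript_annotation"}.
#' @export
read_annotation <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "utr5_start", "utr5_end",
            "cds_start", "cds_end", "utr3_start", "utr3_end", "protein_coding")
  if (!all(need %in% names(df)))
    dt_stop("annotation must have columns ", paste(need, collapse = ", "))
  n_in <- nrow(df)
  ok_struct <- df$utr5_start == 0 &
    df$utr5_end == df$cds_start &
    df$cds_end == df$utr3_start &
    df$utr5_end >= df$utr5_start &
    df$cds_end > df$cds_start &
    df$utr3_end >= df$utr3_start
  if (any(!ok_struct))
    dt_stop("non-contiguous or mis-ordered intervals for transcript(s): ",
            paste(utils::head(df$transcript_id[!ok_struct], 5), collapse = ", "))
  cds_len <- df$cds_end - df$cds_start
  bad_frame <- cds_len %% 3L != 0L
  if (any(bad_frame)) {
    warning(sprintf("skipping %d transcript(s) with CDS length not divisible by 3: %s",
                    sum(bad_frame),
                    paste(utils::head(df$transcript_id[bad_frame], 5), collapse = ", ")),
            call. = FALSE)
    df <- df[!bad_frame, , drop = FALSE]
  }
  dt_log("read_annotation", n_in, nrow(df))
  rownames(df) <- NULL
  class(df) <- c("transcript_annotation", "data.frame")
  df
}

#' Read a footprint alignment table
#'
#' Transcript-coordinate ribosome footprints: tab-separated columns
#' \code{transcript_id}, \code{five_prime_pos} (0-based offset of the read
#' 5' end on the transcript) and \code{read_length} (nt). Reads outside the
#' configured size window are rejected.
#'
#' @param path file path or equivalent data.frame.
#' @param annotation optional [read_annotation()] table; when given,
#'   footprints must lie within their transcript.
#' @param size_range allowed read lengths (default 26--35 nt, the RPF window).
#' @return data.frame of class \code{"footprint_alignment"}.
#' @export
read_footprints <- function(path, annotation = NULL, size_range = c(26L, 35L)) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "five_prime_pos", "read_length")
  if (!all(need %in% names(df)))
    dt_stop("footprint table must have columns ", paste(need, collapse = ", "))
  if (any(df$five_prime_pos < 0))
    dt_stop("negative five_prime_pos")
  out_of_window <- df$read_length < size_range[1] | df$read_length > size_range[2]
  if (any(out_of_window))
    dt_stop(sum(out_of_window), " footprint(s) outside the ", size_range[1], "-",
            size_range[2], " nt size window")
  if (!is.null(annotation)) {
    tx_len <- with(annotation, utr3_end)[match(df$transcript_id, annotation$transcript_id)]
    if (anyNA(tx_len))
      dt_stop("footprints on unannotated transcript(s): ",
              paste(utils::head(unique(df$transcript_id[is.na(tx_len)]), 5), collapse = ", "))
    if (any(df$five_prime_pos + df$read_length > tx_len))
      dt_stop("footprint(s) extend past transcript end")
  }
  rownames(df) <- NULL
  class(df) <- c("footprint_alignment", "data.frame")
  df
}

#' Read transcript sequences from FASTA
#'
#' RNA alphabet (U) is normalised to DNA (T) internally so annotation-derived
#' and sequencing-derived FASTA agree.
#'
#' @param path FASTA file.
#' @return Named character vector, transcript id to DNA-alphabet sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write transcript sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write uORF records as transcript-relative BED6
#'
#' One line per retained uORF: chrom = transcript id, start/end = the uORF
#' coding span (0-based half-open), name = uORF id, score = -log10 of the
#' frame-bias p-value (capped at 1000), strand = "+".
#'
#' @param uorfs data.frame from [call_translated()] / [detect_uorfs()].
#' @param path output path.
#' @export
write_uorf_bed <- function(uorfs, path) {
  score <- rep(0, nrow(uorfs))
  if ("frame_bias_p" %in% names(uorfs)) {
    p <- uorfs$frame_bias_p
    score <- ifelse(is.na(p), 0, pmin(1000, -log10(pmax(p, 1e-300))))
  }
  bed <- data.frame(
    chrom = uorfs$transcript_id,
    start = uorfs$start,
    end = uorfs$end,
    name = sprintf("%s_uORF_%d", uorfs$transcript_id, seq_len(nrow(uorfs))),
    score = round(score, 3),
    strand = "+"
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read isoform proportion tables
#'
#' Per gene and organ, the relative expression proportions of its
#' protein-coding transcript isoforms. Tab-separated columns: \code{gene_id},
#' \code{transcript_id}, \code{organ}, \code{proportion}. Proportions must be
#' non-negative and sum to 1 per gene and organ (tolerance 1e-9); absent
#' isoforms may be omitted (treated as 0).
#'
#' @param path file path or equivalent data.frame.
#' @return data.frame of class \code{"isoform_proportions"}.
#' @export
read_isoform_proportions <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "organ", "proportion")
  if (!all(need %in% names(df)))
    dt_stop("isoform table must have columns ", paste(need, collapse = ", "))
  if (any(df$proportion < 0)) dt_stop("negative isoform proportion")
  sums <- tapply(df$proportion, interaction(df$gene_id, df$organ, drop = TRUE), sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad) > 0)
    dt_stop("isoform proportions do not sum to 1 for gene x organ: ",
            paste(utils::head(bad, 5), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("isoform_proportions", "data.frame")
  df
}

#' Read an expression table (RPKM or TE) from TSV
#'
#' First column \code{gene}, remaining columns libraries named
#' \code{organ_assay_ZTxx_repN}; the inverse of the tables written by
#' [run_pipeline()].
#'
#' @param path file path.
#' @param unit value unit, \code{"RPKM"} or \code{"TE"}.
#' @return An \code{"expression_table"}.
#' @export
read_expression <- function(path, unit = "RPKM") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") dt_stop("first column must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  expression_table(m, unit = unit)
}

#' Read a pipeline configuration file
#'
#' YAML key/value file holding input paths, thresholds and seeds. Missing
#' thresholds fall back to the study defaults: FDR 0.01, TE fold gate 1.5,
#' peak-to-trough amplitude gate 1.5, uORF minimum length 18 nt, uORF coverage
#' 0.10, RPF size window 26--35 nt.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    fdr = 0.01, te_fold = 1.5, amplitude_fold = 1.5,
    uorf_min_len = 18L, uorf_coverage = 0.10, uorf_alpha = 0.05,
    rpf_size_range = c(26L, 35L), pseudo_count = 0.05, seed = 1L
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}
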