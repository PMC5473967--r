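#' Detect AUG-initiated uORFs in a transcript's 5'UTR
#'
#' Scans every AUG in the 5'UTR and extends to the first in-frame stop codon.
#' Candidates are retained when the coding span (AUG through the last codon
#' before the stop) is at least \code{min_len} nt. A uORF without an in-frame
#' stop before the CDS overlaps the CDS: in the same frame it is discarded;
#' in a different frame it is kept but only its 5'UTR-specific part counts
#' for read quantification (the countable span).
#'
#' @param sequence transcript sequence (DNA or RNA alphabet).
#' @param annotation one row of a [read_annotation()] table (or the full
#'   table; the row matching \code{transcript_id} is used).
#' @param transcript_id transcript to scan (default: the single row given).
#' @param min_len minimal coding-span length in nt (default 18; boundary
#'   included).
#' @return data.frame of class \code{"uorf_records"}: \code{transcript_id},
#'   \code{start}, \code{end} (0-based half-open coding span), \code{frame}
#'   (relative to the transcript), \code{cds_overlap} (\code{"none"} or
#'   \code{"out-of-frame"}), \code{countable_start}, \code{countable_end}
#'   (5'UTR-specific part), \code{composite} (FALSE here). Zero rows when no
#'   candidate qualifies.
#' @export
detect_uorfs <- function(sequence, annotation, transcript_id = NULL,
                         min_len = 18L) {
  ann <- as.data.frame(annotation)
  if (!is.null(transcript_id))
    ann <- ann[ann$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ann) != 1) dt_stop("need exactly one annotation row")
  seq <- chartr("Uu", "Tt", toupper(sequence))
  if (nchar(seq) != ann$utr3_end)
    dt_stop("sequence length (", nchar(seq), ") does not match annotation (",
            ann$utr3_end, ") for ", ann$transcript_id)
  utr5_end <- ann$utr5_end
  cds_start <- ann$cds_start
  stops <- c("TAA", "TAG", "TGA")
  empty <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), frame = integer(),
                      cds_overlap = character(), countable_start = integer(),
                      countable_end = integer(), composite = logical(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("uorf_records", "data.frame")
  if (utr5_end < 3) return(empty)
  # AUG starts strictly inside the 5'UTR
  aug <- gregexpr("ATG", substr(seq, 1, utr5_end), fixed = TRUE)[[1]]
  aug <- aug[aug > 0] - 1L                       # 0-based
  rows <- lapply(aug, function(a) {
    # walk codons from the AUG to the first in-frame stop, through the CDS
    # if necessary
    pos <- seq(a, nchar(seq) - 3, by = 3)
    codons <- substring(seq, pos + 1, pos + 3)
    hit <- which(codons %in% stops)
    end <- if (length(hit) > 0) pos[hit[1]] else NA_integer_  # stop start, excl.
    if (is.na(end)) return(NULL)                 # runs off the transcript
    len <- end - a
    if (len < min_len) return(NULL)
    overlap <- if (end <= utr5_end) "none"
      else if ((cds_start - a) %% 3 == 0) "in-frame"
      else "out-of-frame"
    if (overlap == "in-frame") return(NULL)      # same frame as CDS: dropped
    data.frame(transcript_id = ann$transcript_id, start = a, end = end,
               frame = a %% 3L, cds_overlap = overlap,
               countable_start = a, countable_end = min(end, utr5_end),
               composite = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  class(out) <- c("uorf_records", "data.frame")
  out
}

#' Merge overlapping uORFs into composite records
#'
#' When several uORFs of one 5'UTR overlap partially or completely, a single
#' composite uORF spanning their union is used for read counting. Disjoint
#' records pass through unchanged.
#'
#' @param records a \code{"uorf_records"} table for one transcript.
#' @return \code{"uorf_records"} with overlapping spans unioned
#'   (\code{composite = TRUE}); the frame and frame origin of a composite is
#'   that of its 5'-most constituent AUG, the countable span the union of the
#'   constituents' countable spans.
#' @export
merge_composites <- function(records) {
  if (nrow(records) <= 1) return(records)
  if (length(unique(records$transcript_id)) != 1)
    dt_stop("merge_composites expects records of a single transcript")
  r <- records[order(records$start, records$end), , drop = FALSE]
  groups <- integer(nrow(r))
  g <- 1L; cur_end <- r$end[1]; groups[1] <- g
  for (i in seq_len(nrow(r))[-1]) {
    if (r$start[i] < cur_end) {          # overlap (half-open intervals)
      groups[i] <- g
      cur_end <- max(cur_end, r$end[i])
    } else {
      g <- g + 1L
      groups[i] <- g
      cur_end <- r$end[i]
    }
  }
  rows <- lapply(split(seq_len(nrow(r)), groups), function(idx) {
    if (length(idx) == 1) return(r[idx, , drop = FALSE])
    sub <- r[idx, , drop = FALSE]
    ov <- unique(sub$cds_overlap)
    data.frame(transcript_id = sub$transcript_id[1],
               start = min(sub$start), end = max(sub$end),
               frame = sub$frame[1],          # 5'-most AUG defines the frame
               cds_overlap = if (length(ov) == 1) ov else "out-of-frame",
               countable_start = min(sub$countable_start),
               countable_end = max(sub$countable_end),
               composite = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("uorf_records", "data.frame")
  out
}

#' Call uORF translation from A-site frame bias and coverage
#'
#' Over a uORF's countable span (its 5'UTR-specific part), a uORF is
#' translated when the A-sites show significant bias towards the uORF's
#' reading frame (one-sided exact binomial test of the frame-0 count against
#' the null rate 1/3) and more than \code{min_coverage} of the countable
#' positions carry at least one A-site. Adding frame-0 reads can only move a
#' record towards a translated call.
#'
#' @param records \code{"uorf_records"} table.
#' @param profile an [a_site_positions()] table for the same transcript(s).
#' @param alpha significance level for the frame-bias test (default 0.05).
#' @param min_coverage minimal covered fraction of countable positions
#'   (default 0.10).
#' @param codon_resolution count coverage per codon instead of per nt.
#' @return The records with added columns \code{n_asites}, \code{n_frame0},
#'   \code{frame_bias_p} (NA when no A-sites), \code{coverage},
#'   \code{translated}.
#' @export
call_translated <- function(records, profile, alpha = 0.05,
                            min_coverage = 0.10, codon_resolution = FALSE) {
  n <- nrow(records)
  records$n_asites <- integer(n)
  records$n_frame0 <- integer(n)
  records$frame_bias_p <- rep(NA_real_, n)
  records$coverage <- numeric(n)
  records$translated <- logical(n)
  for (i in seq_len(n)) {
    cs <- records$countable_start[i]; ce <- records$countable_end[i]
    p <- profile$pos[profile$transcript_id == records$transcript_id[i] &
                       profile$pos >= cs & profile$pos < ce]
    ntot <- length(p)
    records$n_asites[i] <- ntot
    if (ntot == 0) next
    k <- sum((p - records$start[i]) %% 3 == 0)
    records$n_frame0[i] <- k
    # one-sided exact binomial tail: P(X >= k), X ~ Bin(n, 1/3)
    records$frame_bias_p[i] <- stats::pbinom(k - 1, ntot, 1 / 3,
                                             lower.tail = FALSE)
    if (codon_resolution) {
      cod <- unique((p - records$start[i]) %/% 3)
      n_pos <- ceiling((ce - cs) / 3)
      records$coverage[i] <- length(cod) / n_pos
    } else {
      records$coverage[i] <- length(unique(p)) / (ce - cs)
    }
    records$translated[i] <- records$frame_bias_p[i] < alpha &&
      records$coverage[i] > min_coverage
  }
  records
}

#' uORF translation efficiency per sample
#'
#' TE of a uORF span: the ratio of RPF to RNA reads whose A-sites (RPF) or
#' positions (RNA) fall in the countable span, each scaled by the library's
#' effective size (the span length cancels between numerator and
#' denominator). Missing where the RNA span count is zero.
#'
#' @param rpf_span_counts,rna_span_counts named numeric vectors of span
#'   counts per library (names are sample keys).
#' @param rpf_sizes,rna_sizes effective library sizes aligned with the count
#'   vectors.
#' @return Numeric vector of per-sample TE values, named after the RPF
#'   libraries.
#' @export
uorf_te <- function(rpf_span_counts, rna_span_counts, rpf_sizes, rna_sizes) {
  if (length(rpf_span_counts) != length(rna_span_counts))
    dt_stop("RPF and RNA span count vectors differ in length")
  te <- (rpf_span_counts / as.numeric(rpf_sizes)) /
        (rna_span_counts / as.numeric(rna_sizes))
  te[rna_span_counts == 0] <- NA_real_
  te
}

#' Kidney/liver ratio table for uORF vs CDS translation efficiency
#'
#' For genes carrying an AUG-initiated translated uORF in both organs, joins
#' the cross-organ (kidney/liver) TE ratio of the uORF with that of the main
#' CDS, and reports their association.
#'
#' @param uorf_ratio named numeric vector: per gene, kidney/liver uORF TE
#'   ratio.
#' @param cds_ratio named numeric vector: per gene, kidney/liver CDS TE
#'   ratio.
#' @return data.frame (\code{gene}, \code{uorf_te_ratio},
#'   \code{cds_te_ratio}) with attributes \code{r} (Pearson correlation of
#'   the log2 ratios) and \code{r_squared}.
#' @export
uorf_vs_cds_ratio_table <- function(uorf_ratio, cds_ratio) {
  genes <- intersect(names(uorf_ratio), names(cds_ratio))
  genes <- genes[is.finite(uorf_ratio[genes]) & is.finite(cds_ratio[genes])]
  if (length(genes) == 0)
    dt_stop("no gene has both uORF and CDS TE ratios")
  out <- data.frame(gene = genes,
                    uorf_te_ratio = unname(uorf_ratio[genes]),
                    cds_te_ratio = unname(cds_ratio[genes]))
  if (length(genes) >= 3) {
    r <- stats::cor(log2(out$uorf_te_ratio), log2(out$cds_te_ratio))
    attr(out, "r") <- r
    attr(out, "r_squared") <- r^2
  } else if (length(genes) >= 2) {
    attr(out, "r") <- stats::cor(log2(out$uorf_te_ratio), log2(out$cds_te_ratio))
    attr(out, "r_squared") <- attr(out, "r")^2
  }
  rownames(out) <- NULL
  out
}
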