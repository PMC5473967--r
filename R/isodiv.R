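#' Hellinger distance between isoform proportion vectors
#'
#' Divergence of a gene's relative transcript-isoform usage between two
#' organs: \code{H = 1/sqrt(2) * sqrt(sum_i (sqrt(pL_i) - sqrt(pK_i))^2)}.
#' H is 0 for identical isoform distributions and 1 when the expressed
#' isoform sets do not overlap. Vectors share a transcript index across
#' organs; an isoform absent from one organ carries proportion 0 there.
#'
#' @param p_liver,p_kidney non-negative proportion vectors of equal length,
#'   each summing to 1 (tolerance 1e-9).
#' @return Hellinger distance in [0, 1].
#' @examples
#' hellinger_distance(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))  # 0
#' hellinger_distance(c(1, 0), c(0, 1))                    # 1
#' @export
hellinger_distance <- function(p_liver, p_kidney) {
  if (length(p_liver) != length(p_kidney))
    dt_stop("proportion vectors differ in length")
  if (any(p_liver < 0) || any(p_kidney < 0))
    dt_stop("proportions must be non-negative")
  if (abs(sum(p_liver) - 1) > 1e-9 || abs(sum(p_kidney) - 1) > 1e-9)
    dt_stop("proportion vectors must sum to 1")
  h <- sqrt(sum((sqrt(p_liver) - sqrt(p_kidney))^2)) / sqrt(2)
  min(1, h)  # clip roundoff above the theoretical maximum
}

#' Per-gene Hellinger distances from an isoform proportion table
#'
#' @param isoforms a [read_isoform_proportions()] table covering two organs.
#' @param organs the two organ labels to compare (default: the two present).
#' @return data.frame: \code{gene}, \code{n_isoforms}, \code{hellinger}.
#' @export
hellinger_table <- function(isoforms, organs = NULL) {
  if (is.null(organs)) organs <- sort(unique(isoforms$organ))
  if (length(organs) != 2) dt_stop("need exactly two organs")
  rows <- lapply(split(isoforms, isoforms$gene_id), function(g) {
    txs <- sort(unique(g$transcript_id))
    p <- vapply(organs, function(o) {
      v <- stats::setNames(rep(0, length(txs)), txs)
      sub <- g[g$organ == o, ]
      v[sub$transcript_id] <- sub$proportion
      v
    }, numeric(length(txs)))
    if (length(txs) == 1) p <- matrix(p, nrow = 1)   # keep organs in columns
    data.frame(gene = g$gene_id[1], n_isoforms = length(txs),
               hellinger = hellinger_distance(p[, 1], p[, 2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the feature origin of cross-organ isoform divergence
#'
#' Determines which transcript feature drives a gene's isoform diversity
#' between two organs by comparing the feature sequences of all expressed
#' isoforms: \code{"identical-set"} (same isoforms at the same proportions),
#' \code{"5'UTR-only"} (expressed isoforms share CDS and 3'UTR, differ in
#' 5'UTR), \code{"5'UTR-identical"} (5'UTR shared, CDS and/or 3'UTR differ),
#' \code{"CDS-only"}, \code{"3'UTR-only"}, or \code{"mixed"}.
#'
#' @param isoforms a [read_isoform_proportions()] table for one gene and two
#'   organs.
#' @param annotation [read_annotation()] rows covering the gene's isoforms.
#' @param sequences named transcript sequences.
#' @return Character scalar, one of the categories above.
#' @export
classify_divergence <- function(isoforms, annotation, sequences) {
  organs <- sort(unique(isoforms$organ))
  if (length(organs) != 2) dt_stop("need exactly two organs")
  expressed <- sort(unique(isoforms$transcript_id[isoforms$proportion > 0]))
  unannotated <- setdiff(expressed, annotation$transcript_id)
  if (length(unannotated) > 0)
    dt_stop("unannotated isoform(s): ", paste(unannotated, collapse = ", "))
  # identical proportion vectors across organs?
  txs <- sort(unique(isoforms$transcript_id))
  prop <- vapply(organs, function(o) {
    v <- stats::setNames(rep(0, length(txs)), txs)
    sub <- isoforms[isoforms$organ == o, ]
    v[sub$transcript_id] <- sub$proportion
    v
  }, numeric(length(txs)))
  if (length(txs) == 1) prop <- matrix(prop, nrow = 1)
  if (max(abs(prop[, 1] - prop[, 2])) < 1e-9) return("identical-set")
  feat_seq <- function(tx, what) {
    a <- annotation[annotation$transcript_id == tx, ]
    bounds <- switch(what,
      utr5 = c(a$utr5_start, a$utr5_end),
      cds = c(a$cds_start, a$cds_end),
      utr3 = c(a$utr3_start, a$utr3_end))
    substr(sequences[[tx]], bounds[1] + 1, bounds[2])
  }
  differs <- vapply(c("utr5", "cds", "utr3"), function(what) {
    length(unique(vapply(expressed, feat_seq, "", what = what))) > 1
  }, logical(1))
  names(differs) <- c("utr5", "cds", "utr3")
  if (differs["utr5"] && !differs["cds"] && !differs["utr3"]) return("5'UTR-only")
  if (!differs["utr5"] && differs["cds"] && !differs["utr3"]) return("CDS-only")
  if (!differs["utr5"] && !differs["cds"] && differs["utr3"]) return("3'UTR-only")
  if (!differs["utr5"] && (differs["cds"] || differs["utr3"])) return("5'UTR-identical")
  "mixed"
}

#' Kozak context score of a start codon
#'
#' Scores the 10-nt initiation context (positions -6..-1, the AUG, and +4)
#' against the consensus \code{GccA/GccAUGG}: highly conserved positions
#' score +3 when matched (G at -6; A or G at -3; G at +4), common positions
#' +1 (C at -5, -4, -2, -1); the AUG itself is not scored. Maximum 13.
#' Positions missing because the 5'UTR is shorter than 6 nt score 0 (pad the
#' context with \code{"N"}).
#'
#' @param context 10-character string with AUG/ATG at positions 7-9.
#' @return Integer score in 0..13.
#' @examples
#' kozak_score("GCCACCAUGG")  # 13
#' @export
kozak_score <- function(context) {
  ctx <- chartr("Uu", "Tt", toupper(context))
  if (nchar(ctx) != 10)
    dt_stop("Kozak context must be exactly 10 nt (-6..-1, AUG, +4)")
  if (substr(ctx, 7, 9) != "ATG")
    dt_stop("positions 7-9 of the context must be the AUG start codon")
  nt <- strsplit(ctx, "")[[1]]
  score <- 0L
  if (nt[1] == "G") score <- score + 3L                 # -6
  if (nt[2] == "C") score <- score + 1L                 # -5
  if (nt[3] == "C") score <- score + 1L                 # -4
  if (nt[4] %in% c("A", "G")) score <- score + 3L       # -3
  if (nt[5] == "C") score <- score + 1L                 # -2
  if (nt[6] == "C") score <- score + 1L                 # -1
  if (nt[10] == "G") score <- score + 3L                # +4
  score
}

#' Transcript feature table
#'
#' Deterministic per-transcript characteristics for association analyses:
#' feature lengths, GC contents, the Kozak context score of the annotated
#' start codon, and an optional externally supplied 5'UTR minimum-free-energy
#' column.
#'
#' @param annotation a [read_annotation()] table.
#' @param sequences named transcript sequences matching the annotation.
#' @param mfe optional named numeric vector of pre-computed 5'UTR MFE values.
#' @return data.frame with one row per transcript: lengths (nt) and GC
#'   fractions of the transcript, 5'UTR, CDS and 3'UTR (GC is NA for empty
#'   features), \code{kozak}, and \code{utr5_mfe} when supplied.
#' @export
feature_table <- function(annotation, sequences, mfe = NULL) {
  gc_frac <- function(s) {
    if (nchar(s) == 0) return(NA_real_)
    nt <- strsplit(s, "")[[1]]
    sum(nt %in% c("G", "C")) / length(nt)
  }
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    a <- annotation[i, ]
    s <- sequences[[a$transcript_id]]
    if (is.null(s)) dt_stop("no sequence for ", a$transcript_id)
    s <- chartr("Uu", "Tt", toupper(s))
    if (nchar(s) != a$utr3_end)
      dt_stop("sequence/annotation length mismatch for ", a$transcript_id)
    utr5 <- substr(s, a$utr5_start + 1, a$utr5_end)
    cds <- substr(s, a$cds_start + 1, a$cds_end)
    utr3 <- substr(s, a$utr3_start + 1, a$utr3_end)
    up <- substr(s, max(1, a$cds_start - 5), a$cds_start)
    ctx <- paste0(strrep("N", 6 - nchar(up)), up,
                  substr(s, a$cds_start + 1, a$cds_start + 4))
    data.frame(
      transcript_id = a$transcript_id, gene_id = a$gene_id,
      tx_len = nchar(s), utr5_len = nchar(utr5), cds_len = nchar(cds),
      utr3_len = nchar(utr3),
      tx_gc = gc_frac(s), utr5_gc = gc_frac(utr5), cds_gc = gc_frac(cds),
      utr3_gc = gc_frac(utr3),
      kozak = if (nchar(ctx) == 10 && substr(ctx, 7, 9) == "ATG")
        kozak_score(ctx) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(mfe)) out$utr5_mfe <- unname(mfe[out$transcript_id])
  rownames(out) <- NULL
  out
}
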