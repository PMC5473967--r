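#' Construct a validated count matrix
#'
#' Container for CDS-mapping read counts of one organ x assay stratum (or any
#' set of libraries), together with per-gene feature lengths. Counts are
#' non-negative integers; gene ids are unique; columns parse as sample keys.
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids,
#'   colnames are sample names in \code{organ_assay_ZTxx_repN} form.
#' @param lengths data.frame with columns \code{gene}, \code{utr5_len},
#'   \code{cds_len}, \code{utr3_len} (nt); must cover all genes in
#'   \code{counts}.
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts}, \code{lengths} and \code{samples} (parsed keys).
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    dt_stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    dt_stop("duplicate gene ids: ",
            paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    dt_stop("negative count at gene '", rownames(counts)[neg[1, 1]],
            "', sample '", colnames(counts)[neg[1, 2]], "'")
  if (any(counts != round(counts)))
    dt_stop("counts must be integers")
  samples <- parse_sample_keys(colnames(counts))
  lengths <- as.data.frame(lengths)
  need <- c("gene", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(lengths)))
    dt_stop("lengths must have columns ", paste(need, collapse = ", "))
  miss <- setdiff(rownames(counts), lengths$gene)
  if (length(miss) > 0)
    dt_stop("genes missing from lengths: ", paste(utils::head(miss, 5), collapse = ", "))
  lengths <- lengths[match(rownames(counts), lengths$gene), , drop = FALSE]
  rownames(lengths) <- NULL
  if (any(lengths$cds_len <= 0))
    dt_stop("CDS lengths must be > 0")
  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  organs: ", paste(unique(x$samples$organ), collapse = ", "),
      "; assays: ", paste(unique(x$samples$assay), collapse = ", "), "\n", sep = "")
  cat("  timepoints: ", paste(sort(unique(x$samples$timepoint)), collapse = ", "),
      " (h); replicates: ", paste(sort(unique(x$samples$replicate)), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read / write count tables
#'
#' Tab-separated, genes as rows. The first four columns are \code{gene},
#' \code{utr5_len}, \code{cds_len}, \code{utr3_len}; remaining columns are
#' libraries named \code{organ_assay_ZTxx_repN}. \code{write_counts} and
#' \code{read_counts} round-trip exactly.
#'
#' @param path file path.
#' @return \code{read_counts}: a [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(df)[1:4]))
    dt_stop("count table must start with columns ", paste(need, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  cn <- as.matrix(df[, sample_cols, drop = FALSE])
  if (any(is.na(cn)))
    dt_stop("missing count values in ", path)
  rownames(cn) <- df$gene
  count_matrix(cn, df[, need])
}

#' @param x a [count_matrix()].
#' @rdname read_counts
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  out <- cbind(x$lengths[, c("gene", "utr5_len", "cds_len", "utr3_len")],
               as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a count matrix by sample predicate
#'
#' @param x a [count_matrix()].
#' @param organ,assay optional filters; \code{NULL} keeps all.
#' @return A [count_matrix()] with the selected libraries.
#' @export
subset_samples <- function(x, organ = NULL, assay = NULL) {
  keep <- rep(TRUE, ncol(x$counts))
  if (!is.null(organ)) keep <- keep & x$samples$organ %in% organ
  if (!is.null(assay)) keep <- keep & x$samples$assay %in% assay
  if (!any(keep)) dt_stop("no libraries match the requested organ/assay")
  count_matrix(x$counts[, keep, drop = FALSE], x$lengths)
}
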