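#' Upper-quartile effective library sizes
#'
#' Library scaling for count tables: per library, the normalization factor is
#' the 75th percentile of the counts of genes with a positive count in that
#' library, divided by the raw library size; factors are then rescaled to
#' geometric mean 1 and the effective size of a library is its raw size times
#' its factor. RPKM computed against these effective sizes is invariant under
#' global depth rescaling of any one library.
#'
#' @param x a [count_matrix()].
#' @return Named numeric vector of effective library sizes (one per library),
#'   with attributes \code{factors} (geometric-mean-1 factors) and
#'   \code{raw_sizes}.
#' @export
upper_quartile_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  raw <- colSums(counts)
  if (any(raw == 0))
    dt_stop("all-zero library: ", paste(colnames(counts)[raw == 0], collapse = ", "))
  uq <- apply(counts, 2, function(cc) {
    pos <- cc[cc > 0]
    stats::quantile(pos, 0.75, names = FALSE, type = 7)
  })
  f <- uq / raw
  f <- f / exp(mean(log(f)))          # rescale to geometric mean 1
  eff <- raw * f
  attr(eff, "factors") <- f
  attr(eff, "raw_sizes") <- raw
  eff
}

#' RPKM expression table
#'
#' Reads per kilobase of feature per effective million:
#' \code{RPKM = count / (length/1000) / (effective_size/1e6)}. No
#' mappable-length ("faux reads") correction is applied.
#'
#' @param x a [count_matrix()].
#' @param effective_sizes per-library effective sizes, e.g. from
#'   [upper_quartile_factors()]; defaults to computing them from \code{x}.
#' @param lengths per-gene feature lengths in nt; defaults to the CDS lengths
#'   carried by \code{x} (counts are CDS counts).
#' @return An \code{"expression_table"}: numeric genes x samples matrix with
#'   parsed sample keys in attribute \code{samples} and \code{unit = "RPKM"}.
#' @export
rpkm <- function(x, effective_sizes = NULL, lengths = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(effective_sizes)) effective_sizes <- upper_quartile_factors(x)
  if (is.null(lengths)) lengths <- x$lengths$cds_len
  if (length(effective_sizes) != ncol(x$counts))
    dt_stop("effective_sizes length does not match the number of libraries")
  if (any(lengths <= 0)) dt_stop("feature lengths must be > 0")
  v <- x$counts / (lengths / 1000)
  v <- sweep(v, 2, as.numeric(effective_sizes) / 1e6, "/")
  expression_table(v, unit = "RPKM")
}

expression_table <- function(values, unit) {
  values <- as.matrix(values)
  samples <- parse_sample_keys(colnames(values))
  structure(values, samples = samples, unit = unit,
            class = c("expression_table", class(values)))
}

#' @export
print.expression_table <- function(x, ...) {
  s <- attr(x, "samples")
  cat(sprintf("expression_table [%s]: %d genes x %d libraries (%s / %s)\n",
              attr(x, "unit"), nrow(x), ncol(x),
              paste(unique(s$organ), collapse = ","),
              paste(unique(s$assay), collapse = ",")))
  invisible(x)
}

# Subsetting keeps metadata in step with the retained columns; dropping to a
# vector behaves like a plain matrix.
#' @export
`[.expression_table` <- function(x, i, j, ..., drop = TRUE) {
  s <- attr(x, "samples"); u <- attr(x, "unit")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    keep <- match(colnames(out), s$sample)
    attr(out, "samples") <- s[keep, , drop = FALSE]
    attr(out, "unit") <- u
    class(out) <- c("expression_table", "matrix", "array")
  }
  out
}

#' Translation efficiency
#'
#' Relative TE per gene and sample: the ratio of RPF-RPKM to RNA-RPKM for the
#' same organ, timepoint and replicate. TE is undefined (NA) where the RNA
#' RPKM is zero; the gene is retained.
#'
#' @param rpf,rna \code{"expression_table"}s in RPKM, one RPF and one RNA,
#'   with matching genes and matching (organ, timepoint, replicate) keys.
#' @return An \code{"expression_table"} of TE values; columns are named after
#'   the RPF libraries.
#' @export
translation_efficiency <- function(rpf, rna) {
  sp <- attr(rpf, "samples"); sn <- attr(rna, "samples")
  key <- function(s) paste(s$organ, s$timepoint, s$replicate, sep = "|")
  if (!setequal(key(sp), key(sn)) || nrow(sp) != nrow(sn)) {
    unmatched <- c(setdiff(key(sp), key(sn)), setdiff(key(sn), key(sp)))
    dt_stop("RPF/RNA sample keys do not match: ", paste(unmatched, collapse = ", "))
  }
  if (!identical(rownames(rpf), rownames(rna))) {
    if (!setequal(rownames(rpf), rownames(rna)))
      dt_stop("RPF/RNA gene sets differ")
    rna <- rna[rownames(rpf), , drop = FALSE]
    sn <- attr(rna, "samples")
  }
  ord <- match(key(sp), key(sn))
  denom <- unclass(rna)[, ord, drop = FALSE]
  te <- unclass(rpf) / denom
  te[denom == 0] <- NA_real_
  colnames(te) <- colnames(rpf)
  expression_table(te, unit = "TE")
}

#' Replicate measurement error by expression decile
#'
#' Quantifies technical reproducibility separately per organ and assay.
#' Genes are binned into \code{n_bins} deciles of overall expression, defined
#' as the fourth root of the product of the four stratum means (liver RNA x
#' liver RPF x kidney RNA x kidney RPF mean normalised counts). Within a bin,
#' for each organ x assay and each timepoint t, the measurement error is
#' \code{ME_t = mean_g (log x_g1 - log x_g2)^2 / 2} over the two replicates,
#' on natural log of (normalised count + pseudo); the 12 timepoints provide
#' the spread of the estimate.
#'
#' @param counts a [count_matrix()] holding all four organ x assay strata
#'   (the full 96-library design, or any complete 2-replicate subset).
#' @param effective_sizes per-library effective sizes; default recomputed.
#' @param n_bins number of expression bins (default 10).
#' @param pseudo pseudo-count added before the log (default 0.5).
#' @param filter_ratio when \code{TRUE}, genes whose mean expression ratio
#'   (between organs or between RNA and RPF) exceeds 2 at all timepoints are
#'   excluded before binning.
#' @return data.frame with one row per bin x organ x assay: bin index and
#'   bounds, mean ME over timepoints (\code{me}, log^2 units) and its spread
#'   (\code{me_sd}), plus gene count per bin.
#' @export
measurement_error <- function(counts, effective_sizes = NULL, n_bins = 10,
                              pseudo = 0.5, filter_ratio = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(effective_sizes)) effective_sizes <- upper_quartile_factors(counts)
  s <- counts$samples
  if (!all(tapply(s$replicate, interaction(s$organ, s$assay, s$timepoint),
                  function(r) setequal(r, 1:2))))
    dt_stop("measurement_error requires exactly 2 replicates per organ x assay x timepoint")
  # normalised counts: scale every library to the geometric-mean effective size
  norm <- sweep(counts$counts, 2, as.numeric(effective_sizes) /
                  exp(mean(log(effective_sizes))), "/")
  strata <- unique(s[, c("organ", "assay")])
  stratum_mean <- sapply(seq_len(nrow(strata)), function(i) {
    sel <- s$organ == strata$organ[i] & s$assay == strata$assay[i]
    rowMeans(norm[, sel, drop = FALSE])
  })
  overall <- apply(stratum_mean, 1, function(v) prod(v)^(1 / length(v)))
  n_in <- nrow(norm)
  keep <- rep(TRUE, n_in)
  if (filter_ratio) {
    lx <- log(norm + pseudo)
    tps <- sort(unique(s$timepoint))
    # per-timepoint mean log expression per stratum (over the 2 replicates)
    high_all <- rep(FALSE, n_in)
    pair_ids <- utils::combn(nrow(strata), 2)
    for (k in seq_len(ncol(pair_ids))) {
      i <- pair_ids[1, k]; j <- pair_ids[2, k]
      ratio_high <- rep(TRUE, n_in)
      for (tp in tps) {
        si <- s$organ == strata$organ[i] & s$assay == strata$assay[i] & s$timepoint == tp
        sj <- s$organ == strata$organ[j] & s$assay == strata$assay[j] & s$timepoint == tp
        r <- abs(rowMeans(lx[, si, drop = FALSE]) - rowMeans(lx[, sj, drop = FALSE]))
        ratio_high <- ratio_high & r > log(2)
      }
      high_all <- high_all | ratio_high
    }
    keep <- !high_all
  }
  dt_log("measurement_error gene filter", n_in, sum(keep))
  overall <- overall[keep]
  norm <- norm[keep, , drop = FALSE]
  bin <- cut(rank(overall, ties.method = "first"),
             breaks = stats::quantile(rank(overall, ties.method = "first"),
                                      probs = seq(0, 1, length.out = n_bins + 1)),
             include.lowest = TRUE, labels = FALSE)
  tps <- sort(unique(s$timepoint))
  out <- list()
  for (i in seq_len(nrow(strata))) {
    for (b in seq_len(n_bins)) {
      g <- bin == b
      me_t <- vapply(tps, function(tp) {
        c1 <- s$organ == strata$organ[i] & s$assay == strata$assay[i] &
          s$timepoint == tp & s$replicate == 1
        c2 <- s$organ == strata$organ[i] & s$assay == strata$assay[i] &
          s$timepoint == tp & s$replicate == 2
        d <- log(norm[g, c1] + pseudo) - log(norm[g, c2] + pseudo)
        mean(d^2) / 2
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        organ = strata$organ[i], assay = strata$assay[i], bin = b,
        bin_lo = min(overall[g]), bin_hi = max(overall[g]),
        n_genes = sum(g), me = mean(me_t), me_sd = stats::sd(me_t)
      )
    }
  }
  do.call(rbind, out)
}
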