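#' Per-gene dissimilarity between the four organ x assay profiles
#'
#' For one gene, the 4x4 matrix of Euclidean distances between its
#' replicate-averaged 12-point log2 time courses in kidney-RNA, kidney-RPF,
#' liver-RNA and liver-RPF.
#'
#' @param profiles numeric 4 x 12 matrix (rows named by profile, columns the
#'   ZT grid); no missing values.
#' @return Symmetric 4x4 matrix of class \code{"profile_dissimilarity"} with
#'   zero diagonal.
#' @export
profile_dissimilarity <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles)) dt_stop("profiles contain missing timepoints")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
  d <- as.matrix(stats::dist(profiles, method = "euclidean"))
  structure(d, class = c("profile_dissimilarity", class(d)))
}

#' Weighted fusion of per-gene dissimilarity matrices
#'
#' Elementwise weighted mean of the genes' dissimilarity matrices; the
#' default weights are equal.
#'
#' @param matrices list of equally sized [profile_dissimilarity()] matrices.
#' @param weights non-negative weights, one per matrix, not all zero
#'   (default equal).
#' @return The fused matrix.
#' @export
fuse_dissimilarities <- function(matrices, weights = NULL) {
  if (length(matrices) == 0) dt_stop("no matrices to fuse")
  dims <- vapply(matrices, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    dt_stop("dissimilarity matrices differ in dimension: ",
            paste(unique(dims), collapse = " vs "))
  if (is.null(weights)) weights <- rep(1, length(matrices))
  if (length(weights) != length(matrices))
    dt_stop("one weight per matrix required")
  if (any(weights < 0) || sum(weights) == 0)
    dt_stop("weights must be non-negative and not all zero")
  acc <- matrices[[1]] * weights[1]
  for (i in seq_along(matrices)[-1]) acc <- acc + matrices[[i]] * weights[i]
  out <- acc / sum(weights)
  structure(as.matrix(out), class = c("profile_dissimilarity", "matrix", "array"))
}

#' Average-linkage hierarchical clustering of profile dissimilarities
#'
#' Agglomerative clustering (UPGMA) of the four organ x assay profiles (or
#' any dissimilarity matrix). Ties in the agglomeration are broken
#' deterministically by lexicographic leaf label.
#'
#' @param d symmetric dissimilarity matrix with labelled rows.
#' @param linkage agglomeration method (default \code{"average"}).
#' @return An \code{hclust} tree.
#' @export
hcluster <- function(d, linkage = "average") {
  d <- as.matrix(d)
  ord <- order(rownames(d))   # lexicographic labels give a fixed tie-break
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' First merge of a clustering tree
#'
#' @param tree an \code{hclust} object.
#' @return Character vector of the two leaf labels merged first.
#' @export
first_merge <- function(tree) {
  m <- tree$merge[1, ]
  if (any(m > 0)) dt_stop("first merge is not a leaf pair")
  sort(tree$labels[-m])
}

#' Export a clustering tree as Newick
#'
#' @param tree an \code{hclust} object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}

#' Build the four organ x assay profiles of a gene
#'
#' Replicate-averaged log2 time courses from the four RPKM tables, ordered
#' kidney_RNA, kidney_RPF, liver_RNA, liver_RPF.
#'
#' @param tables named list of four RPKM \code{"expression_table"}s with
#'   names like \code{kidney_RNA}; each covering one organ x assay stratum.
#' @param gene gene id.
#' @param pseudo pseudo-count before log2 (default 0.05).
#' @param zscore standardise each profile to mean 0, sd 1 (default FALSE).
#' @return 4 x 12 matrix suitable for [profile_dissimilarity()].
#' @export
gene_profiles <- function(tables, gene, pseudo = 0.05, zscore = FALSE) {
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    s <- attr(tb, "samples")
    y <- log2(unclass(tb)[gene, ] + pseudo)
    prof <- tapply(y, s$timepoint, mean)
    prof[order(as.numeric(names(prof)))]
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(tables)
  if (zscore) m <- t(scale(t(m)))
  m
}
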