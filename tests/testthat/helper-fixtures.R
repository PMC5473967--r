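# Shared fixture builders and independent oracles. Everything is generated in
# code; no fixture files.

# A tiny count matrix over the full 4-tuple key space (1 organ x 1 assay by
# default), with controllable counts.
toy_counts <- function(counts, organ = "kidney", assay = "RNA",
                       timepoints = c(0, 2), replicates = 1:2,
                       cds_len = 300L) {
  keys <- as.vector(outer(replicates, timepoints, function(r, t)
    format_sample_keys(organ, assay, t, r)))
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(keys))
  colnames(counts) <- keys
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(gene = rownames(counts), utr5_len = 100L,
                                  cds_len = cds_len, utr3_len = 100L))
}

# Expression table straight from a value matrix (columns must be sample keys).
toy_expression <- function(values, organ = "kidney", assay = "RNA",
                           timepoints = seq(0, 22, 2), replicates = 1:2,
                           unit = "RPKM") {
  keys <- unlist(lapply(timepoints, function(t)
    format_sample_keys(organ, assay, t, replicates)))
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(keys))
  colnames(values) <- keys
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  dualtrans:::expression_table(values, unit = unit)
}

# One-transcript annotation row.
toy_annotation <- function(utr5, cds, utr3, transcript_id = "tx1",
                           gene_id = "g1") {
  read_annotation(data.frame(
    transcript_id = transcript_id, gene_id = gene_id,
    utr5_start = 0L, utr5_end = utr5,
    cds_start = utr5, cds_end = utr5 + cds,
    utr3_start = utr5 + cds, utr3_end = utr5 + cds + utr3,
    protein_coding = TRUE))
}

# Transcript sequence with a given 5'UTR and a valid CDS/3'UTR.
toy_transcript <- function(utr5_seq, cds_codons = 100, utr3_len = 50,
                           seed = 42) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  cds <- paste0("ATG", paste(sample(sense, cds_codons - 2, replace = TRUE),
                             collapse = ""), "TAA")
  utr3 <- paste(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
                collapse = "")
  list(seq = paste0(utr5_seq, cds, utr3),
       ann = toy_annotation(nchar(utr5_seq), nchar(cds), utr3_len))
}

# A-site profile from explicit positions.
toy_profile <- function(pos, transcript_id = "tx1") {
  structure(data.frame(transcript_id = rep(transcript_id, length(pos)),
                       pos = pos,
                       read_length = rep(30L, length(pos))),
            class = c("asite_profile", "data.frame"))
}

# uORF record(s) from explicit spans.
toy_uorf_records <- function(start, end, transcript_id = "tx1",
                             countable_end = end) {
  structure(data.frame(
    transcript_id = transcript_id, start = start, end = end,
    frame = start %% 3L, cds_overlap = "none",
    countable_start = start, countable_end = countable_end,
    composite = FALSE, stringsAsFactors = FALSE
  ), class = c("uorf_records", "data.frame"))
}

## --- independent oracles -------------------------------------------------

# Brute-force uORF enumerator: finds every AUG in the 5'UTR and every stop in
# the transcript, then pairs each AUG with its nearest in-frame stop. Written
# against the rules, not against the implementation.
oracle_uorfs <- function(seq, utr5_end, cds_start, min_len = 18) {
  seq <- toupper(seq)
  augs <- c()
  for (i in seq_len(max(0, utr5_end - 2)))
    if (substr(seq, i, i + 2) == "ATG") augs <- c(augs, i - 1L)
  stops <- c()
  for (i in seq_len(nchar(seq) - 2))
    if (substr(seq, i, i + 2) %in% c("TAA", "TAG", "TGA"))
      stops <- c(stops, i - 1L)
  out <- NULL
  for (a in augs) {
    sp <- stops[stops >= a + 3 & (stops - a) %% 3 == 0]
    if (length(sp) == 0) next
    e <- min(sp)
    if (e - a < min_len) next
    overlap <- if (e <= utr5_end) "none"
      else if ((cds_start - a) %% 3 == 0) "in-frame" else "out-of-frame"
    if (overlap == "in-frame") next
    out <- rbind(out, data.frame(start = a, end = e, cds_overlap = overlap))
  }
  out
}

# Random 5'UTR able to contain AUGs and stops in any frame.
random_utr5 <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Average-linkage agglomeration by exhaustive recomputation (4 leaves).
oracle_average_linkage_merges <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
    }
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]],
                                           clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Leaves under each merge node of an hclust tree.
hclust_merge_members <- function(tree) {
  members <- list()
  for (i in seq_len(nrow(tree$merge))) {
    get <- function(k) if (k < 0) tree$labels[-k] else members[[k]]
    members[[i]] <- sort(c(get(tree$merge[i, 1]), get(tree$merge[i, 2])))
  }
  members
}
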