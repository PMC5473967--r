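#' Default A-site offset table
#'
#' Ribosome A-site position inferred from a footprint's 5' end plus a
#' length-dependent offset: +14 nt for 26--30 nt reads, +15 nt for 31--35 nt
#' reads. Exposed so the table can be replaced per protocol.
#'
#' @return Named integer vector, read length (nt) to offset (nt).
#' @export
default_asite_offsets <- function() {
  stats::setNames(c(rep(14L, 5), rep(15L, 5)), 26:35)
}

#' A-site positions from footprint alignments
#'
#' For each footprint the A-site is \code{five_prime_pos + offset(read_length)}.
#' Reads with a length absent from the offset table are dropped and logged.
#'
#' @param footprints a [read_footprints()] table.
#' @param offsets named vector, read length to offset nt
#'   (default [default_asite_offsets()]).
#' @return data.frame of class \code{"asite_profile"} with columns
#'   \code{transcript_id}, \code{pos} (0-based A-site transcript coordinate)
#'   and \code{read_length}; attribute \code{offsets} records the table used.
#' @export
a_site_positions <- function(footprints, offsets = default_asite_offsets()) {
  off <- offsets[as.character(footprints$read_length)]
  n_in <- nrow(footprints)
  keep <- !is.na(off)
  dt_log("a_site_positions (lengths in offset table)", n_in, sum(keep))
  out <- data.frame(
    transcript_id = footprints$transcript_id[keep],
    pos = footprints$five_prime_pos[keep] + as.integer(off[keep]),
    read_length = footprints$read_length[keep]
  )
  structure(out, offsets = offsets,
            class = c("asite_profile", "data.frame"))
}

#' Reading-frame statistics for a translation unit
#'
#' Counts A-sites per reading frame relative to a unit's start codon (the
#' annotated CDS, or a uORF span). Frame 0 is the frame of the start codon.
#'
#' @param profile an [a_site_positions()] table.
#' @param transcript_id transcript holding the unit.
#' @param unit_start,unit_end 0-based half-open span of the unit.
#' @param frame_origin position defining frame 0 (default \code{unit_start}).
#' @return List of class \code{"frame_stats"}: \code{counts} (f0, f1, f2),
#'   \code{fractions} (NA when the unit holds no A-sites), \code{total}.
#' @export
frame_stats <- function(profile, transcript_id, unit_start, unit_end,
                        frame_origin = unit_start) {
  p <- profile$pos[profile$transcript_id == transcript_id &
                     profile$pos >= unit_start & profile$pos < unit_end]
  fr <- (p - frame_origin) %% 3
  counts <- stats::setNames(tabulate(fr + 1L, 3L), c("f0", "f1", "f2"))
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else stats::setNames(rep(NA_real_, 3), names(counts))
  structure(list(counts = counts, fractions = fractions, total = total),
            class = "frame_stats")
}

#' @export
print.frame_stats <- function(x, ...) {
  cat("frame_stats:", x$total, "A-sites; fractions",
      paste(sprintf("%s=%.3f", names(x$fractions), x$fractions), collapse = " "), "\n")
  invisible(x)
}

#' Metagene density around start and stop codons
#'
#' Average A-site density in windows anchored at the CDS start and stop, over
#' genes passing the expression and length filters used for periodicity
#' analysis: average RPF RPKM above \code{min_rpkm} and CDS longer than
#' \code{min_cds_nt}. Per-transcript densities are normalised to mean 1 over
#' the window before averaging, so every gene contributes equally.
#'
#' @param profile an [a_site_positions()] table.
#' @param annotation a [read_annotation()] table.
#' @param window_nt half-window width in nt around each anchor (default 60).
#' @param mean_rpkm optional named per-transcript average RPF RPKM used for
#'   the \code{min_rpkm} filter; \code{NULL} disables that filter.
#' @param min_rpkm,min_cds_nt gene filters (defaults 5 RPKM, 400 nt).
#' @return List of class \code{"metagene"} with numeric vectors \code{start}
#'   and \code{stop} (positions -window..window relative to the anchor) and
#'   \code{n_transcripts}.
#' @export
metagene <- function(profile, annotation, window_nt = 60,
                     mean_rpkm = NULL, min_rpkm = 5, min_cds_nt = 400) {
  ann <- annotation
  keep <- (ann$cds_end - ann$cds_start) > min_cds_nt
  if (!is.null(mean_rpkm))
    keep <- keep & (mean_rpkm[ann$transcript_id] > min_rpkm) %in% TRUE
  n_in <- nrow(ann)
  ann <- ann[keep, , drop = FALSE]
  dt_log("metagene transcript filters", n_in, nrow(ann))
  if (nrow(ann) == 0) dt_stop("no transcript passes the metagene filters")
  rel <- seq(-window_nt, window_nt)
  acc_start <- acc_stop <- numeric(length(rel))
  n_used <- 0L
  by_tx <- split(profile$pos, profile$transcript_id)
  for (i in seq_len(nrow(ann))) {
    pos <- by_tx[[ann$transcript_id[i]]]
    if (is.null(pos) || length(pos) == 0) next
    for (anchor in c("start", "stop")) {
      a <- if (anchor == "start") ann$cds_start[i] else ann$cds_end[i] - 3L
      d <- pos - a
      d <- d[d >= -window_nt & d <= window_nt]
      dens <- tabulate(d + window_nt + 1L, length(rel))
      m <- mean(dens)
      if (m > 0) dens <- dens / m
      if (anchor == "start") acc_start <- acc_start + dens
      else acc_stop <- acc_stop + dens
    }
    n_used <- n_used + 1L
  }
  if (n_used == 0) dt_stop("no qualifying transcript has A-site coverage")
  structure(list(
    position = rel,
    start = acc_start / n_used,
    stop = acc_stop / n_used,
    n_transcripts = n_used
  ), class = "metagene")
}

#' @export
print.metagene <- function(x, ...) {
  cat(sprintf("metagene: %d transcripts, window +/-%d nt\n",
              x$n_transcripts, max(x$position)))
  invisible(x)
}

#' @export
plot.metagene <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$position, x$start, type = "h", xlab = "nt from CDS start",
                 ylab = "mean density", main = "start", ...)
  graphics::plot(x$position, x$stop, type = "h", xlab = "nt from stop codon",
                 ylab = "mean density", main = "stop", ...)
  invisible(x)
}
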