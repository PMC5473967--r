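#' Parse sample-column names into sample keys
#'
#' A library in the two-organ around-the-clock design is identified by the
#' 4-tuple (organ, assay, timepoint, replicate) and encoded in column names as
#' \code{organ_assay_ZTxx_repN}, e.g. \code{kidney_RPF_ZT02_rep1}. The full
#' design comprises 96 libraries: 2 organs x 2 assays x 12 timepoints x 2
#' replicates.
#'
#' @param x character vector of sample names.
#' @return A data.frame with columns \code{sample} (the input name),
#'   \code{organ}, \code{assay} (\code{"RPF"} or \code{"RNA"}),
#'   \code{timepoint} (ZT hours, numeric) and \code{replicate} (integer).
#' @examples
#' parse_sample_keys(c("kidney_RPF_ZT02_rep1", "liver_RNA_ZT14_rep2"))
#' @export
parse_sample_keys <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9]+)_(RPF|RNA)_ZT([0-9]{1,2})_rep([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    dt_stop("malformed sample name(s): ", paste(x[bad], collapse = ", "),
            " (expected organ_assay_ZTxx_repN)")
  }
  data.frame(
    sample    = x,
    organ     = vapply(m, `[`, "", 2L),
    assay     = vapply(m, `[`, "", 3L),
    timepoint = as.numeric(vapply(m, `[`, "", 4L)),
    replicate = as.integer(vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Format sample keys as column names
#'
#' Inverse of [parse_sample_keys()].
#'
#' @param organ,assay character vectors.
#' @param timepoint ZT hours.
#' @param replicate replicate index.
#' @return Character vector \code{organ_assay_ZTxx_repN}.
#' @export
format_sample_keys <- function(organ, assay, timepoint, replicate) {
  sprintf("%s_%s_ZT%02d_rep%d", organ, assay, as.integer(timepoint),
          as.integer(replicate))
}
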