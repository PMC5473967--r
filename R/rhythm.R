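#' Genome-wide rhythm calling
#'
#' Fits the flat-vs-harmonic model pair ([fit_harmonic()]) to every gene of an
#' expression table (one organ x assay stratum) and applies the amplitude
#' gate. Values are log2-transformed with a pseudo-count before fitting
#' unless already on the log scale.
#'
#' @param table an \code{"expression_table"} (RPKM or TE) for one stratum.
#' @param amplitude_cutoff minimal peak-to-trough fold (default 1.5).
#' @param log2_transform apply \code{log2(x + pseudo)} first (default TRUE).
#' @param pseudo pseudo-count (default 0.05 RPKM).
#' @return data.frame of class \code{"rhythm_calls"}, one row per gene:
#'   \code{gene}, \code{organ}, \code{assay}, \code{mesor}, \code{a},
#'   \code{b}, \code{amp}, \code{phase}, \code{fold}, \code{aic_rhythmic},
#'   \code{aic_flat}, \code{rhythmic}.
#' @export
call_rhythms <- function(table, amplitude_cutoff = 1.5, log2_transform = TRUE,
                         pseudo = 0.05) {
  s <- attr(table, "samples")
  v <- unclass(table)
  if (log2_transform) v <- log2(v + pseudo)
  organ <- paste(unique(s$organ), collapse = "+")
  assay <- paste(unique(s$assay), collapse = "+")
  rows <- lapply(rownames(v), function(g) {
    y <- v[g, ]
    ok <- is.finite(y)
    if (sum(ok) < 3) return(NULL)
    f <- fit_harmonic(s$timepoint[ok], y[ok], amplitude_cutoff = amplitude_cutoff)
    data.frame(gene = g, organ = organ, assay = assay,
               mesor = unname(f$coefficients["mesor"]),
               a = unname(f$coefficients["a"]), b = unname(f$coefficients["b"]),
               amp = f$amp, phase = f$phase, fold = f$fold,
               aic_rhythmic = f$aic_rhythmic, aic_flat = f$aic_flat,
               rhythmic = f$rhythmic)
  })
  out <- do.call(rbind, rows)
  dt_log(sprintf("call_rhythms %s/%s", organ, assay), nrow(v), sum(out$rhythmic))
  rownames(out) <- NULL
  class(out) <- c("rhythm_calls", "data.frame")
  out
}

#' Overlap of rhythmic gene sets across strata
#'
#' @param ... named \code{"rhythm_calls"} tables (e.g. \code{RNA = ...,
#'   RPF = ...}).
#' @return List with per-stratum rhythmic gene vectors, all pairwise
#'   intersections, and the intersection of all strata (\code{all}).
#' @export
rhythm_overlap <- function(...) {
  calls <- list(...)
  if (length(calls) == 1 && is.list(calls[[1]]) && !inherits(calls[[1]], "data.frame"))
    calls <- calls[[1]]
  sets <- lapply(calls, function(cc) cc$gene[cc$rhythmic])
  pairs <- list()
  nm <- names(sets)
  if (length(sets) > 1) {
    idx <- utils::combn(length(sets), 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      pairs[[paste(nm[i], nm[j], sep = "&")]] <- intersect(sets[[i]], sets[[j]])
    }
  }
  list(sets = sets, pairwise = pairs, all = Reduce(intersect, sets))
}

#' Phase differences between RPF and RNA rhythms
#'
#' For genes rhythmic in both assays, the phase difference RPF peak minus RNA
#' peak, wrapped into (-12, +12] hours (the boundary maps to +12; negative
#' values mean footprints peak before mRNA).
#'
#' @param fits_rpf,fits_rna \code{"rhythm_calls"} for the two assays of one
#'   organ.
#' @param genes genes to compare; default: rhythmic in both.
#' @return data.frame of class \code{"phase_comparison"}: \code{gene},
#'   \code{phase_rpf}, \code{phase_rna}, \code{delta} (h); attributes
#'   \code{mean_delta}, \code{n_advance} (delta < 0), \code{n_delay}.
#' @export
phase_differences <- function(fits_rpf, fits_rna, genes = NULL) {
  if (is.null(genes))
    genes <- intersect(fits_rpf$gene[fits_rpf$rhythmic],
                       fits_rna$gene[fits_rna$rhythmic])
  i <- match(genes, fits_rpf$gene)
  j <- match(genes, fits_rna$gene)
  missing <- is.na(i) | is.na(j)
  if (any(missing))
    dt_log("phase_differences (genes with fits in both assays)",
           length(genes), sum(!missing))
  genes <- genes[!missing]; i <- i[!missing]; j <- j[!missing]
  delta <- wrap_phase_diff(fits_rpf$phase[i] - fits_rna$phase[j])
  out <- data.frame(gene = genes, phase_rpf = fits_rpf$phase[i],
                    phase_rna = fits_rna$phase[j], delta = delta)
  attr(out, "mean_delta") <- mean(delta)
  attr(out, "n_advance") <- sum(delta < 0)
  attr(out, "n_delay") <- sum(delta > 0)
  class(out) <- c("phase_comparison", "data.frame")
  out
}

# Two-sample Kolmogorov-Smirnov distance (handles ties).
ks_distance <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts)
  Fb <- stats::ecdf(b)(pts)
  max(abs(Fa - Fb))
}

#' Permutation test for a difference between two phase-lag distributions
#'
#' Two-sample test on wrapped phase differences: the statistic is the
#' Kolmogorov-Smirnov distance between the two samples; the null is built by
#' pooling both samples and re-splitting at the original sizes. The p-value
#' uses the add-one estimator \code{(1 + #(perm >= obs)) / (n_perm + 1)}.
#'
#' @param delta_a,delta_b numeric samples (e.g. phase differences of two
#'   organs).
#' @param n_perm number of permutations (>= 100; default 10000).
#' @param seed optional integer seed for reproducibility.
#' @return List: \code{p}, \code{statistic} (observed KS distance),
#'   \code{n_perm}.
#' @export
permutation_test_distributions <- function(delta_a, delta_b, n_perm = 10000,
                                           seed = NULL) {
  if (length(delta_a) == 0 || length(delta_b) == 0)
    dt_stop("both samples must be non-empty")
  if (n_perm < 100) dt_stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  obs <- ks_distance(delta_a, delta_b)
  pool <- c(delta_a, delta_b)
  na <- length(delta_a)
  n <- length(pool)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, na)
    if (ks_distance(pool[idx], pool[-idx]) >= obs) hits <- hits + 1L
  }
  list(p = (1 + hits) / (n_perm + 1), statistic = obs, n_perm = n_perm)
}

#' Watson-Wheeler test for homogeneity of phases
#'
#' Nonparametric circular-statistics test that two or more groups of peak
#' phases share the same angular distribution. Phases (hours) are converted
#' to angles (\code{h * 2 * pi / 24}), jointly ranked on the circle (ties get
#' average ranks), and each observation is mapped to a uniform score; the
#' statistic is \code{W = sum_k 2 * (C_k^2 + S_k^2) / n_k} with \code{C_k,
#' S_k} the within-group sums of the score cosines/sines, compared against a
#' chi-square with \code{2 * (k - 1)} degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors of phases in hours.
#' @param min_n minimal group size for the chi-square approximation
#'   (default 10).
#' @param period hours per cycle (default 24).
#' @return List of class \code{"watson_wheeler"}: \code{W}, \code{df},
#'   \code{p}, \code{n} per group.
#' @export
watson_wheeler <- function(groups, min_n = 10, period = 24) {
  if (!is.list(groups) || length(groups) < 2)
    dt_stop("watson_wheeler needs a list of at least 2 phase groups")
  sizes <- lengths(groups)
  if (any(sizes < min_n))
    dt_stop("group(s) below the minimum size of ", min_n, ": n = ",
            paste(sizes, collapse = ", "))
  phases <- unlist(groups, use.names = FALSE) %% period
  grp <- rep(seq_along(groups), sizes)
  N <- length(phases)
  rk <- rank(phases, ties.method = "average")
  if (anyDuplicated(phases))
    dt_log("watson_wheeler tied phases (average circular ranks)",
           N, length(unique(phases)))
  beta <- 2 * pi * rk / N
  W <- 0
  for (k in seq_along(groups)) {
    Ck <- sum(cos(beta[grp == k]))
    Sk <- sum(sin(beta[grp == k]))
    W <- W + 2 * (Ck^2 + Sk^2) / sizes[k]
  }
  df <- 2 * (length(groups) - 1)
  structure(list(W = W, df = df,
                 p = stats::pchisq(W, df, lower.tail = FALSE),
                 n = sizes),
            class = "watson_wheeler")
}

#' @export
print.watson_wheeler <- function(x, ...) {
  cat(sprintf("Watson-Wheeler test: W = %.3f, df = %d, p = %.3g (n = %s)\n",
              x$W, x$df, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Lagged cross-correlation between RPF and RNA profiles
#'
#' Correlation of the (replicate-averaged) RPF time course against the RNA
#' time course at integer multiples of the sampling step:
#' \code{r(k) = sum_t (x[t+k] - mean(x)) * (y[t] - mean(y)) / (n * s_x *
#' s_y)} with overall means and (population) SDs and truncation at the series
#' ends. With \code{x} the RPF profile, negative lags correspond to RPF
#' leading RNA.
#'
#' @param x_rpf,y_rna equal-length profiles on the common ZT grid
#'   (replicates averaged first).
#' @param step_h sampling step in hours (default 2).
#' @param max_lag_h maximal absolute lag in hours (default 8).
#' @param circular wrap indices around the cycle instead of truncating.
#' @return data.frame of class \code{"lag_correlation"}: \code{lag_h},
#'   \code{r}; attribute \code{best_lag_h} is the argmax lag.
#' @export
cross_correlate <- function(x_rpf, y_rna, step_h = 2, max_lag_h = 8,
                            circular = FALSE) {
  n <- length(x_rpf)
  if (length(y_rna) != n) dt_stop("profiles must have equal length")
  sx <- stats::sd(x_rpf) * sqrt((n - 1) / n)
  sy <- stats::sd(y_rna) * sqrt((n - 1) / n)
  if (sx == 0 || sy == 0) {
    warning("constant profile: cross-correlation undefined", call. = FALSE)
    lags <- seq(-max_lag_h, max_lag_h, by = step_h)
    out <- data.frame(lag_h = lags, r = NA_real_)
    attr(out, "best_lag_h") <- NA_real_
    class(out) <- c("lag_correlation", "data.frame")
    return(out)
  }
  xc <- x_rpf - mean(x_rpf)
  yc <- y_rna - mean(y_rna)
  ks <- seq(-max_lag_h / step_h, max_lag_h / step_h)
  r <- vapply(ks, function(k) {
    if (circular) {
      idx <- ((seq_len(n) - 1 + k) %% n) + 1
      sum(xc[idx] * yc) / (n * sx * sy)
    } else {
      tt <- seq_len(n)
      tt <- tt[tt + k >= 1 & tt + k <= n]
      sum(xc[tt + k] * yc[tt]) / (n * sx * sy)
    }
  }, numeric(1))
  out <- data.frame(lag_h = ks * step_h, r = r)
  attr(out, "best_lag_h") <- out$lag_h[which.max(out$r)]
  class(out) <- c("lag_correlation", "data.frame")
  out
}

#' Screen for genes rhythmic in translation only
#'
#' Flags genes whose footprints cycle while their mRNA does not, with
#' corroborating time-dependent variation of TE: (i) RPF called rhythmic,
#' (ii) RNA not rhythmic and RNA fold below the amplitude cutoff, (iii)
#' Kruskal-Wallis test of TE across the 12 ZT groups significant at
#' Benjamini-Hochberg FDR < alpha.
#'
#' @param fits_rna,fits_rpf \code{"rhythm_calls"} of one organ.
#' @param te_table TE \code{"expression_table"} of the same organ.
#' @param alpha FDR level for the TE-variation condition (default 0.05).
#' @param amplitude_cutoff RNA amplitude gate (default 1.5).
#' @return data.frame: \code{gene}, the three condition flags, \code{kw_p},
#'   \code{kw_q}, \code{selected}; attribute \code{genes} holds the selected
#'   gene ids.
#' @export
translation_only_screen <- function(fits_rna, fits_rpf, te_table, alpha = 0.05,
                                    amplitude_cutoff = 1.5) {
  genes <- Reduce(intersect, list(fits_rna$gene, fits_rpf$gene,
                                  rownames(te_table)))
  s <- attr(te_table, "samples")
  tp <- factor(s$timepoint)
  kw_p <- vapply(genes, function(g) {
    y <- unclass(te_table)[g, ]
    ok <- is.finite(y)
    if (length(unique(tp[ok])) < 2) return(NA_real_)
    stats::kruskal.test(y[ok], tp[ok])$p.value
  }, numeric(1))
  kw_q <- stats::p.adjust(kw_p, method = "BH")
  i <- match(genes, fits_rna$gene)
  j <- match(genes, fits_rpf$gene)
  rpf_rhythmic <- fits_rpf$rhythmic[j]
  rna_flat <- !fits_rna$rhythmic[i] & fits_rna$fold[i] < amplitude_cutoff
  te_varies <- !is.na(kw_q) & kw_q < alpha
  out <- data.frame(gene = genes, rpf_rhythmic = rpf_rhythmic,
                    rna_flat = rna_flat, kw_p = kw_p, kw_q = kw_q,
                    te_varies = te_varies,
                    selected = rpf_rhythmic & rna_flat & te_varies)
  dt_log("translation_only_screen", length(genes), sum(out$selected))
  attr(out, "genes") <- out$gene[out$selected]
  rownames(out) <- NULL
  out
}
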