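#' Reads-per-million normalisation
#'
#' `RPM = count / librarySize * 1e6`.  Library sizes default to the column
#' sums of the matrix; zero library sizes are an error.
#'
#' @param counts non-negative feature x sample count matrix.
#' @param lib_sizes per-sample library sizes; defaults to `colSums(counts)`.
#' @return matrix of RPM values with the same dimnames.
#' @export
rpm <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(length(lib_sizes) == ncol(counts))
  if (any(lib_sizes <= 0)) stop("zero or negative library size")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Expressed-copy filter
#'
#' A feature counts as expressed when strictly more than `min_reads` reads
#' are seen in at least `min_samples` samples — the filter used to separate
#' transcribed new gene copies from silent pseudogenes.
#'
#' @param counts count matrix (features x samples) or a single feature's
#'   count vector.
#' @param min_reads read threshold, exceeded strictly (default 20).
#' @param min_samples minimum number of qualifying samples (default 2).
#' @return logical vector, one element per feature.
#' @export
is_expressed <- function(counts, min_reads = 20, min_samples = 2) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(all(counts >= 0))
  unname(rowSums(counts > min_reads) >= min_samples)
}

#' Tau tissue-specificity index
#'
#' For per-tissue expression values `x` (log scale, non-negative),
#' `tau = sum(1 - x / max(x)) / (n - 1)`.  Tau is 0 for a constant positive
#' profile (ubiquitous expression), 1 for a single-tissue profile (fully
#' specific), lies in \[0, 1\] otherwise, and is invariant to positive
#' rescaling.  An all-zero profile has no defined peak and returns `NA`.
#'
#' @param x numeric vector of per-tissue expression values (>= 0), length
#'   >= 2.
#' @return tau in \[0, 1\], or `NA` for an all-zero profile.
#' @examples
#' tau(rep(5, 19))   # 0
#' tau(c(9, rep(0, 18)))   # 1
#' tau(c(8, 4, 0))   # 0.75
#' @export
tau <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (any(is.na(x))) return(NA_real_)
  stopifnot(all(x >= 0))
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Mean log2(RPM + 1) per tissue
#'
#' Aggregates sample-level log2(RPM + 1) values into per-tissue means — the
#' profile Tau is computed on.
#'
#' @param counts feature x sample count matrix.
#' @param sample_tissues character vector mapping each sample (column) to a
#'   tissue; names, when present, must match the column names.
#' @param lib_sizes optional per-sample library sizes (default column sums).
#' @return feature x tissue matrix of mean log2(RPM + 1) values.
#' @export
tissue_means <- function(counts, sample_tissues, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(sample_tissues)) && !is.null(colnames(counts))) {
    stopifnot(all(colnames(counts) %in% names(sample_tissues)))
    sample_tissues <- sample_tissues[colnames(counts)]
  }
  stopifnot(length(sample_tissues) == ncol(counts))
  lg <- log2(rpm(counts, lib_sizes) + 1)
  tissues <- sort(unique(as.character(sample_tissues)))
  out <- vapply(tissues, function(tt)
    rowMeans(lg[, sample_tissues == tt, drop = FALSE]),
    numeric(nrow(counts)))
  if (nrow(counts) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(rownames(counts),
                                                        tissues))
  out
}

#' Per-feature tissue specificity from a count matrix
#'
#' The full expression workflow: RPM-normalise, log2(RPM + 1), average
#' samples within tissues, compute Tau per feature, call the peak tissue
#' (ties go to the lexicographically first tissue) and label features with
#' `tau > tau_threshold` (strict) as tissue specific.  Also reports the
#' expressed-copy filter (strictly more than `min_reads` reads in at least
#' `min_samples` samples), the number of qualifying samples and the maximum
#' sample-level log2(RPM + 1).
#'
#' @param counts feature x sample count matrix (row names = feature ids).
#' @param sample_tissues sample-to-tissue map (see [tissue_means()]).
#' @param lib_sizes optional per-sample library sizes (default column sums).
#' @param min_reads,min_samples expressed-copy filter settings (defaults 20
#'   and 2).
#' @param tau_threshold specificity cut, exceeded strictly (default 0.8).
#' @return a data.frame of class `tau_result` with columns `id`, `tau`,
#'   `peakTissue`, `isSpecific`, `expressed`, `nSamplesExpressed`,
#'   `maxLog2RPM`; the per-tissue mean matrix is attached as attribute
#'   `tissue_means`.
#' @export
tissue_specificity <- function(counts, sample_tissues, lib_sizes = NULL,
                               min_reads = 20, min_samples = 2,
                               tau_threshold = 0.8) {
  counts <- as.matrix(counts)
  tm <- tissue_means(counts, sample_tissues, lib_sizes)
  if (ncol(tm) < 2L) stop("tau requires at least two tissues")
  taus <- apply(tm, 1L, tau)
  peak <- colnames(tm)[apply(tm, 1L, which.max)]
  peak[is.na(taus)] <- NA_character_
  lg <- log2(rpm(counts, lib_sizes) + 1)
  out <- data.frame(id = if (is.null(rownames(counts)))
                      paste0("feature-", seq_len(nrow(counts)))
                    else rownames(counts),
                    tau = unname(taus),
                    peakTissue = peak,
                    isSpecific = !is.na(taus) & taus > tau_threshold,
                    expressed = is_expressed(counts, min_reads, min_samples),
                    nSamplesExpressed = unname(rowSums(counts > min_reads)),
                    maxLog2RPM = unname(apply(lg, 1L, max)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("tau_result", "data.frame"),
            tissue_means = tm, tau_threshold = tau_threshold)
}

#' Label Tau results as tissue specific
#'
#' @param results a `tau_result` data.frame (or any data.frame with a `tau`
#'   column).
#' @param threshold specificity cut, exceeded strictly (default 0.8).
#' @return `results` with `isSpecific` re-evaluated.
#' @export
classify_tissue_specific <- function(results, threshold = 0.8) {
  results$isSpecific <- !is.na(results$tau) & results$tau > threshold
  attr(results, "tau_threshold") <- threshold
  results
}

#' @export
print.tau_result <- function(x, ...) {
  thr <- attr(x, "tau_threshold")
  cat("<tau_result> ", nrow(x), " feature(s); ", sum(x$isSpecific),
      " tissue-specific (tau > ", thr, ")\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}
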