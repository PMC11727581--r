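#' Build an annotation set from category BED intervals
#'
#' Each named category (one BED file or interval data frame per category) is
#' held as a `GRanges`; a total priority order over the categories resolves
#' overlapping assignments.  Intervals are 0-based half-open on input (BED
#' convention).
#'
#' @param categories named list; each element is either a path to a BED file
#'   or a data.frame whose first three columns are chrom, start, end
#'   (optionally name, score, strand).
#' @param priority character vector ordering the category names from highest
#'   to lowest precedence; defaults to the supplied names in
#'   repeat > CDS > UTR > exon > intron > promoter order where present,
#'   with any further categories appended in input order.
#' @return a list of class `annotation_set`.
#' @export
annotation_set <- function(categories, priority = NULL) {
  stopifnot(is.list(categories), !is.null(names(categories)),
            all(nzchar(names(categories))))
  canonical <- c("repeat", "CDS", "UTR", "exon", "intron", "promoter")
  if (is.null(priority))
    priority <- c(intersect(canonical, names(categories)),
                  setdiff(names(categories), canonical))
  stopifnot(setequal(priority, names(categories)))
  grl <- lapply(categories, function(x) {
    df <- if (is.character(x)) read_bed(x) else x
    stopifnot(ncol(df) >= 3L)
    GenomicRanges::GRanges(
      seqnames = as.character(df[[1]]),
      ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
  })
  structure(list(categories = grl, priority = priority),
            class = "annotation_set")
}

#' Read a BED file (first six columns)
#'
#' @param path path to a BED file (no header; tab- or space-separated).
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(ncol(df), 6L))] <- cols[seq_len(min(ncol(df), 6L))]
  df
}

#' Assign each candidate to a genomic category
#'
#' Among the categories whose intervals overlap the candidate's insertion
#' interval by at least one base, the highest-priority one wins; candidates
#' overlapping nothing (including those on chromosomes absent from the
#' annotation) are labelled `"intergenic"`.
#'
#' @param candidates a `retro_candidates` data frame (or any data frame with
#'   `chrom`, `start`, `end`).
#' @param annotation an [annotation_set()].
#' @return character vector of category labels, one per candidate.
#' @export
assign_category <- function(candidates, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  n <- nrow(candidates)
  out <- rep("intergenic", n)
  if (n == 0L) return(out)
  cand <- GenomicRanges::GRanges(
    seqnames = candidates$chrom,
    ranges = IRanges::IRanges(start = candidates$start + 1L,
                              end = pmax(candidates$end,
                                         candidates$start + 1L)))
  assigned <- rep(FALSE, n)
  for (cat_name in annotation$priority) {
    gr <- annotation$categories[[cat_name]]
    # disjoint sequence universes are expected (a chromosome absent from a
    # category simply cannot contribute an overlap), so the seqlevel-mismatch
    # warning is noise here
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(cand, gr, minoverlap = 1L))
    idx <- unique(S4Vectors::queryHits(hits))
    idx <- idx[!assigned[idx]]
    out[idx] <- cat_name
    assigned[idx] <- TRUE
  }
  out
}

#' Summarise the genomic category distribution of a candidate set
#'
#' @param candidates a `retro_candidates` data frame.
#' @param annotation an [annotation_set()].
#' @return data.frame with `category`, `count`, `fraction` (fractions sum to
#'   1 over non-empty categories); empty input yields zero rows.
#' @export
summarize_distribution <- function(candidates, annotation) {
  if (nrow(candidates) == 0L)
    return(data.frame(category = character(0), count = integer(0),
                      fraction = numeric(0)))
  lab <- assign_category(candidates, annotation)
  tab <- table(lab)
  df <- data.frame(category = names(tab), count = as.integer(tab),
                   fraction = as.numeric(tab) / sum(tab),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$category), , drop = FALSE]
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Scan candidate 5' insertion edges for the L1 endonuclease motif
#'
#' Scans `window` nucleotides on each side of every candidate's 5' insertion
#' edge, on the candidate's strand, for exact and near (Hamming distance at
#' most `max_mismatch`) occurrences of the motif (default the L1
#' endonuclease cleavage consensus TTAAAA).  The reported offset is the
#' signed distance from the motif's 3' end to the insertion edge, negative
#' when the motif lies upstream; among multiple occurrences the one closest
#' to the edge wins, ties going upstream.
#'
#' @param candidates a `retro_candidates` data frame.
#' @param genome named character vector of chromosome sequences.
#' @param motif motif sequence (default `"TTAAAA"`).
#' @param window bases scanned on each side of the edge (default 20).
#' @param max_mismatch Hamming tolerance for a "similar" occurrence
#'   (default 1).
#' @return a list of class `motif_report`: `candidates` (data.frame `id`,
#'   `hasExactMotif`, `hasSimilarMotif`, `bestOffset`), `fraction_exact`,
#'   `fraction_similar`, `offset_table` (histogram of best offsets), plus
#'   the scan settings.
#' @export
scan_motif <- function(candidates, genome, motif = "TTAAAA", window = 20L,
                       max_mismatch = 1L) {
  window <- as.integer(window)
  k <- nchar(motif)
  n <- nrow(candidates)
  has_exact <- logical(n)
  has_similar <- logical(n)
  best_offset <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    chrom <- candidates$chrom[i]
    plus <- candidates$strand[i] != "-"
    edge <- if (plus) candidates$start[i] else candidates$end[i]
    lo <- max(0L, edge - window)
    hi <- min(nbytes(genome[[chrom]]), edge + window)
    s <- seq_slice(genome, chrom, lo, hi)
    edge_idx <- if (plus) edge - lo else hi - edge
    if (!plus) s <- revcomp(s)
    np <- nchar(s) - k
    if (np < 0L) next
    for (p in 0:np) {
      mm <- hamming(substr(s, p + 1L, p + k), motif)
      if (mm > max_mismatch) next
      off <- (p + k) - edge_idx
      if (abs(off) > window) next
      if (mm == 0L) has_exact[i] <- TRUE
      has_similar[i] <- TRUE
      if (is.na(best_offset[i]) ||
          abs(off) < abs(best_offset[i]) ||
          (abs(off) == abs(best_offset[i]) && off < best_offset[i]))
        best_offset[i] <- off
    }
  }
  structure(list(candidates = data.frame(id = candidates$id,
                                         hasExactMotif = has_exact,
                                         hasSimilarMotif = has_similar,
                                         bestOffset = best_offset,
                                         stringsAsFactors = FALSE),
                 fraction_exact = if (n) mean(has_exact) else NA_real_,
                 fraction_similar = if (n) mean(has_similar) else NA_real_,
                 offset_table = table(best_offset[has_similar]),
                 motif = motif, window = window,
                 max_mismatch = as.integer(max_mismatch)),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> motif ", x$motif, ", window +/-", x$window, " nt\n",
      sep = "")
  cat(sprintf("  exact: %.1f%%   similar (<=%d mismatch): %.1f%%\n",
              100 * x$fraction_exact, x$max_mismatch,
              100 * x$fraction_similar))
  invisible(x)
}
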