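#' Detection parameters
#'
#' Tuning knobs of the retrotransposon caller.  Defaults implement the
#' stringent published filter (TSD length >= 7, poly(A) length >= 5) with a
#' flank extension that comfortably exceeds the longest TSDs seen in real
#' calls (18 nt).
#'
#' @param min_tsd_len minimum aligned TSD length retained (default 7).
#' @param min_polya_len minimum poly(A) run length retained (default 5).
#' @param extend_out bases of outward flank extension beyond each fill edge
#'   (default 30; must be >= `min_tsd_len`).
#' @param extend_in bases of inward extension into the fill (default 30).
#' @param max_tsd_mismatches maximum edits tolerated inside the TSD alignment
#'   (default 1; the alignment is ungapped, so edits are substitutions).
#' @param max_polya_interruptions maximum non-A positions tolerated inside a
#'   poly(A) run (default 1; terminal positions must be A).
#' @param polya_max_gap maximum distance in bases between the poly(A) run's
#'   3' end and the 3'-TSD's inner edge (default 5).
#' @param min_score minimum total score retained (default 12 =
#'   `min_tsd_len + min_polya_len` under unit scoring).
#' @param mode `"self"` for a same-species net, `"cross"` for a cross-species
#'   net; detection logic is identical, the label is carried through for
#'   provenance.
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(min_tsd_len = 7L, min_polya_len = 5L,
                          extend_out = 30L, extend_in = 30L,
                          max_tsd_mismatches = 1L,
                          max_polya_interruptions = 1L,
                          polya_max_gap = 5L, min_score = 12,
                          mode = c("self", "cross")) {
  mode <- match.arg(mode)
  p <- list(min_tsd_len = as.integer(min_tsd_len),
            min_polya_len = as.integer(min_polya_len),
            extend_out = as.integer(extend_out),
            extend_in = as.integer(extend_in),
            max_tsd_mismatches = as.integer(max_tsd_mismatches),
            max_polya_interruptions = as.integer(max_polya_interruptions),
            polya_max_gap = as.integer(polya_max_gap),
            min_score = as.numeric(min_score),
            mode = mode)
  stopifnot(p$min_tsd_len >= 1L, p$min_polya_len >= 1L,
            p$extend_out >= p$min_tsd_len, p$extend_in >= 0L,
            p$max_tsd_mismatches >= 0L, p$max_polya_interruptions >= 0L,
            p$polya_max_gap >= 0L)
  structure(p, class = "detect_params")
}

#' Extract extended flanks around a fill region
#'
#' The left flank spans `[start - extend_out, start + extend_in)` and the
#' right flank `[end - extend_in, end + extend_out)`, both clamped at the
#' chromosome edges.  The returned offsets map flank-local positions back to
#' reference coordinates (reference position = offset + flank position).
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end fill reference interval, 0-based half-open.
#' @param params a [detect_params()] object.
#' @return list with `left`, `right` (strings), `left_offset`, `right_offset`
#'   (integer reference coordinates of each flank's first base).
#' @export
extend_flanks <- function(genome, chrom, start, end, params = detect_params()) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nbytes(genome[[chrom]])
  ls <- max(0L, as.integer(start) - params$extend_out)
  le <- min(L, as.integer(start) + params$extend_in)
  rs <- max(0L, as.integer(end) - params$extend_in)
  re <- min(L, as.integer(end) + params$extend_out)
  list(left = seq_slice(genome, chrom, ls, le),
       right = seq_slice(genome, chrom, rs, re),
       left_offset = as.integer(ls), right_offset = as.integer(rs))
}

#' Find the best target-site duplication between two flanks
#'
#' Scans all ungapped local alignments between a left-flank substring and a
#' right-flank substring (unit match reward, unit mismatch penalty) subject
#' to: aligned length >= `min_tsd_len`, at most `max_tsd_mismatches` edits,
#' and — when fill-edge positions are supplied — positional anchoring: the
#' left copy must end within `extend_in` bases of the fill's 5' edge and the
#' right copy must begin within `extend_in` bases of the fill's 3' edge.
#' Ties are broken by longer length, then fewer mismatches, then smaller
#' distance of the left copy's end to the fill edge, then leftmost start
#' positions.
#'
#' @param left_flank,right_flank flank sequences (see [extend_flanks()]).
#' @param params a [detect_params()] object.
#' @param left_edge,right_edge optional 0-based positions of the fill's 5'
#'   edge within `left_flank` and of its 3' edge within `right_flank`; `NULL`
#'   disables anchoring.
#' @param max_end_start_diff optional bound on (left copy end − right copy
#'   start) in flank coordinates, used to keep the two copies from
#'   overlapping on the reference when the flanks themselves overlap.
#' @return `NULL` if no qualifying pair exists, otherwise a list with
#'   `left_start`, `left_end`, `right_start`, `right_end` (flank-local,
#'   0-based half-open), `length`, `matches`, `mismatches`, `indels` (always
#'   0), `score`, `seq_left`, `seq_right`.
#' @export
find_tsd <- function(left_flank, right_flank, params = detect_params(),
                     left_edge = NULL, right_edge = NULL,
                     max_end_start_diff = NULL) {
  n <- nchar(left_flank)
  m <- nchar(right_flank)
  if (n < params$min_tsd_len || m < params$min_tsd_len) return(NULL)
  if (is.null(left_edge)) {
    e_lo <- params$min_tsd_len; e_hi <- n
  } else {
    e_lo <- max(params$min_tsd_len, left_edge - params$extend_in)
    e_hi <- min(n, left_edge + params$extend_in)
  }
  if (is.null(right_edge)) {
    s_lo <- 0L; s_hi <- m - params$min_tsd_len
  } else {
    s_lo <- max(0L, right_edge - params$extend_in)
    s_hi <- min(m - params$min_tsd_len, right_edge + params$extend_in)
  }
  if (is.null(max_end_start_diff)) max_end_start_diff <- n + m
  hit <- tsd_scan_cpp(left_flank, right_flank,
                      params$min_tsd_len, params$max_tsd_mismatches,
                      as.integer(e_lo), as.integer(e_hi),
                      as.integer(s_lo), as.integer(s_hi),
                      if (is.null(left_edge)) -1L else as.integer(left_edge),
                      as.integer(max_end_start_diff))
  if (length(hit) == 0L) return(NULL)
  list(left_start = hit[1], left_end = hit[2],
       right_start = hit[3], right_end = hit[4],
       length = hit[5], matches = hit[6], mismatches = hit[7],
       indels = 0L, score = hit[8],
       seq_left = substr(left_flank, hit[1] + 1L, hit[2]),
       seq_right = substr(right_flank, hit[3] + 1L, hit[4]))
}

#' Find the poly(A) run abutting the 3'-TSD
#'
#' `inner_seq` is the sequence immediately element-side of the 3'-TSD's inner
#' edge, oriented 5' to 3' so that its last base abuts the TSD.  The best run
#' must end within `polya_max_gap` bases of that edge, start and end on an A,
#' contain at most `max_polya_interruptions` internal non-A bases, and span
#' at least `min_polya_len` bases.  Among qualifying runs the longest wins;
#' ties go to fewer interruptions, then to the end closest to the TSD.  Score
#' is `a_count - interruptions`.
#'
#' @param inner_seq element-side sequence adjacent to the 3'-TSD.
#' @param params a [detect_params()] object.
#' @return `NULL` if no qualifying run exists, otherwise a list with `start`,
#'   `end` (0-based half-open within `inner_seq`), `length`, `a_count`,
#'   `interruptions`, `score`, `seq`.
#' @export
find_polya <- function(inner_seq, params = detect_params()) {
  n <- nchar(inner_seq)
  if (n < params$min_polya_len) return(NULL)
  x <- strsplit(inner_seq, "", fixed = TRUE)[[1]]
  is_a <- x == "A"
  best <- NULL
  e_min <- max(params$min_polya_len, n - params$polya_max_gap)
  for (e in n:e_min) {                      # e = 1-based inclusive end
    if (!is_a[e]) next
    ints <- 0L
    j <- e - 1L
    while (j >= 1L) {
      len <- e - j + 1L
      if (is_a[j] && len >= params$min_polya_len) {
        cand <- list(start = j - 1L, end = e, length = len,
                     a_count = len - ints, interruptions = ints,
                     score = (len - ints) - ints)
        if (is.null(best) ||
            cand$length > best$length ||
            (cand$length == best$length && cand$interruptions < best$interruptions) ||
            (cand$length == best$length && cand$interruptions == best$interruptions &&
             cand$end > best$end))
          best <- cand
      }
      # extending one more base makes x[j] internal
      if (!is_a[j]) {
        ints <- ints + 1L
        if (ints > params$max_polya_interruptions) break
      }
      j <- j - 1L
    }
  }
  if (is.null(best)) return(NULL)
  best$seq <- substr(inner_seq, best$start + 1L, best$end)
  best
}

#' Score a candidate from its TSD and poly(A) hits
#'
#' Unit-per-base additive scoring: the TSD contributes
#' `matches - mismatches - indels`, the poly(A) run `a_count -
#' interruptions`, and the total is their sum.  Deterministic and monotone:
#' more matching TSD bases or more As never decrease the total.
#'
#' @param tsd a hit from [find_tsd()].
#' @param polya a hit from [find_polya()].
#' @return list with `tsd_score`, `polya_score`, `total_score`.
#' @export
score_candidate <- function(tsd, polya) {
  stopifnot(!is.null(tsd), !is.null(polya))
  ts <- tsd$matches - tsd$mismatches - tsd$indels
  ps <- polya$a_count - polya$interruptions
  list(tsd_score = ts, polya_score = ps, total_score = ts + ps)
}

# Try one orientation of one gap-enclosed fill.  Returns NULL or a one-row
# candidate description with reference-coordinate intervals.
call_orientation <- function(genome, chrom, fs, fe, params, orient) {
  fl <- extend_flanks(genome, chrom, fs, fe, params)
  lf <- fl$left; rf <- fl$right
  lf_s <- fl$left_offset; rf_s <- fl$right_offset
  lf_e <- lf_s + nchar(lf); rf_e <- rf_s + nchar(rf)
  if (orient == "+") {
    tsd <- find_tsd(lf, rf, params,
                    left_edge = fs - lf_s, right_edge = fe - rf_s,
                    max_end_start_diff = rf_s - lf_s)
    if (is.null(tsd)) return(NULL)
    ltsd <- c(lf_s + tsd$left_start, lf_s + tsd$left_end)
    rtsd <- c(rf_s + tsd$right_start, rf_s + tsd$right_end)
    inner_s <- max(0L, rtsd[1] - params$extend_in)
    inner <- seq_slice(genome, chrom, inner_s, rtsd[1])
    pa <- find_polya(inner, params)
    if (is.null(pa)) return(NULL)
    polya_iv <- c(inner_s + pa$start, inner_s + pa$end)
  } else {
    # mirror the problem through reverse complement: the oriented left flank
    # is the reverse complement of the genomic right flank and vice versa
    lf2 <- revcomp(rf); rf2 <- revcomp(lf)
    tsd <- find_tsd(lf2, rf2, params,
                    left_edge = nchar(rf) - (fe - rf_s),
                    right_edge = nchar(lf) - (fs - lf_s),
                    max_end_start_diff = rf_e - lf_e)
    if (is.null(tsd)) return(NULL)
    # oriented left copy lives on the genomic right flank, oriented right
    # copy on the genomic left flank
    rtsd <- c(rf_s + nchar(rf) - tsd$left_end, rf_s + nchar(rf) - tsd$left_start)
    ltsd <- c(lf_s + nchar(lf) - tsd$right_end, lf_s + nchar(lf) - tsd$right_start)
    inner_ref_s <- ltsd[2]
    inner_ref_e <- min(nbytes(genome[[chrom]]), ltsd[2] + params$extend_in)
    inner <- revcomp(seq_slice(genome, chrom, inner_ref_s, inner_ref_e))
    pa <- find_polya(inner, params)
    if (is.null(pa)) return(NULL)
    nS <- nchar(inner)
    polya_iv <- c(inner_ref_s + nS - pa$end, inner_ref_s + nS - pa$start)
  }
  sc <- score_candidate(tsd, pa)
  list(strand = orient,
       start = ltsd[2], end = rtsd[1],
       ltsd = ltsd, rtsd = rtsd, polya_iv = polya_iv,
       tsd = tsd, polya = pa,
       tsd_score = sc$tsd_score, polya_score = sc$polya_score,
       total_score = sc$total_score)
}

#' Call retrotransposon candidates from a net and a genome
#'
#' For every gap-enclosed fill of the net (at any synteny level), extends the
#' fill's flanks, searches for the TSD pair and the adjacent poly(A) run on
#' the + orientation, repeats on the reverse complement (mapping coordinates
#' back), and keeps the orientation with the higher total score (ties go to
#' +).  A candidate is emitted only when both a TSD and a poly(A) hit exist
#' in some orientation; `passedFilters` records whether it clears the length
#' and score floors.  Candidates are sorted by (chrom, start) and ids
#' assigned in that order as `<prefix>-retrotransposon-N`.
#'
#' @param net a [net_file()] object.
#' @param genome named character vector of chromosome sequences covering
#'   every reference chromosome named in `net`.
#' @param params a [detect_params()] object.
#' @param prefix id prefix, typically a species tag (default `"ref"`).
#' @return a `data.frame` of class `retro_candidates` with columns `id`,
#'   `chrom`, `start`, `end`, `strand`, `tsdLen`, `tsdSeqLeft`, `tsdSeqRight`,
#'   `tsdMismatches`, `polyALen`, `polyAInterruptions`, `sourceChrom`,
#'   `sourceStrand`, `sourceStart`, `sourceSize`, `tsdScore`, `polyAScore`,
#'   `totalScore`, `passedFilters`.  The insertion interval `[start, end)`
#'   runs from the inner edge of the 5' TSD copy to the inner edge of the 3'
#'   copy, 0-based half-open.
#' @export
detect_candidates <- function(net, genome, params = detect_params(),
                              prefix = "ref") {
  stopifnot(inherits(net, "net_file"))
  for (nt in net$nets)
    if (!nt$chrom %in% names(genome))
      stop("genome is missing reference chromosome: ", nt$chrom)
  pairs <- iter_gap_fill_pairs(net)
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    fs <- p$fill$ref_start
    fe <- fs + p$fill$ref_size
    plus <- call_orientation(genome, p$chrom, fs, fe, params, "+")
    minus <- call_orientation(genome, p$chrom, fs, fe, params, "-")
    best <- if (is.null(plus)) minus
            else if (is.null(minus)) plus
            else if (minus$total_score > plus$total_score) minus else plus
    if (is.null(best)) next
    rows[[i]] <- data.frame(
      chrom = p$chrom, start = best$start, end = best$end,
      strand = best$strand,
      tsdLen = best$tsd$length,
      tsdSeqLeft = seq_slice(genome, p$chrom, best$ltsd[1], best$ltsd[2]),
      tsdSeqRight = seq_slice(genome, p$chrom, best$rtsd[1], best$rtsd[2]),
      tsdMismatches = best$tsd$mismatches,
      polyALen = best$polya$length,
      polyAInterruptions = best$polya$interruptions,
      sourceChrom = p$fill$q_chrom, sourceStrand = p$fill$q_strand,
      sourceStart = p$fill$q_start, sourceSize = p$fill$q_size,
      tsdScore = best$tsd_score, polyAScore = best$polya_score,
      totalScore = best$total_score,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    df <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     strand = character(0), tsdLen = integer(0),
                     tsdSeqLeft = character(0), tsdSeqRight = character(0),
                     tsdMismatches = integer(0), polyALen = integer(0),
                     polyAInterruptions = integer(0), sourceChrom = character(0),
                     sourceStrand = character(0), sourceStart = integer(0),
                     sourceSize = integer(0), tsdScore = numeric(0),
                     polyAScore = numeric(0), totalScore = numeric(0),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  }
  df <- cbind(id = if (nrow(df)) paste0(prefix, "-retrotransposon-",
                                        seq_len(nrow(df))) else character(0),
              df, stringsAsFactors = FALSE)
  df$passedFilters <- df$tsdLen >= params$min_tsd_len &
    df$polyALen >= params$min_polya_len &
    df$totalScore >= params$min_score
  rownames(df) <- NULL
  structure(df, class = c("retro_candidates", "data.frame"),
            params = params)
}

#' Retain candidates that pass the stringent filters
#'
#' Keeps exactly the candidates whose `passedFilters` flag is `TRUE`; when
#' `params` is supplied the flag is first re-evaluated against those
#' thresholds (TSD length, poly(A) length, total score).
#'
#' @param candidates a `retro_candidates` data frame.
#' @param params optional [detect_params()] to re-evaluate the filters.
#' @return the retained subset, same class.
#' @export
filter_candidates <- function(candidates, params = NULL) {
  if (!is.null(params)) {
    candidates$passedFilters <- candidates$tsdLen >= params$min_tsd_len &
      candidates$polyALen >= params$min_polya_len &
      candidates$totalScore >= params$min_score
  }
  out <- candidates[candidates$passedFilters, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.retro_candidates <- function(x, ...) {
  cat("<retro_candidates> ", nrow(x), " candidate(s), ",
      sum(x$passedFilters), " passing filters\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
summary.retro_candidates <- function(object, ...) {
  pass <- object[object$passedFilters, , drop = FALSE]
  out <- list(n = nrow(object), n_pass = nrow(pass),
              tsd_len = if (nrow(pass)) summary(pass$tsdLen) else NULL,
              polya_len = if (nrow(pass)) summary(pass$polyALen) else NULL,
              total_score = if (nrow(pass)) summary(pass$totalScore) else NULL)
  class(out) <- "summary.retro_candidates"
  out
}

#' @export
print.summary.retro_candidates <- function(x, ...) {
  cat("Candidates:", x$n, " passing filters:", x$n_pass, "\n")
  if (!is.null(x$tsd_len)) {
    cat("TSD length (passing):\n"); print(x$tsd_len)
    cat("poly(A) length (passing):\n"); print(x$polya_len)
    cat("total score (passing):\n"); print(x$total_score)
  }
  invisible(x)
}

#' Write candidate calls to disk
#'
#' Produces `<prefix>.bed` (BED6: insertion interval, id, rounded total
#' score, strand) and `<prefix>.candidates.tsv` (the full table).
#'
#' @param candidates a `retro_candidates` data frame.
#' @param prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
write_candidates <- function(candidates, prefix) {
  bed <- data.frame(chrom = candidates$chrom, start = candidates$start,
                    end = candidates$end, name = candidates$id,
                    score = round(candidates$totalScore),
                    strand = candidates$strand)
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".candidates.tsv")
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(candidates), tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(bed = bed_path, table = tsv_path))
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path path to a `*.candidates.tsv` file.
#' @return a `retro_candidates` data frame.
#' @export
read_candidates <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(tsdSeqLeft = "character",
                                  tsdSeqRight = "character"))
  structure(df, class = c("retro_candidates", "data.frame"))
}
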