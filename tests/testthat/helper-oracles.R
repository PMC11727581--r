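# Independent reference implementations and fixture builders used across the
# test files.  These stay deliberately naive: exhaustive enumeration and
# direct formulas, never calling into the code paths they check.

# ---- brute-force TSD oracle -------------------------------------------------

# lexicographic "is h1 better than h2" under the documented tie-break order
tsd_better <- function(h1, h2) {
  k1 <- c(-h1$score, -h1$length, h1$mismatches, h1$dist, h1$left_start, h1$right_start)
  k2 <- c(-h2$score, -h2$length, h2$mismatches, h2$dist, h2$left_start, h2$right_start)
  d <- k1 - k2
  i <- which(d != 0)[1]
  !is.na(i) && d[i] < 0
}

# exhaustive enumeration of every (left substring, right substring) pair of
# equal length under the ungapped <= max-mismatch constraint
oracle_find_tsd <- function(left, right, params = detect_params(),
                            left_edge = NULL, right_edge = NULL,
                            max_end_start_diff = NULL) {
  L <- strsplit(left, "")[[1]]
  R <- strsplit(right, "")[[1]]
  n <- length(L); m <- length(R)
  min_len <- params$min_tsd_len
  max_mis <- params$max_tsd_mismatches
  if (n < min_len || m < min_len) return(NULL)
  e_lo <- if (is.null(left_edge)) min_len else
    max(min_len, left_edge - params$extend_in)
  e_hi <- if (is.null(left_edge)) n else min(n, left_edge + params$extend_in)
  s_lo <- if (is.null(right_edge)) 0L else
    max(0L, right_edge - params$extend_in)
  s_hi <- if (is.null(right_edge)) m - min_len else
    min(m - min_len, right_edge + params$extend_in)
  D <- if (is.null(max_end_start_diff)) n + m else max_end_start_diff
  best <- NULL
  for (a in 0:(n - min_len)) {
    for (b in 0:(m - min_len)) {
      if (b < s_lo || b > s_hi) next
      kmax <- min(n - a, m - b)
      mmv <- cumsum(L[a + seq_len(kmax)] != R[b + seq_len(kmax)])
      lens <- seq_len(kmax)
      e <- a + lens
      ok <- lens >= min_len & mmv <= max_mis & e >= e_lo & e <= e_hi &
        (e - b) <= D
      if (!any(ok)) next
      lens_ok <- lens[ok]; mm_ok <- mmv[ok]; e_ok <- e[ok]
      score <- lens_ok - 2 * mm_ok
      dist <- if (is.null(left_edge)) rep(0L, length(e_ok)) else
        abs(e_ok - left_edge)
      pick <- order(-score, -lens_ok, mm_ok, dist)[1]
      cand <- list(left_start = a, left_end = a + lens_ok[pick],
                   right_start = b, right_end = b + lens_ok[pick],
                   length = lens_ok[pick],
                   matches = lens_ok[pick] - mm_ok[pick],
                   mismatches = mm_ok[pick],
                   score = score[pick], dist = dist[pick])
      if (is.null(best) || tsd_better(cand, best)) best <- cand
    }
  }
  best
}

# ---- AUC rank-statistic oracle ---------------------------------------------

oracle_auc_rank <- function(scores_true, scores_ctrl) {
  mean(outer(scores_true, scores_ctrl, ">") +
         0.5 * outer(scores_true, scores_ctrl, "=="))
}

# ---- random sequences and genomes ------------------------------------------

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# cap A/T homopolymer runs at 3 so a planted poly(A)/poly(T) tail cannot tie
# a spurious alignment against a chance run in the random context
break_runs <- function(s) {
  x <- strsplit(s, "")[[1]]
  r <- rle(x)
  pos <- cumsum(c(1L, r$lengths))
  for (i in which(r$lengths > 3L & r$values %in% c("A", "T"))) {
    idx <- seq(pos[i] + 3L, pos[i] + r$lengths[i] - 1L, by = 4L)
    x[idx] <- if (r$values[i] == "A") "C" else "G"
  }
  paste(x, collapse = "")
}

# Hand-built single-insertion fixture with guard bases that rule out any
# score-improving or score-neutral extension of the planted TSD pair, so the
# expected call is exactly the planted layout.
plant_one <- function(tsd = "GATTACAG", polya_len = 9L, elem_len = 300L,
                      backbone_len = 3000L, at = 1500L, strand = "+") {
  elem <- break_runs(rand_seq(elem_len))
  substr(elem, 1L, 2L) <- "TT"
  substr(elem, elem_len - 1L, elem_len) <- "GG"
  backbone <- break_runs(rand_seq(backbone_len))
  substr(backbone, at - 1L, at) <- "CC"          # outer guard, left of block
  substr(backbone, at + 1L, at + 2L) <- "GG"     # outer guard, right of block
  body <- paste0(elem, strrep("A", polya_len))
  if (strand == "-") body <- revcomp(body)
  block <- paste0(tsd, body, tsd)
  post <- paste0(substr(backbone, 1L, at), block,
                 substr(backbone, at + 1L, backbone_len))
  tl <- nchar(tsd)
  if (strand == "+") {
    fill_s <- at + tl
    fill_e <- at + tl + elem_len
  } else {
    fill_s <- at + tl + polya_len
    fill_e <- at + tl + polya_len + elem_len
  }
  net <- net_file(list(list(
    chrom = "chrT", size = nchar(post),
    fills = list(net_node("fill", 0L, nchar(post), "chrQ", "+", 0L,
                          backbone_len, attrs = c("id", "1"),
                          children = list(
      net_node("gap", at, nchar(block), "chrQ", "+", at, 0L,
               children = list(
        net_node("fill", fill_s, fill_e - fill_s, "chrQ", strand,
                 5000L, elem_len, attrs = c("id", "2"))))))))))
  list(genome = c(chrT = post), net = net, at = at, tsd = tsd,
       polya_len = polya_len, elem_len = elem_len, block_len = nchar(block),
       strand = strand)
}

# ---- random net trees for round-trip properties ----------------------------

random_attrs <- function() {
  if (runif(1) < 0.3) return(character(0))
  ks <- sample(c("id", "score", "ali", "type", "qDup"), sample(1:3, 1))
  as.character(rbind(ks, sample.int(9999L, length(ks))))
}

random_net_tree <- function(seed) {
  set.seed(seed)
  mk_fill <- function(lo, hi, depth) {
    w <- hi - lo
    s <- lo + sample.int(max(w %/% 4L, 1L), 1L) - 1L
    sz <- sample.int(max(hi - s, 1L), 1L)
    kids <- list()
    if (depth < 3L && sz > 40L && runif(1) < 0.8) {
      gs <- s + sample.int(sz %/% 3L, 1L)
      gsz <- sample.int(max((s + sz - gs) %/% 2L, 1L), 1L)
      gkids <- list()
      if (gsz > 10L && runif(1) < 0.8)
        gkids <- list(mk_fill(gs + 1L, gs + gsz - 1L, depth + 1L))
      kids <- list(net_node("gap", gs, gsz, "chrQ1", "+",
                            sample.int(1e6L, 1L), 0L, children = gkids))
    }
    net_node("fill", s, sz, paste0("chrQ", sample.int(3L, 1L)),
             sample(c("+", "-"), 1L), sample.int(1e6L, 1L),
             sample.int(5000L, 1L), attrs = random_attrs(), children = kids)
  }
  n_chrom <- sample(1:2, 1L)
  net_file(lapply(seq_len(n_chrom), function(i)
    list(chrom = paste0("chrT", i), size = 10000L,
         fills = list(mk_fill(0L, 9000L, 1L)))))
}

# brute-force full-tree walk collecting gap/fill child pairs (reference
# implementation for iter_gap_fill_pairs)
walk_gap_fill <- function(net) {
  out <- list()
  rec <- function(node, chrom) {
    for (ch in node$children) {
      if (node$kind == "gap" && ch$kind == "fill")
        out[[length(out) + 1L]] <<- c(chrom = chrom,
                                      gap_start = node$ref_start,
                                      fill_start = ch$ref_start)
      rec(ch, chrom)
    }
  }
  for (nt in net$nets) for (f in nt$fills) rec(f, nt$chrom)
  out
}

# ---- strand-symmetry helpers ------------------------------------------------

flip_node <- function(node, L) {
  s <- node$ref_start
  e <- node$ref_start + node$ref_size
  node$ref_start <- L - e
  node$children <- rev(lapply(node$children, flip_node, L = L))
  node
}

# mirror a single-chromosome net through the reverse complement of its
# reference chromosome
flip_net <- function(net) {
  L <- net$nets[[1]]$size
  net_file(list(list(chrom = net$nets[[1]]$chrom, size = L,
                     fills = rev(lapply(net$nets[[1]]$fills, flip_node,
                                        L = L)))))
}
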