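#' Default inserted element sequence
#'
#' Returns the bundled synthetic ~1 kb element used as the retrotransposed
#' body in simulations.  It is a fixed random-composition sequence standing
#' in for a LINE1-class element — long enough to produce realistic fill
#' regions, with no terminal A runs that could blur the planted poly(A)
#' tail.  Any user-supplied sequence can be used instead via
#' [sim_config()]`$element`.
#'
#' @return a single character string.
#' @export
default_element <- function() {
  path <- system.file("extdata", "synthetic_element.fa", package = "retronet")
  unname(read_genome(path)[1])
}

#' Simulation configuration
#'
#' Conditions of the insertion benchmark: a random genome receives
#' TPRT-style insertions (random-base TSD duplicated on both sides of the
#' strand-oriented element plus poly(A) tail) and bare-element negative
#' controls, then a net file emulating the pre- vs post-insertion pairwise
#' alignment is produced.  Published protocol scale is a 60 Mb genome with
#' 1000 true and 1000 control insertions; the desk-scale default is 5 Mb
#' with 200 + 200, which preserves the per-insertion statistics.
#'
#' @param genome_length genome size in bases (default 5e6).
#' @param base_probs named probabilities over A/C/G/T (default uniform).
#' @param n_true number of TPRT insertions (default 200).
#' @param n_control number of bare-element control insertions (default 200).
#' @param tsd_len_range inclusive TSD length range, default `c(7, 20)`.
#' @param polya_len_range inclusive poly(A) length range, default `c(5, 20)`.
#' @param element inserted element sequence; `NULL` loads the bundled
#'   synthetic ~1 kb element.
#' @param strand_random insert on a random strand (default `TRUE`).
#' @param boundary_jitter maximum +/- perturbation, in bases, applied
#'   independently to each emulated fill edge (default 3), standing in for
#'   alignment-boundary fuzz.
#' @param motif_mode `"off"` or `"tprt"`: in `"tprt"` mode a TTAAAA hexamer
#'   is written into the pre-insertion genome so that its 3' end lies
#'   `motif_offset` bases upstream of the insertion point (strand-aware).
#' @param motif_offset bases between motif 3' end and insertion point in
#'   `"tprt"` mode (default 10).
#' @param min_spacing minimum distance between insertion points (default
#'   1000), avoiding compound events.
#' @param seed integer seed consumed by [simulate_retro()] /
#'   [random_genome()]; `NULL` uses the current RNG state.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       n_true = 200L, n_control = 200L,
                       tsd_len_range = c(7L, 20L),
                       polya_len_range = c(5L, 20L),
                       element = NULL, strand_random = TRUE,
                       boundary_jitter = 3L,
                       motif_mode = c("off", "tprt"), motif_offset = 10L,
                       min_spacing = 1000L, seed = NULL) {
  motif_mode <- match.arg(motif_mode)
  if (is.null(element)) element <- default_element()
  stopifnot(genome_length > 0, n_true >= 0, n_control >= 0,
            length(base_probs) == 4L,
            all(sort(names(base_probs)) == c("A", "C", "G", "T")),
            abs(sum(base_probs) - 1) < 1e-8,
            tsd_len_range[1] >= 1L, tsd_len_range[2] >= tsd_len_range[1],
            polya_len_range[1] >= 1L,
            polya_len_range[2] >= polya_len_range[1],
            nchar(element) > 0L, boundary_jitter >= 0L, motif_offset >= 0L,
            min_spacing >= 0L)
  structure(list(genome_length = as.integer(genome_length),
                 base_probs = base_probs[c("A", "C", "G", "T")],
                 n_true = as.integer(n_true),
                 n_control = as.integer(n_control),
                 tsd_len_range = as.integer(tsd_len_range),
                 polya_len_range = as.integer(polya_len_range),
                 element = element,
                 strand_random = isTRUE(strand_random),
                 boundary_jitter = as.integer(boundary_jitter),
                 motif_mode = motif_mode,
                 motif_offset = as.integer(motif_offset),
                 min_spacing = as.integer(min_spacing),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Generate a random genome
#'
#' One chromosome (`chrSim`) of i.i.d. bases drawn under
#' `config$base_probs`.  Reproducible: a given `config$seed` always yields
#' the same sequence.
#'
#' @param config a [sim_config()] object.
#' @return named character vector of length 1.
#' @export
random_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bases <- sample(c("A", "C", "G", "T"), config$genome_length,
                  replace = TRUE, prob = config$base_probs)
  c(chrSim = paste(bases, collapse = ""))
}

random_bases <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# insert blocks at 0-based cut positions (distinct, any order)
splice_blocks <- function(seqstr, positions, blocks) {
  if (length(positions) == 0L) return(seqstr)
  o <- order(positions)
  positions <- positions[o]; blocks <- blocks[o]
  k <- length(positions)
  pieces <- substring(seqstr, c(1L, positions + 1L),
                      c(positions, nbytes(seqstr)))
  out <- character(2L * k + 1L)
  out[seq(1L, 2L * k + 1L, by = 2L)] <- pieces
  out[seq(2L, 2L * k, by = 2L)] <- blocks
  paste(out, collapse = "")
}

jitter_draw <- function(k, j) {
  if (j == 0L) rep(0L, k) else sample(seq.int(-j, j), k, replace = TRUE)
}

#' Plant TPRT insertions and controls into a genome
#'
#' True insertions are built as `TSD + oriented(element + A^polyALen) + TSD`:
#' the random-base TSD is duplicated on both sides of the element, and on the
#' minus strand the element-plus-tail is reverse complemented before flanking
#' (so the tail appears as a poly(T) run 5'-ward on the reference).  Controls
#' are the bare (strand-oriented) element with neither TSD nor tail.
#' Insertion points are drawn uniformly, kept at least `min_spacing` apart
#' and away from the chromosome ends; placement is retried a bounded number
#' of times.  In `motif_mode = "tprt"` a TTAAAA hexamer (reverse complemented
#' for minus-strand insertions, on the other side) is written into the
#' pre-insertion sequence at `motif_offset` bases from the insertion point.
#'
#' @param pre named character vector with one chromosome (the pre-insertion
#'   genome).
#' @param config a [sim_config()] object (`seed` is not consulted here; set
#'   the RNG beforehand or use [simulate_retro()]).
#' @param avoid optional positions (e.g. a parental locus) insertions must
#'   stay `min_spacing` away from.
#' @return list with `post` (post-insertion genome) and `truths`, a
#'   data.frame with columns `id`, `chrom`, `prePosition`, `postStart`,
#'   `postEnd`, `strand`, `tsdSeq`, `tsdLen`, `polyALen`, `isControl`.
#' @export
plant_insertions <- function(pre, config, avoid = integer(0)) {
  stopifnot(inherits(config, "sim_config"), length(pre) == 1L)
  chrom <- names(pre)[1]
  L <- nbytes(pre[[1]])
  n <- config$n_true + config$n_control
  if (n == 0L)
    return(list(post = pre,
                truths = empty_truths()))
  margin <- max(2000L, config$min_spacing)
  spacing <- config$min_spacing
  slack <- L - 2L * margin - (n - 1L) * spacing
  if (slack < n)
    stop("genome too short for the requested number of spaced insertions")
  # spacing transform: sorted draws without replacement from the slack, plus
  # cumulative offsets, give uniform positions with a guaranteed minimum gap
  ok <- FALSE
  for (try in 1:200) {
    pos <- sort(sample.int(slack, n)) + margin +
      (seq_len(n) - 1L) * spacing
    if (length(avoid) == 0L ||
        all(vapply(pos, function(p) min(abs(p - avoid)), 0) >= spacing)) {
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("failed to place non-overlapping insertions after 200 tries")

  is_control <- sample(rep(c(FALSE, TRUE),
                           c(config$n_true, config$n_control)))
  strand <- if (config$strand_random)
    sample(c("+", "-"), n, replace = TRUE) else rep("+", n)
  tsd_len <- sample.int(config$tsd_len_range[2] - config$tsd_len_range[1] + 1L,
                        n, replace = TRUE) + config$tsd_len_range[1] - 1L
  polya_len <- sample.int(config$polya_len_range[2] -
                            config$polya_len_range[1] + 1L,
                          n, replace = TRUE) + config$polya_len_range[1] - 1L
  tsd_len[is_control] <- 0L
  polya_len[is_control] <- 0L
  tsd_seq <- character(n)
  blocks <- character(n)
  for (i in seq_len(n)) {
    if (is_control[i]) {
      tsd_seq[i] <- ""
      body <- if (strand[i] == "+") config$element else revcomp(config$element)
      blocks[i] <- body
    } else {
      tsd_seq[i] <- random_bases(tsd_len[i], config$base_probs)
      body <- paste0(config$element, strrep("A", polya_len[i]))
      if (strand[i] == "-") body <- revcomp(body)
      blocks[i] <- paste0(tsd_seq[i], body, tsd_seq[i])
    }
  }

  seqstr <- pre[[1]]
  if (config$motif_mode == "tprt") {
    d <- config$motif_offset
    for (i in seq_len(n)) {
      if (is_control[i]) next
      if (strand[i] == "+") {
        s <- pos[i] - d - 6L
        if (s >= 0L)
          substr(seqstr, s + 1L, s + 6L) <- "TTAAAA"
      } else {
        s <- pos[i] + d
        if (s + 6L <= L)
          substr(seqstr, s + 1L, s + 6L) <- "TTTTAA"
      }
    }
  }

  block_len <- nchar(blocks)
  post_start <- pos + c(0L, cumsum(block_len))[seq_len(n)]
  post_end <- post_start + block_len
  post <- setNames(splice_blocks(seqstr, pos, blocks), chrom)

  ids <- character(n)
  ids[!is_control] <- paste0("sim-retro-", seq_len(sum(!is_control)))
  ids[is_control] <- paste0("sim-control-", seq_len(sum(is_control)))
  truths <- data.frame(id = ids, chrom = chrom,
                       prePosition = pos,
                       postStart = post_start, postEnd = post_end,
                       strand = strand, tsdSeq = tsd_seq, tsdLen = tsd_len,
                       polyALen = polya_len, isControl = is_control,
                       stringsAsFactors = FALSE)
  list(post = post, truths = truths)
}

empty_truths <- function() {
  data.frame(id = character(0), chrom = character(0),
             prePosition = integer(0), postStart = integer(0),
             postEnd = integer(0), strand = character(0),
             tsdSeq = character(0), tsdLen = integer(0),
             polyALen = integer(0), isControl = logical(0),
             stringsAsFactors = FALSE)
}

#' Emulate the net alignment of a post- vs pre-insertion genome
#'
#' Builds the net file a pairwise aligner would produce for the reference
#' (post-insertion) genome against the query (pre-insertion) genome: one
#' level-1 fill spanning the aligned backbone, and for each inserted block a
#' gap at its post-insertion interval containing a level-2 fill whose
#' reference span covers the element body — the TSD copies and poly(A) tail
#' fall partially or fully outside the fill, as in real TPRT alignments —
#' and whose query coordinates point at the parental locus.  Each fill edge
#' is independently jittered by up to `config$boundary_jitter` bases and
#' clamped inside its gap.  Controls receive the same treatment with the
#' fill covering the whole bare element.
#'
#' @param truths truth table from [plant_insertions()].
#' @param pre,post pre- and post-insertion genomes (named character
#'   vectors).
#' @param parent_locus list with `chrom`, `strand`, `start`, `size`: the
#'   element's native locus in the query genome.
#' @param config a [sim_config()] object.
#' @return a [net_file()] object that round-trips through
#'   [write_net()]/[parse_net()].
#' @export
emulate_net <- function(truths, pre, post, parent_locus, config) {
  stopifnot(inherits(config, "sim_config"))
  chrom <- names(post)[1]
  post_len <- nbytes(post[[1]])
  pre_len <- nbytes(pre[[1]])
  gaps <- list()
  if (nrow(truths)) {
    o <- order(truths$postStart)
    truths <- truths[o, , drop = FALSE]
    j1 <- jitter_draw(nrow(truths), config$boundary_jitter)
    j2 <- jitter_draw(nrow(truths), config$boundary_jitter)
    elem_len <- nchar(config$element)
    for (i in seq_len(nrow(truths))) {
      tr <- truths[i, ]
      gs <- tr$postStart
      ge <- tr$postEnd
      if (tr$isControl) {
        bs <- gs; be <- ge
      } else if (tr$strand == "+") {
        bs <- gs + tr$tsdLen
        be <- ge - tr$tsdLen - tr$polyALen
      } else {
        bs <- gs + tr$tsdLen + tr$polyALen
        be <- ge - tr$tsdLen
      }
      fs <- min(max(bs + j1[i], gs), ge - 1L)
      fe <- max(min(be + j2[i], ge), fs + 1L)
      fill <- net_node("fill", fs, fe - fs,
                       parent_locus$chrom, tr$strand,
                       parent_locus$start, elem_len,
                       attrs = c("id", as.character(i)))
      gaps[[length(gaps) + 1L]] <-
        net_node("gap", gs, ge - gs, chrom, "+", tr$prePosition, 0L,
                 children = list(fill))
    }
  }
  top <- net_node("fill", 0L, post_len, chrom, "+", 0L, pre_len,
                  attrs = c("id", "0"), children = gaps)
  net_file(list(list(chrom = chrom, size = post_len, fills = list(top))))
}

#' Run the full insertion simulation
#'
#' Sets the seed, draws the random genome, plants one parental element copy
#' (the source locus the emulated net's level-2 fills point at), plants the
#' true and control insertions, and emulates the net.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `retro_sim` with elements `pre`, `post`,
#'   `truths`, `net`, `parent_locus`, `config`.
#' @export
simulate_retro <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg0 <- config
  cfg0$seed <- NULL
  g0 <- random_genome(cfg0)
  L <- nbytes(g0[[1]])
  margin <- max(2000L, config$min_spacing)
  ppos <- sample.int(L - 2L * margin, 1L) + margin
  pre <- setNames(splice_blocks(g0[[1]], ppos, config$element), names(g0)[1])
  parent_locus <- list(chrom = names(g0)[1], strand = "+",
                       start = ppos, size = nchar(config$element))
  planted <- plant_insertions(pre, config,
                              avoid = c(ppos, ppos + nchar(config$element)))
  net <- emulate_net(planted$truths, pre, planted$post, parent_locus, config)
  structure(list(pre = pre, post = planted$post, truths = planted$truths,
                 net = net, parent_locus = parent_locus, config = config),
            class = "retro_sim")
}

#' @export
print.retro_sim <- function(x, ...) {
  cat("<retro_sim> genome ", nbytes(x$post[[1]]), " bp (",
      sum(!x$truths$isControl), " insertions + ",
      sum(x$truths$isControl), " controls), jitter +/-",
      x$config$boundary_jitter, "\n", sep = "")
  invisible(x)
}
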