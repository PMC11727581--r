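#' Net alignment tree nodes and files
#'
#' A UCSC net file describes a pairwise whole-genome alignment as a hierarchy
#' per reference chromosome: `fill` lines are regions aligned in both
#' genomes, `gap` lines are regions present in the reference but absent from
#' the query, and nesting (one extra space of indentation per line) encodes
#' synteny levels.  A fill's children are gaps and a gap's children are fills;
#' a fill nested inside a level-1 fill's gap is a level-2 fill — the signature
#' this package scans for.
#'
#' `net_node()` builds one fill or gap record.  Reference coordinates are
#' 0-based half-open on the + strand; query coordinates are on the strand
#' named in the record, following the UCSC convention.  Attribute tokens
#' beyond the six positional coordinate fields (`id`, `score`, `ali`, `type`,
#' ...) are preserved verbatim and never interpreted.
#'
#' @param kind `"fill"` or `"gap"`.
#' @param ref_start,ref_size reference start (0-based) and span length.
#' @param q_chrom,q_strand,q_start,q_size query chromosome, strand (`"+"` or
#'   `"-"`), start on that strand, and span length (0 allowed for gaps).
#' @param attrs character vector of attribute tokens, kept verbatim.
#' @param children list of child `net_node` objects (gaps under a fill, fills
#'   under a gap).
#' @return a list of class `net_node`.
#' @export
net_node <- function(kind, ref_start, ref_size, q_chrom, q_strand, q_start,
                     q_size, attrs = character(0), children = list()) {
  kind <- match.arg(kind, c("fill", "gap"))
  stopifnot(q_strand %in% c("+", "-"),
            ref_size >= 0, q_size >= 0, ref_start >= 0, q_start >= 0)
  structure(list(kind = kind,
                 ref_start = as.integer(ref_start),
                 ref_size = as.integer(ref_size),
                 q_chrom = as.character(q_chrom),
                 q_strand = as.character(q_strand),
                 q_start = as.integer(q_start),
                 q_size = as.integer(q_size),
                 level = NA_integer_,
                 attrs = as.character(attrs),
                 children = children),
            class = "net_node")
}

#' @rdname net_node
#' @param nets list of per-chromosome entries, each a list with elements
#'   `chrom`, `size` and `fills` (list of top-level `net_node` fills).
#' @return `net_file()`: a list of class `net_file`; fill levels are
#'   (re)computed from the tree depth.
#' @export
net_file <- function(nets = list()) {
  nets <- lapply(nets, function(nt) {
    stopifnot(is.character(nt$chrom), is.numeric(nt$size))
    nt$size <- as.integer(nt$size)
    nt$fills <- lapply(nt$fills, annotate_levels, level = 1L)
    nt[c("chrom", "size", "fills")]
  })
  structure(list(nets = nets), class = "net_file")
}

annotate_levels <- function(node, level) {
  node$level <- if (node$kind == "fill") as.integer(level) else NA_integer_
  next_level <- if (node$kind == "fill") level + 1L else level
  node$children <- lapply(node$children, annotate_levels, level = next_level)
  node
}

#' Parse UCSC net-format text
#'
#' Accepts the full net grammar: `net <chrom> <size>` headers (one per
#' reference chromosome) followed by indented `fill`/`gap` lines with six
#' positional coordinate fields and free attribute pairs.  One leading space
#' encodes one nesting step; tabs are tolerated on input (each counts as one
#' step) but never emitted.  Structural invariants are enforced: children must
#' lie within their parent's reference interval, fills and gaps must
#' alternate, and node ends may not exceed the chromosome size.
#'
#' @param lines character vector of net-format lines.
#' @return a [net_file()] object.
#' @seealso [read_net()], [write_net()]
#' @export
parse_net <- function(lines) {
  stopifnot(is.character(lines))
  keep <- which(!grepl("^[[:space:]]*$", lines))
  n <- length(keep)
  depth <- integer(n)
  kind <- character(n)
  toks <- vector("list", n)
  for (j in seq_len(n)) {
    line <- lines[keep[j]]
    d <- 0L
    while (d < nchar(line) && substr(line, d + 1L, d + 1L) %in% c(" ", "\t"))
      d <- d + 1L
    depth[j] <- d
    tk <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    kind[j] <- tk[1]
    toks[[j]] <- tk
  }

  pos <- 1L
  lineno <- function(j) keep[j]

  coord <- function(tk, field, j) {
    v <- suppressWarnings(as.integer(tk[field]))
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop(sprintf("net parse error at line %d: malformed coordinate field '%s'",
                   lineno(j), tk[field]))
    v
  }

  make_node <- function(j) {
    tk <- toks[[j]]
    if (length(tk) < 7L)
      stop(sprintf("net parse error at line %d: expected 6 coordinate fields",
                   lineno(j)))
    if (!tk[5] %in% c("+", "-"))
      stop(sprintf("net parse error at line %d: bad strand '%s'", lineno(j), tk[5]))
    net_node(kind = tk[1],
             ref_start = coord(tk, 2L, j), ref_size = coord(tk, 3L, j),
             q_chrom = tk[4], q_strand = tk[5],
             q_start = coord(tk, 6L, j), q_size = coord(tk, 7L, j),
             attrs = if (length(tk) > 7L) tk[-(1:7)] else character(0))
  }

  parse_children <- function(parent_depth, parent_kind, parent_iv) {
    children <- list()
    repeat {
      if (pos > n) break
      d <- depth[pos]
      k <- kind[pos]
      if (k == "net" || d <= parent_depth) break
      if (d != parent_depth + 1L)
        stop(sprintf("net parse error at line %d: unexpected indentation depth %d",
                     lineno(pos), d))
      expected <- if (parent_kind %in% c("net", "gap")) "fill" else "gap"
      if (k != expected)
        stop(sprintf("net parse error at line %d: expected '%s' under '%s', found '%s'",
                     lineno(pos), expected, parent_kind, k))
      node <- make_node(pos)
      s <- node$ref_start
      e <- node$ref_start + node$ref_size
      if (s < parent_iv[1] || e > parent_iv[2])
        stop(sprintf(paste0("net structural error at line %d: child interval ",
                            "[%d,%d) escapes parent [%d,%d)"),
                     lineno(pos), s, e, parent_iv[1], parent_iv[2]))
      j <- pos
      pos <<- pos + 1L
      node$children <- parse_children(depth[j], k, c(s, e))
      children[[length(children) + 1L]] <- node
    }
    children
  }

  nets <- list()
  while (pos <= n) {
    if (kind[pos] != "net" || depth[pos] != 0L)
      stop(sprintf("net parse error at line %d: expected 'net' header", lineno(pos)))
    tk <- toks[[pos]]
    if (length(tk) < 3L)
      stop(sprintf("net parse error at line %d: 'net' header needs chrom and size",
                   lineno(pos)))
    chrom <- tk[2]
    size <- coord(tk, 3L, pos)
    pos <- pos + 1L
    fills <- parse_children(0L, "net", c(0L, size))
    nets[[length(nets) + 1L]] <- list(chrom = chrom, size = size, fills = fills)
  }
  net_file(nets)
}

#' Read a net file from disk
#'
#' @param path path to a UCSC net-format file.
#' @return a [net_file()] object.
#' @export
read_net <- function(path) parse_net(readLines(path))

#' Serialise a net tree back to UCSC net-format text
#'
#' Emits one space of indentation per nesting step and single-space-separated
#' fields, so `parse_net(write_net(x))` is structurally the identity and
#' files produced by this writer round-trip byte-identically.
#'
#' @param net a [net_file()] object.
#' @param path optional output path; when given the lines are written there.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_net <- function(net, path = NULL) {
  stopifnot(inherits(net, "net_file"))
  emit <- function(node, d) {
    line <- paste0(strrep(" ", d), node$kind, " ",
                   node$ref_start, " ", node$ref_size, " ",
                   node$q_chrom, " ", node$q_strand, " ",
                   node$q_start, " ", node$q_size)
    if (length(node$attrs))
      line <- paste(line, paste(node$attrs, collapse = " "))
    c(line, unlist(lapply(node$children, emit, d = d + 1L), use.names = FALSE))
  }
  lines <- unlist(lapply(net$nets, function(nt) {
    c(paste("net", nt$chrom, nt$size),
      unlist(lapply(nt$fills, emit, d = 1L), use.names = FALSE))
  }), use.names = FALSE)
  if (is.null(lines)) lines <- character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Enumerate (gap, child fill) pairs of a net tree
#'
#' Yields every pair in which a fill is the direct child of a gap — the net
#' signature of a sequence present in the reference but absent from the query
#' at that locus, yet aligning back to a source locus elsewhere: the candidate
#' unit for retrotransposition calling.  Pairs are returned in reference
#' coordinate order (per net, by gap start then fill start).
#'
#' @param net a [net_file()] object.
#' @return list of entries `list(chrom, gap, fill)`.
#' @export
iter_gap_fill_pairs <- function(net) {
  stopifnot(inherits(net, "net_file"))
  out <- list()
  walk <- function(node, chrom) {
    if (node$kind == "gap") {
      for (child in node$children) {
        if (child$kind == "fill")
          out[[length(out) + 1L]] <<- list(chrom = chrom, gap = node, fill = child)
      }
    }
    for (child in node$children) walk(child, chrom)
  }
  for (nt in net$nets) for (f in nt$fills) walk(f, nt$chrom)
  if (length(out) > 1L) {
    key <- vapply(out, function(p) p$gap$ref_start + p$fill$ref_start * 1e-9, 0)
    chr <- vapply(out, function(p) p$chrom, "")
    out <- out[order(match(chr, unique(chr)), key)]
  }
  out
}

#' @export
print.net_file <- function(x, ...) {
  n_nodes <- function(node) 1L + sum(vapply(node$children, n_nodes, 0L))
  total <- sum(vapply(x$nets, function(nt)
    sum(vapply(nt$fills, n_nodes, 0L)), 0L))
  cat("<net_file> ", length(x$nets), " chromosome(s), ", total,
      " fill/gap node(s), ", length(iter_gap_fill_pairs(x)),
      " gap-enclosed fill(s)\n", sep = "")
  invisible(x)
}
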