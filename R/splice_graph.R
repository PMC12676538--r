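# Weighted splice graph of one locus.
#
# Vertices are "partial exons": maximal read-covered genomic intervals
# between splice sites (junction endpoints) and coverage gaps. Each vertex
# carries w_v (mean per-base coverage) and w_m (number of UMI fragments with
# at least one aligned base in the interval). A directed edge connects two
# vertices bridged by a fragment, via a splice junction or by reading
# through an abutting boundary, weighted by the number of supporting
# fragments (w_e). A source s and sink t flank the graph. All edges point
# from lower to higher genomic coordinate, so the graph is acyclic for both
# strands; strand only affects the 5'/3' interpretation downstream.

new_splice_graph <- function(chrom, strand, vertices, edges,
                             removed = NULL) {
  t_id <- if (nrow(vertices)) max(vertices$id) + 1L else 1L
  if (is.null(removed)) {
    removed <- data.frame(id = integer(0), start = integer(0),
                          end = integer(0), rule = character(0),
                          stringsAsFactors = FALSE)
  }
  structure(list(chrom = chrom, strand = strand, vertices = vertices,
                 edges = edges, s = 0L, t = t_id, removed = removed),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("<splice_graph %s(%s): %d vertices, %d edges, %d removed>\n",
              x$chrom, x$strand, nrow(x$vertices), nrow(x$edges),
              nrow(x$removed)))
  invisible(x)
}

vertex_row <- function(G, id) G$vertices[match(id, G$vertices$id), ]

in_edges <- function(G, id) G$edges[G$edges$to == id, , drop = FALSE]
out_edges <- function(G, id) G$edges[G$edges$from == id, , drop = FALSE]

edge_weight <- function(G, from, to) {
  w <- G$edges$we[G$edges$from == from & G$edges$to == to]
  if (length(w)) w[1] else NA_real_
}

#' Are two vertices immediately joint?
#'
#' Two vertices are immediately joint when their genomic intervals abut
#' exactly (the end of `u` equals the start of `v`), i.e. they are
#' consecutive regions in the genome.
#'
#' @param G A `splice_graph`.
#' @param u,v Vertex ids, `u` preceding `v` in coordinate.
#' @return `TRUE` iff `u_r == v_l`.
#' @export
immediately_joint <- function(G, u, v) {
  ru <- vertex_row(G, u); rv <- vertex_row(G, v)
  stopifnot(!is.na(ru$id), !is.na(rv$id))
  if (rv$start < ru$end && ru$start < rv$end) {
    stop("vertex intervals overlap; invalid splice graph", call. = FALSE)
  }
  stopifnot(ru$start <= rv$start)
  ru$end == rv$start
}

# ordered vertex ids overlapped (>=1 base) by each fragment's blocks
compute_vertex_paths <- function(frags, vertices) {
  if (!nrow(vertices) || !nrow(frags)) {
    return(rep(list(integer(0)), nrow(frags)))
  }
  vr <- IRanges::IRanges(vertices$start + 1L, vertices$end)
  nb <- vapply(frags$blocks, nrow, integer(1))
  allb <- do.call(rbind, frags$blocks)
  br <- IRanges::IRanges(allb[, 1] + 1L, allb[, 2])
  fidx <- rep(seq_len(nrow(frags)), nb)
  hits <- IRanges::findOverlaps(br, vr)
  paths <- rep(list(integer(0)), nrow(frags))
  if (length(hits)) {
    qh <- fidx[S4Vectors::queryHits(hits)]
    sh <- vertices$id[S4Vectors::subjectHits(hits)]
    sp <- split(sh, qh)
    for (nm in names(sp)) {
      paths[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
    }
  }
  paths
}

#' Build the splice graph of a locus
#'
#' Splice sites are the union of junction endpoints observed in the locus.
#' The locus span is cut at splice sites, and each maximal read-covered run
#' between cuts becomes one vertex (a putative partial or full exon).
#' Junction edges connect donor/acceptor vertices with weight equal to the
#' number of supporting fragments; read-through edges connect immediately
#' joint vertices bridged by at least one fragment block spanning the
#' boundary. The source `s` feeds every vertex without an in-edge and every
#' vertex without an out-edge drains into the sink `t`, weighted by the
#' number of fragments starting (ending) there.
#'
#' @param locus A `locus` object with at least one fragment.
#' @return A `splice_graph`.
#' @export
build_graph <- function(locus) {
  frags <- locus$fragments
  if (is.null(frags) || nrow(frags) == 0) {
    stop("cannot build a splice graph from a locus with zero fragments",
         call. = FALSE)
  }
  off <- locus$start
  width <- locus$end - locus$start
  delta <- integer(width + 1L)
  for (b in frags$blocks) {
    delta[b[, 1] - off + 1L] <- delta[b[, 1] - off + 1L] + 1L
    delta[b[, 2] - off + 1L] <- delta[b[, 2] - off + 1L] - 1L
  }
  cov <- cumsum(delta[seq_len(width)])

  sites <- sort(unique(unlist(lapply(frags$junctions, function(j) c(j)))))
  sites <- sites[sites > locus$start & sites < locus$end]
  bounds <- c(locus$start, sites, locus$end)

  vs <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    seg <- cov[(lo - off + 1L):(hi - off)]
    r <- rle(seg > 0)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    for (k in which(r$values)) {
      vs[[length(vs) + 1L]] <- c(lo + starts[k], lo + ends[k])
    }
  }
  if (!length(vs)) stop("locus has no covered bases", call. = FALSE)
  vm <- do.call(rbind, vs)
  vertices <- data.frame(id = seq_len(nrow(vm)), start = vm[, 1],
                         end = vm[, 2])
  vertices$wv <- vapply(seq_len(nrow(vertices)), function(i) {
    idx <- (vertices$start[i] - off + 1L):(vertices$end[i] - off)
    sum(cov[idx]) / length(idx)
  }, numeric(1))

  paths <- compute_vertex_paths(frags, vertices)

  vertices$wm <- 0L
  umi_idx <- which(frags$read_type == "UMI")
  if (length(umi_idx)) {
    tab <- table(unlist(paths[umi_idx]))
    vertices$wm[match(as.integer(names(tab)), vertices$id)] <-
      as.integer(tab)
  }

  vstart <- vertices$start; vend <- vertices$end

  # junction edges
  jtally <- new.env(parent = emptyenv())
  # read-through edges: adjacent vertex pairs spanned by one block
  rtally <- new.env(parent = emptyenv())
  bump <- function(env, key) {
    assign(key, (if (exists(key, envir = env)) get(key, envir = env) else 0L)
           + 1L, envir = env)
  }
  for (i in seq_len(nrow(frags))) {
    j <- frags$junctions[[i]]
    if (nrow(j)) {
      for (k in seq_len(nrow(j))) {
        u <- vertices$id[match(j[k, 1], vend)]
        v <- vertices$id[match(j[k, 2], vstart)]
        if (!is.na(u) && !is.na(v)) bump(jtally, paste(u, v))
      }
    }
    b <- frags$blocks[[i]]
    pairs <- character(0)
    for (k in seq_len(nrow(b))) {
      inside <- which(vstart >= b[k, 1] & vend <= b[k, 2] |
                        (vstart < b[k, 2] & vend > b[k, 1]))
      inside <- inside[order(vstart[inside])]
      if (length(inside) > 1) {
        for (q in seq_len(length(inside) - 1L)) {
          u <- inside[q]; v <- inside[q + 1L]
          # the block must actually cover bases on both sides of the boundary
          if (vend[u] == vstart[v] && b[k, 1] < vend[u] &&
              b[k, 2] > vstart[v]) {
            pairs <- c(pairs, paste(vertices$id[u], vertices$id[v]))
          }
        }
      }
    }
    for (p in unique(pairs)) bump(rtally, p)
  }

  parse_env <- function(env, type) {
    keys <- ls(env)
    if (!length(keys)) {
      return(data.frame(from = integer(0), to = integer(0), we = numeric(0),
                        type = character(0), stringsAsFactors = FALSE))
    }
    parts <- do.call(rbind, strsplit(keys, " "))
    data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
               we = vapply(keys, get, numeric(1), envir = env,
                           USE.NAMES = FALSE),
               type = type, stringsAsFactors = FALSE)
  }
  edges <- rbind(parse_env(jtally, "junction"),
                 parse_env(rtally, "readthrough"))

  s_id <- 0L
  t_id <- nrow(vertices) + 1L
  first_v <- vapply(paths, function(p) if (length(p)) p[1] else NA_integer_,
                    integer(1))
  last_v <- vapply(paths, function(p) if (length(p)) p[length(p)] else
    NA_integer_, integer(1))
  no_in <- setdiff(vertices$id, edges$to)
  no_out <- setdiff(vertices$id, edges$from)
  sedges <- data.frame(from = s_id, to = no_in,
                       we = vapply(no_in, function(v)
                         max(1L, sum(first_v == v, na.rm = TRUE)),
                         numeric(1)),
                       type = "source", stringsAsFactors = FALSE)
  tedges <- data.frame(from = no_out, to = t_id,
                       we = vapply(no_out, function(v)
                         max(1L, sum(last_v == v, na.rm = TRUE)),
                         numeric(1)),
                       type = "sink", stringsAsFactors = FALSE)
  edges <- rbind(edges, sedges, tedges)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  new_splice_graph(locus$chrom, locus$strand, vertices, edges)
}

remove_vertices <- function(G, ids, rule) {
  if (!length(ids)) return(G)
  hit <- G$vertices$id %in% ids
  G$removed <- rbind(G$removed,
                     data.frame(id = G$vertices$id[hit],
                                start = G$vertices$start[hit],
                                end = G$vertices$end[hit],
                                rule = rule, stringsAsFactors = FALSE))
  G$vertices <- G$vertices[!hit, , drop = FALSE]
  G$edges <- G$edges[!(G$edges$from %in% ids | G$edges$to %in% ids), ,
                     drop = FALSE]
  G
}

full_ir_candidates <- function(G, p) {
  out <- integer(0)
  for (v in G$vertices$id) {
    ins <- in_edges(G, v); outs <- out_edges(G, v)
    if (nrow(ins) != 1L || nrow(outs) != 1L) next
    vm <- ins$from; vp <- outs$to
    if (vm == G$s || vp == G$t) next
    rv <- vertex_row(G, v)
    if (vertex_row(G, vm)$end != rv$start) next
    if (rv$end != vertex_row(G, vp)$start) next
    wsk <- edge_weight(G, vm, vp)
    if (is.na(wsk)) next
    skip_rule <- (rv$wv <= p$a1 * wsk || ins$we <= p$a2 * wsk ||
                    outs$we <= p$a3 * wsk) && rv$wm <= p$a4
    lariat_rule <- rv$wv >= p$a5 * max(ins$we, outs$we)
    if (skip_rule || lariat_rule) out <- c(out, v)
  }
  out
}

partial_ir_candidates <- function(G, p) {
  out <- integer(0)
  for (v in G$vertices$id) {
    ins <- in_edges(G, v); outs <- out_edges(G, v)
    if (nrow(ins) != 1L || nrow(outs) != 1L) next
    rv <- vertex_row(G, v)
    if (ins$from == G$s && outs$to != G$t) {
      # false alternative first exon: retained tail of an intron running
      # into the true acceptor exon
      vp <- outs$to
      if (rv$end != vertex_row(G, vp)$start) next
      vin <- in_edges(G, vp)
      if (nrow(vin) < 2L) next
      wprime <- max(vin$we)
      if ((rv$wv <= p$b1 * wprime || outs$we <= p$b2 * wprime) &&
          rv$wm <= p$b3) out <- c(out, v)
    } else if (outs$to == G$t && ins$from != G$s) {
      # mirror image: false alternative last exon
      vm <- ins$from
      if (vertex_row(G, vm)$end != rv$start) next
      vout <- out_edges(G, vm)
      if (nrow(vout) < 2L) next
      wprime <- max(vout$we)
      if ((rv$wv <= p$b1 * wprime || ins$we <= p$b2 * wprime) &&
          rv$wm <= p$b3) out <- c(out, v)
    }
  }
  out
}

isolated_candidates <- function(G, p) {
  out <- integer(0)
  for (v in G$vertices$id) {
    ins <- in_edges(G, v); outs <- out_edges(G, v)
    if (all(ins$from == G$s) && all(outs$to == G$t) &&
        vertex_row(G, v)$wm < p$single_exon_min_umi) {
      out <- c(out, v)
    }
  }
  out
}

prune_fixpoint <- function(G, p, finder, rule) {
  repeat {
    ids <- finder(G, p)
    if (!length(ids)) break
    G <- remove_vertices(G, ids, rule)
  }
  G
}

#' Prune full intron retentions
#'
#' Removes every vertex with a single predecessor and successor, immediately
#' joint to both and skipped by a direct edge between them, whose weights
#' satisfy the full-retention inequalities (see [ir_params()]) — including
#' the intron-lariat clause. Candidates are evaluated against the graph
#' state at the start of each pass, removed together, and passes repeat to a
#' fixed point.
#'
#' @param G A `splice_graph`.
#' @param p [ir_params()].
#' @return The pruned graph; removed vertices are logged in `G$removed`.
#' @export
prune_full_intron_retention <- function(G, p = ir_params()) {
  prune_fixpoint(G, p, full_ir_candidates, "full_ir")
}

#' Prune partial intron retentions
#'
#' Removes vertices that present as false alternative first exons (adjacent
#' to the source, immediately joint to a successor that has competing
#' in-edges) or, mirrored, false alternative last exons, when their weights
#' fall below the partial-retention thresholds and UMI support is low.
#'
#' @inheritParams prune_full_intron_retention
#' @return The pruned graph.
#' @export
prune_partial_intron_retention <- function(G, p = ir_params()) {
  prune_fixpoint(G, p, partial_ir_candidates, "partial_ir")
}

#' Prune isolated vertices
#'
#' A vertex touching only the source and sink is either a single-exon
#' transcript or an intron-lariat/contamination artifact; it is kept only
#' when well supported by UMI reads (`w_m >= single_exon_min_umi`).
#'
#' @inheritParams prune_full_intron_retention
#' @return The pruned graph.
#' @export
prune_isolated_vertices <- function(G, p = ir_params()) {
  prune_fixpoint(G, p, isolated_candidates, "isolated")
}

#' Apply all pruning rules in order
#'
#' Full intron retention, then partial intron retention, then isolated
#' vertices, each iterated to a fixed point.
#'
#' @inheritParams prune_full_intron_retention
#' @return The pruned graph.
#' @export
prune_graph <- function(G, p = ir_params()) {
  G <- prune_full_intron_retention(G, p)
  G <- prune_partial_intron_retention(G, p)
  prune_isolated_vertices(G, p)
}

#' Extract phasing paths from a locus against a (pruned) splice graph
#'
#' Each fragment is mapped to the ordered list of surviving vertices its
#' blocks overlap. Fragments touching a removed vertex or connecting two
#' vertices that are no longer joined by an edge are dropped. Identical
#' vertex sequences are aggregated with fragment and UMI-fragment
#' multiplicities; these chains constrain the decomposition.
#'
#' @param locus The `locus` the graph was built from.
#' @param G The (pruned) `splice_graph`.
#' @return A `data.frame` with list-column `path` (integer vertex ids),
#'   `multiplicity` and `umi_multiplicity`.
#' @export
extract_phasing_paths <- function(locus, G) {
  frags <- locus$fragments
  paths <- compute_vertex_paths(frags, G$vertices)
  ekey <- paste(G$edges$from, G$edges$to)
  keep <- logical(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    p <- paths[[i]]
    if (!length(p)) next
    b <- frags$blocks[[i]]
    if (nrow(G$removed)) {
      touch <- any(vapply(seq_len(nrow(G$removed)), function(k) {
        any(b[, 1] < G$removed$end[k] & b[, 2] > G$removed$start[k])
      }, logical(1)))
      if (touch) next
    }
    if (length(p) > 1) {
      pk <- paste(p[-length(p)], p[-1])
      if (!all(pk %in% ekey)) next
    }
    keep[i] <- TRUE
  }
  key <- vapply(seq_len(nrow(frags)), function(i)
    paste(paths[[i]], collapse = ","), character(1))
  kept <- which(keep)
  if (!length(kept)) {
    out <- data.frame(multiplicity = integer(0),
                      umi_multiplicity = integer(0))
    out$path <- list()
    return(out)
  }
  grp <- split(kept, key[kept])
  ord <- names(grp)[order(names(grp))]
  out <- data.frame(
    multiplicity = vapply(grp[ord], length, integer(1)),
    umi_multiplicity = vapply(grp[ord], function(ii)
      sum(frags$read_type[ii] == "UMI"), integer(1)),
    row.names = NULL)
  out$path <- lapply(grp[ord], function(ii) paths[[ii[1]]])
  out
}

#' Parse a splice graph from its text description
#'
#' The format has one record per line: `chrom <name>`, `strand <+/->`,
#' `vertex <id> <start> <end> wv=<float> wm=<int>` and
#' `edge <from> <to> we=<float>` where `from`/`to` may be `s`/`t`.
#' Blank lines and lines starting with `#` are ignored. A packaged example
#' (`system.file("extdata", "ir_pruning_example_graph.txt", package =
#' "umisplice")`) encodes an eight-vertex topology containing one full
#' intron retention, one partial intron retention, and one isolated
#' intronic vertex.
#'
#' @param text Character vector of lines, a single string with newlines, or
#'   a file path.
#' @return A `splice_graph`.
#' @export
make_graph_fixture <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\n")[[1]]
  }
  lines <- text
  chrom <- "chr1"; strand <- "+"
  vrows <- list(); erows <- list()
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (l == "" || startsWith(l, "#")) next
    tok <- strsplit(l, "[ \t]+")[[1]]
    fail <- function(msg) stop(sprintf("graph description line %d: %s",
                                       ln, msg), call. = FALSE)
    kv <- function(x, k) {
      if (!startsWith(x, paste0(k, "="))) fail(paste("expected", k, "=..."))
      as.numeric(sub(paste0(k, "="), "", x))
    }
    if (tok[1] == "chrom") chrom <- tok[2]
    else if (tok[1] == "strand") {
      if (!tok[2] %in% c("+", "-")) fail("strand must be + or -")
      strand <- tok[2]
    } else if (tok[1] == "vertex") {
      if (length(tok) != 6) fail("vertex needs id start end wv= wm=")
      vrows[[length(vrows) + 1L]] <-
        data.frame(id = as.integer(tok[2]), start = as.integer(tok[3]),
                   end = as.integer(tok[4]), wv = kv(tok[5], "wv"),
                   wm = as.integer(kv(tok[6], "wm")))
    } else if (tok[1] == "edge") {
      if (length(tok) != 4) fail("edge needs from to we=")
      erows[[length(erows) + 1L]] <-
        data.frame(from = tok[2], to = tok[3], we = kv(tok[4], "we"),
                   stringsAsFactors = FALSE)
    } else fail(paste("unknown record", tok[1]))
  }
  if (!length(vrows)) stop("graph description has no vertices",
                           call. = FALSE)
  vertices <- do.call(rbind, vrows)
  vertices <- vertices[order(vertices$start), , drop = FALSE]
  rownames(vertices) <- NULL
  if (anyDuplicated(vertices$id)) stop("duplicate vertex id", call. = FALSE)
  if (nrow(vertices) > 1 &&
      any(vertices$start[-1] < vertices$end[-nrow(vertices)])) {
    stop("vertex intervals overlap", call. = FALSE)
  }
  t_id <- max(vertices$id) + 1L
  edges <- do.call(rbind, erows)
  conv <- function(x) ifelse(x == "s", 0L,
                             ifelse(x == "t", t_id, suppressWarnings(
                               as.integer(x))))
  from <- conv(edges$from); to <- conv(edges$to)
  if (any(is.na(from)) || any(is.na(to))) {
    stop("edge endpoint is neither s, t nor a vertex id", call. = FALSE)
  }
  if (any(to == 0L)) stop("source must have no in-edges", call. = FALSE)
  if (any(from == t_id)) stop("sink must have no out-edges", call. = FALSE)
  type <- rep("junction", length(from))
  vst <- vertices$start[match(to, vertices$id)]
  ven <- vertices$end[match(from, vertices$id)]
  inner <- from != 0L & to != t_id
  if (any(inner & vst < ven)) {
    stop("edges must run from lower to higher coordinate", call. = FALSE)
  }
  type[inner & ven == vst] <- "readthrough"
  type[from == 0L] <- "source"
  type[to == t_id] <- "sink"
  G <- new_splice_graph(chrom, strand, vertices,
                        data.frame(from = from, to = to, we = edges$we,
                                   type = type, stringsAsFactors = FALSE))
  G$t <- t_id
  G
}

#' Serialize a splice graph to its text description
#'
#' Inverse of [make_graph_fixture()]; round-trips exactly.
#'
#' @param G A `splice_graph`.
#' @return Character vector of lines.
#' @export
dump_graph <- function(G) {
  v <- G$vertices
  e <- G$edges
  lab <- function(id) ifelse(id == G$s, "s", ifelse(id == G$t, "t",
                                                    as.character(id)))
  c(paste("chrom", G$chrom),
    paste("strand", G$strand),
    sprintf("vertex %d %d %d wv=%s wm=%d", v$id, v$start, v$end,
            format(v$wv, trim = TRUE), v$wm),
    sprintf("edge %s %s we=%s", lab(e$from), lab(e$to),
            format(e$we, trim = TRUE)))
}
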