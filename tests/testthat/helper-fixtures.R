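# Shared fixtures: hand-built SAM files, the packaged pruning example
# graph, a random splice-graph generator, and an independent brute-force
# evaluator of the pruning inequalities (kept deliberately separate from
# the package implementation: it re-reads the written conditions directly).

example_graph <- function() {
  make_graph_fixture(system.file("extdata", "ir_pruning_example_graph.txt",
                                 package = "umisplice"))
}

# --- minimal SAM construction -------------------------------------------

sam_header <- function(len = 100000L, chrom = "chr1") {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

# one alignment record; blocks are 0-based half-open
sam_record <- function(qname, blocks, flag = 0L, chrom = "chr1",
                       mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L,
                       tags = character(0)) {
  cig <- paste(vapply(seq_len(nrow(blocks)), function(i) {
    out <- sprintf("%dM", blocks[i, 2] - blocks[i, 1])
    if (i < nrow(blocks)) {
      out <- paste0(out, sprintf("%dN", blocks[i + 1, 1] - blocks[i, 2]))
    }
    out
  }, character(1)), collapse = "")
  paste(c(qname, flag, chrom, blocks[1, 1] + 1L, mapq, cig, rnext, pnext,
          tlen, "*", "*", tags), collapse = "\t")
}

write_sam <- function(records, chrom = "chr1", len = 100000L) {
  path <- tempfile(fileext = ".sam")
  pos <- as.integer(vapply(strsplit(records, "\t"), `[[`, character(1), 4))
  writeLines(c(sam_header(len, chrom), records[order(pos)]), path)
  path
}

# a simple paired fragment: two FR mates, optionally spliced, with tags
sam_pair <- function(qname, blocks1, blocks2, umi = NULL, cell = "BC1",
                     strand = "+", xs = NULL) {
  tags1 <- tags2 <- sprintf("BC:Z:%s", cell)
  if (!is.null(umi)) {
    tags1 <- c(tags1, sprintf("UB:Z:%s", umi))
    tags2 <- c(tags2, sprintf("UB:Z:%s", umi))
  }
  if (!is.null(xs)) {
    if (nrow(blocks1) > 1) tags1 <- c(tags1, sprintf("XS:A:%s", xs))
    if (nrow(blocks2) > 1) tags2 <- c(tags2, sprintf("XS:A:%s", xs))
  }
  m1rev <- strand == "-"
  f1 <- 1L + 2L + 64L + (if (m1rev) 16L else 0L) + (if (!m1rev) 32L else 0L)
  f2 <- 1L + 2L + 128L + (if (!m1rev) 16L else 0L) + (if (m1rev) 32L else 0L)
  c(sam_record(qname, blocks1, f1, rnext = "=", pnext = blocks2[1, 1] + 1L,
               tags = tags1),
    sam_record(qname, blocks2, f2, rnext = "=", pnext = blocks1[1, 1] + 1L,
               tags = tags2))
}

# --- random splice graphs ------------------------------------------------

random_splice_graph <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:12, 1)
  starts <- integer(n); ends <- integer(n); cur <- 100L
  for (i in seq_len(n)) {
    w <- sample(20:200, 1)
    starts[i] <- cur; ends[i] <- cur + w
    cur <- cur + w + (if (stats::runif(1) < 0.5) 0L else sample(10:100, 1))
  }
  vertices <- data.frame(id = seq_len(n), start = starts, end = ends,
                         wv = round(stats::runif(n, 0, 15), 2),
                         wm = sample(0:3, n, replace = TRUE))
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) {
    if (stats::runif(1) < 0.85) { from <- c(from, i); to <- c(to, i + 1L) }
    if (i + 2L <= n && stats::runif(1) < 0.35) {
      from <- c(from, i); to <- c(to, i + 2L)
    }
    if (i + 3L <= n && stats::runif(1) < 0.1) {
      from <- c(from, i); to <- c(to, i + 3L)
    }
  }
  type <- ifelse(ends[from] == starts[to], "readthrough", "junction")
  we <- sample(0:12, length(from), replace = TRUE)
  t_id <- n + 1L
  no_in <- setdiff(seq_len(n), to)
  no_out <- setdiff(seq_len(n), from)
  extra_s <- setdiff(which(stats::runif(n) < 0.1), no_in)
  extra_t <- setdiff(which(stats::runif(n) < 0.1), no_out)
  edges <- data.frame(
    from = c(from, rep(0L, length(no_in) + length(extra_s)),
             no_out, extra_t),
    to = c(to, no_in, extra_s, rep(t_id, length(no_out) + length(extra_t))),
    we = c(we, sample(1:10, length(no_in) + length(extra_s) +
                        length(no_out) + length(extra_t), replace = TRUE)),
    type = c(type, rep("source", length(no_in) + length(extra_s)),
             rep("sink", length(no_out) + length(extra_t))),
    stringsAsFactors = FALSE)
  G <- umisplice:::new_splice_graph("chr1", sample(c("+", "-"), 1),
                                    vertices, edges)
  G$t <- t_id
  G
}

# --- independent evaluator of the pruning conditions ---------------------

oracle_full_ir <- function(G, p) {
  removed <- integer(0)
  for (v in G$vertices$id) {
    vr <- G$vertices[G$vertices$id == v, ]
    ein <- G$edges[G$edges$to == v, ]
    eout <- G$edges[G$edges$from == v, ]
    if (nrow(ein) != 1 || nrow(eout) != 1) next
    vm <- ein$from; vp <- eout$to
    if (vm == G$s || vp == G$t) next
    rm_ <- G$vertices[G$vertices$id == vm, ]
    rp <- G$vertices[G$vertices$id == vp, ]
    if (!(rm_$end == vr$start && vr$end == rp$start)) next
    skip <- G$edges[G$edges$from == vm & G$edges$to == vp, ]
    if (nrow(skip) == 0) next
    c1 <- (vr$wv <= p$a1 * skip$we) || (ein$we <= p$a2 * skip$we) ||
      (eout$we <= p$a3 * skip$we)
    lowumi <- vr$wm <= p$a4
    lariat <- vr$wv >= p$a5 * max(ein$we, eout$we)
    if ((c1 && lowumi) || lariat) removed <- c(removed, v)
  }
  removed
}

oracle_partial_ir <- function(G, p) {
  removed <- integer(0)
  for (v in G$vertices$id) {
    vr <- G$vertices[G$vertices$id == v, ]
    ein <- G$edges[G$edges$to == v, ]
    eout <- G$edges[G$edges$from == v, ]
    if (nrow(ein) != 1 || nrow(eout) != 1) next
    if (ein$from == G$s && eout$to != G$t) {
      vp <- eout$to
      rp <- G$vertices[G$vertices$id == vp, ]
      if (vr$end != rp$start) next
      allin <- G$edges[G$edges$to == vp, ]
      if (nrow(allin) < 2) next
      wp <- max(allin$we)
      if ((vr$wv <= p$b1 * wp || eout$we <= p$b2 * wp) && vr$wm <= p$b3) {
        removed <- c(removed, v)
      }
    }
    if (eout$to == G$t && ein$from != G$s) {
      vm <- ein$from
      rm_ <- G$vertices[G$vertices$id == vm, ]
      if (rm_$end != vr$start) next
      allout <- G$edges[G$edges$from == vm, ]
      if (nrow(allout) < 2) next
      wp <- max(allout$we)
      if ((vr$wv <= p$b1 * wp || ein$we <= p$b2 * wp) && vr$wm <= p$b3) {
        removed <- c(removed, v)
      }
    }
  }
  unique(removed)
}

oracle_isolated <- function(G, p) {
  removed <- integer(0)
  for (v in G$vertices$id) {
    nb <- c(G$edges$from[G$edges$to == v], G$edges$to[G$edges$from == v])
    if (all(nb %in% c(G$s, G$t)) &&
        G$vertices$wm[G$vertices$id == v] < p$single_exon_min_umi) {
      removed <- c(removed, v)
    }
  }
  removed
}

oracle_drop <- function(G, ids) {
  G$vertices <- G$vertices[!G$vertices$id %in% ids, , drop = FALSE]
  G$edges <- G$edges[!(G$edges$from %in% ids | G$edges$to %in% ids), ,
                     drop = FALSE]
  G
}

# naive fixed-point iteration mirroring the written pass semantics
oracle_prune_all <- function(G, p) {
  removed <- list(full_ir = integer(0), partial_ir = integer(0),
                  isolated = integer(0))
  repeat {
    ids <- oracle_full_ir(G, p)
    if (!length(ids)) break
    removed$full_ir <- c(removed$full_ir, ids)
    G <- oracle_drop(G, ids)
  }
  repeat {
    ids <- oracle_partial_ir(G, p)
    if (!length(ids)) break
    removed$partial_ir <- c(removed$partial_ir, ids)
    G <- oracle_drop(G, ids)
  }
  repeat {
    ids <- oracle_isolated(G, p)
    if (!length(ids)) break
    removed$isolated <- c(removed$isolated, ids)
    G <- oracle_drop(G, ids)
  }
  removed
}

removed_ids <- function(G, rule = NULL) {
  r <- G$removed
  if (!is.null(rule)) r <- r[r$rule == rule, , drop = FALSE]
  sort(r$id)
}
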