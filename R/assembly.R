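# Phase-constrained decomposition of the pruned splice graph and transcript
# selection.

new_transcripts <- function(chrom = character(0), strand = character(0),
                            exons = list(), coverage = numeric(0),
                            cell_id = character(0), source = character(0),
                            gene_id = character(0),
                            transcript_id = character(0)) {
  df <- data.frame(chrom = chrom, strand = strand, coverage = coverage,
                   cell_id = cell_id, source = source, gene_id = gene_id,
                   transcript_id = transcript_id, stringsAsFactors = FALSE)
  df$exons <- exons
  df
}

tx_start <- function(tx) vapply(tx$exons, function(e) e[1, 1], integer(1))
tx_end <- function(tx) vapply(tx$exons, function(e) e[nrow(e), 2], integer(1))

sort_transcripts <- function(tx) {
  if (!nrow(tx)) return(tx)
  o <- order(tx$chrom, tx_start(tx), tx_end(tx),
             vapply(tx$exons, nrow, integer(1)), tx$strand)
  tx <- tx[o, , drop = FALSE]
  rownames(tx) <- NULL
  tx
}

# Merge a vertex path into exons: consecutive immediately-joint vertices
# collapse into one exon. Returns the exon matrix and the vertex-id runs.
path_to_exons <- function(G, path) {
  v <- G$vertices[match(path, G$vertices$id), ]
  runs <- list(); cur <- 1L
  if (nrow(v) > 1) {
    for (i in 2:nrow(v)) {
      if (v$start[i] != v$end[i - 1L]) {
        runs[[length(runs) + 1L]] <- cur:(i - 1L)
        cur <- i
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur:nrow(v)
  exons <- do.call(rbind, lapply(runs, function(ii)
    c(v$start[ii[1]], v$end[ii[length(ii)]])))
  colnames(exons) <- c("start", "end")
  list(exons = exons, runs = lapply(runs, function(ii) v$id[ii]))
}

edge_key <- function(from, to) paste(from, to)

residual_vector <- function(G) {
  stats::setNames(as.numeric(G$edges$we), edge_key(G$edges$from, G$edges$to))
}

# Widest (maximum-bottleneck) s->t path on the residual weights, optionally
# forced through an ordered vertex chain. Ties are broken towards the
# vertex with the smaller genomic start, making the decomposition
# deterministic. Returns NULL if no all-positive path exists (and
# `require_positive` is TRUE).
widest_path <- function(G, res, chain = NULL, require_positive = TRUE) {
  ord <- c(G$s, G$vertices$id[order(G$vertices$start, G$vertices$id)], G$t)
  rank <- stats::setNames(seq_along(ord), ord)
  e <- G$edges
  w <- res[edge_key(e$from, e$to)]
  ok <- if (require_positive) w > 0 else rep(TRUE, length(w))

  dp_forward <- function(target_allowed = NULL) {
    best <- stats::setNames(rep(-Inf, length(ord)), ord)
    pred <- stats::setNames(rep(NA_integer_, length(ord)), ord)
    best[as.character(G$s)] <- Inf
    for (v in ord[-1]) {
      idx <- which(e$to == v & ok)
      if (!length(idx)) next
      cand <- pmin(best[as.character(e$from[idx])], w[idx])
      if (all(!is.finite(cand))) next
      # deterministic: among equal bottlenecks prefer the upstream vertex
      # earliest in coordinate order
      mx <- max(cand)
      tiek <- idx[cand == mx]
      k <- tiek[which.min(rank[as.character(e$from[tiek])])]
      best[as.character(v)] <- mx
      pred[as.character(v)] <- e$from[k]
    }
    list(best = best, pred = pred)
  }
  dp_backward <- function() {
    best <- stats::setNames(rep(-Inf, length(ord)), ord)
    succ <- stats::setNames(rep(NA_integer_, length(ord)), ord)
    best[as.character(G$t)] <- Inf
    for (v in rev(ord[-length(ord)])) {
      idx <- which(e$from == v & ok)
      if (!length(idx)) next
      cand <- pmin(best[as.character(e$to[idx])], w[idx])
      mx <- max(cand)
      if (!is.finite(mx)) next
      tiek <- idx[cand == mx]
      k <- tiek[which.min(rank[as.character(e$to[tiek])])]
      best[as.character(v)] <- mx
      succ[as.character(v)] <- e$to[k]
    }
    list(best = best, succ = succ)
  }

  trace_back <- function(pred, v) {
    path <- unname(v)
    while (path[1] != G$s) {
      p <- pred[[as.character(path[1])]]
      if (is.na(p)) return(NULL)
      path <- c(p, path)
    }
    unname(path)
  }
  trace_fwd <- function(succ, v) {
    path <- unname(v)
    while (path[length(path)] != G$t) {
      nxt <- succ[[as.character(path[length(path)])]]
      if (is.na(nxt)) return(NULL)
      path <- c(path, nxt)
    }
    unname(path)
  }

  fwd <- dp_forward()
  if (is.null(chain)) {
    bn <- fwd$best[as.character(G$t)]
    if (!is.finite(bn)) return(NULL)
    full <- trace_back(fwd$pred, G$t)
    if (is.null(full)) return(NULL)
    return(list(path = full[full != G$s & full != G$t], bottleneck = bn))
  }
  bwd <- dp_backward()
  pre <- fwd$best[as.character(chain[1])]
  suf <- bwd$best[as.character(chain[length(chain)])]
  cbn <- Inf
  if (length(chain) > 1) {
    ck <- edge_key(chain[-length(chain)], chain[-1])
    cw <- res[ck]
    if (any(is.na(cw))) return(NULL)  # chain edge absent from graph
    if (require_positive && any(cw <= 0)) return(NULL)
    cbn <- min(cw)
  }
  bn <- min(pre, cbn, suf)
  if (!is.finite(bn)) return(NULL)
  prefix <- trace_back(fwd$pred, chain[1])
  suffix <- trace_fwd(bwd$succ, chain[length(chain)])
  if (is.null(prefix) || is.null(suffix)) return(NULL)
  full <- c(prefix[-length(prefix)], chain, suffix[-1])
  list(path = full[full != G$s & full != G$t], bottleneck = bn)
}

subtract_path <- function(G, res, path, amount) {
  full <- c(G$s, path, G$t)
  keys <- edge_key(full[-length(full)], full[-1])
  res[keys] <- res[keys] - amount
  res
}

is_subchain <- function(chain, path) {
  n <- length(chain); m <- length(path)
  if (n > m) return(FALSE)
  if (n == 0) return(TRUE)
  starts <- which(path == chain[1])
  for (s0 in starts) {
    if (s0 + n - 1 <= m && all(path[s0:(s0 + n - 1)] == chain)) return(TRUE)
  }
  FALSE
}

#' Decompose a pruned splice graph into candidate transcripts
#'
#' Greedy phase-preserving peeling: phasing paths (vertex chains
#' co-observed within single fragments) are visited in decreasing
#' multiplicity, and for each unsatisfied chain the s-t path through it
#' with maximum residual bottleneck is peeled off (abundance = bottleneck).
#' Remaining residual flow is then peeled along unconstrained widest paths
#' until no strictly positive s-t path is left. Every phasing path with
#' multiplicity at or above `phasing_min_support` ends up contained in at
#' least one returned path.
#'
#' @param G A pruned `splice_graph`.
#' @param phasing Phasing paths from [extract_phasing_paths()].
#' @param params [assembly_params()].
#' @return A `data.frame` with list-column `path` (vertex ids) and
#'   `abundance`; empty (with a warning) when the graph has no s-t path.
#' @export
decompose_graph <- function(G, phasing = NULL, params = assembly_params()) {
  empty <- data.frame(abundance = numeric(0))
  empty$path <- list()
  if (!nrow(G$vertices)) return(empty)
  res <- residual_vector(G)
  if (is.null(widest_path(G, res))) {
    warning("splice graph has no s-t path; nothing to decompose")
    return(empty)
  }

  out_paths <- list(); out_ab <- numeric(0)
  emit <- function(path, ab) {
    out_paths[[length(out_paths) + 1L]] <<- path
    out_ab[length(out_ab) + 1L] <<- ab
  }

  if (!is.null(phasing) && nrow(phasing)) {
    use <- phasing[phasing$multiplicity >= params$phasing_min_support, ,
                   drop = FALSE]
    if (nrow(use)) {
      first_start <- vapply(use$path, function(p)
        G$vertices$start[match(p[1], G$vertices$id)], integer(1))
      chainstr <- vapply(use$path, paste, character(1), collapse = ",")
      ouse <- order(-use$multiplicity, first_start, chainstr)
      for (i in ouse) {
        chain <- use$path[[i]]
        if (any(vapply(out_paths, function(p) is_subchain(chain, p),
                       logical(1)))) next
        wp <- widest_path(G, res, chain = chain)
        if (!is.null(wp) && wp$bottleneck > 0) {
          emit(wp$path, wp$bottleneck)
          res <- subtract_path(G, res, wp$path, wp$bottleneck)
        } else {
          # The chain is read-supported but earlier peels exhausted a
          # shared edge (read coverage is not flow-conserved: UMI reads
          # pile onto the 5' end). Route through the least-starved path
          # and let the chain's own edges set the abundance.
          wp0 <- widest_path(G, res, chain = chain,
                             require_positive = FALSE)
          if (!is.null(wp0)) {
            ab <- 0
            if (length(chain) > 1) {
              cw <- res[edge_key(chain[-length(chain)], chain[-1])]
              ab <- max(min(cw), 0)
            }
            emit(wp0$path, ab)
            if (ab > 0) res <- subtract_path(G, res, wp0$path, ab)
          }
        }
      }
    }
  }

  repeat {
    wp <- widest_path(G, res)
    if (is.null(wp) || wp$bottleneck <= 0) break
    emit(wp$path, wp$bottleneck)
    res <- subtract_path(G, res, wp$path, wp$bottleneck)
  }

  if (!length(out_paths)) return(empty)
  key <- vapply(out_paths, paste, character(1), collapse = ",")
  agg <- tapply(out_ab, key, sum)
  first <- !duplicated(key)
  paths <- out_paths[first]
  keys <- key[first]
  ab <- as.numeric(agg[keys])
  starts <- vapply(paths, function(p)
    G$vertices$start[match(p[1], G$vertices$id)], integer(1))
  o <- order(starts, keys)
  res_df <- data.frame(abundance = ab[o])
  res_df$path <- paths[o]
  res_df
}

#' Anchor candidate transcripts at UMI-supported first exons
#'
#' UMIs sit at the 5' end of the RNA, so UMI reads mark transcript start
#' sites. A candidate survives only when the UMI support of its 5'-terminal
#' exon (first path vertex on `+`, last on `-`; support is the maximum
#' `w_m` over the vertices merged into that exon) reaches
#' `first_exon_min_umi`. Candidates failing the filter are likely intronic
#' or intergenic contamination from internal reads.
#'
#' @param candidates Decomposition result from [decompose_graph()].
#' @param G The `splice_graph` (provides `w_m`).
#' @param params [assembly_params()].
#' @param strand Transcript strand; defaults to the graph's.
#' @return The filtered candidate `data.frame`.
#' @export
anchor_first_exon <- function(candidates, G, params = assembly_params(),
                              strand = G$strand) {
  if (!nrow(candidates)) return(candidates)
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    pe <- path_to_exons(G, candidates$path[[i]])
    run <- if (strand == "-") pe$runs[[length(pe$runs)]] else pe$runs[[1]]
    wm <- max(G$vertices$wm[match(run, G$vertices$id)])
    wm >= params$first_exon_min_umi
  }, logical(1))
  candidates[keep, , drop = FALSE]
}

assemble_locus <- function(locus, ir = ir_params(),
                           asm = assembly_params()) {
  G <- build_graph(locus)
  G <- prune_graph(G, ir)
  if (!nrow(G$vertices)) return(new_transcripts())
  phasing <- extract_phasing_paths(locus, G)
  cands <- suppressWarnings(decompose_graph(G, phasing, asm))
  cands <- anchor_first_exon(cands, G, asm)
  if (!nrow(cands)) return(new_transcripts())
  exons <- lapply(cands$path, function(p) path_to_exons(G, p)$exons)
  tx <- new_transcripts(chrom = locus$chrom, strand = locus$strand,
                        exons = exons, coverage = cands$abundance,
                        cell_id = NA_character_, source = "single_cell",
                        gene_id = NA_character_,
                        transcript_id = NA_character_)
  if (asm$min_transcript_coverage > 0) {
    tx <- tx[tx$coverage >= asm$min_transcript_coverage, , drop = FALSE]
  }
  if (asm$min_transcript_length > 0) {
    len <- vapply(tx$exons, function(e) sum(e[, 2] - e[, 1]), integer(1))
    tx <- tx[len >= asm$min_transcript_length, , drop = FALSE]
  }
  tx
}

#' Assemble one cell's alignments into transcripts
#'
#' Runs the full pipeline: load, deduplicate, cluster into loci, rescue
#' strand of junction-free internal fragments, purge contaminated loci,
#' then per locus build the splice graph, prune intron retentions, extract
#' phasing paths, decompose, anchor first exons, and apply coverage and
#' length floors. Deterministic for fixed input and parameters.
#'
#' @param input Path to a BAM/SAM file, or a fragment `data.frame`.
#' @param cell_id Cell label recorded on transcripts; defaults to the
#'   fragments' cell barcode when unique.
#' @param locus_params,ir,asm Parameter bundles.
#' @param min_mapq,genome Passed to [load_fragments()] for file input.
#' @param dedup Collapse PCR duplicates (disable when the input fragments
#'   were already deduplicated per cell, e.g. inside the meta-assembler).
#' @return Transcript `data.frame` sorted by coordinate, with the list of
#'   purged loci in `attr(, "purged")`.
#' @export
assemble_cell <- function(input, cell_id = NULL,
                          locus_params = locus_filter_params(),
                          ir = ir_params(), asm = assembly_params(),
                          min_mapq = 1, genome = NULL, dedup = TRUE) {
  frags <- if (is.character(input)) {
    load_fragments(input, min_mapq = min_mapq, genome = genome)
  } else input
  if (is.null(cell_id)) {
    cc <- unique(stats::na.omit(frags$cell_id))
    cell_id <- if (length(cc) == 1) cc else "cell"
  }
  if (dedup) frags <- dedup_fragments(frags)
  frags <- sort_fragments(frags)

  loci <- cluster_loci(frags, locus_params)
  unknown <- frags[frags$strand == "*", , drop = FALSE]
  rs <- resolve_internal_strand(unknown, loci, locus_params$nearby_window)
  fl <- filter_contaminant_loci(rs$loci, locus_params)

  parts <- lapply(fl$kept, assemble_locus, ir = ir, asm = asm)
  tx <- if (length(parts)) do.call(rbind, parts) else new_transcripts()
  tx <- sort_transcripts(tx)
  if (nrow(tx)) {
    tx$cell_id <- cell_id
    tx <- assign_gene_ids(tx, cell_id)
  }
  attr(tx, "purged") <- fl$purged
  tx
}

# gene ids group transcripts by overlapping span on the same chrom/strand
assign_gene_ids <- function(tx, prefix) {
  if (!nrow(tx)) return(tx)
  starts <- tx_start(tx); ends <- tx_end(tx)
  gid <- integer(nrow(tx)); cur <- 0L
  last_end <- -1L; last_chrom <- ""; last_strand <- ""
  o <- order(tx$chrom, tx$strand, starts, ends)
  for (i in o) {
    if (tx$chrom[i] != last_chrom || tx$strand[i] != last_strand ||
        starts[i] >= last_end) {
      cur <- cur + 1L
      last_end <- ends[i]
    } else {
      last_end <- max(last_end, ends[i])
    }
    last_chrom <- tx$chrom[i]; last_strand <- tx$strand[i]
    gid[i] <- cur
  }
  tx$gene_id <- sprintf("%s.g%04d", prefix, gid)
  cnt <- stats::ave(seq_len(nrow(tx)), tx$gene_id, FUN = seq_along)
  tx$transcript_id <- sprintf("%s.t%d", tx$gene_id, cnt)
  tx
}
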