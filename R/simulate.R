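# Deterministic synthetic-data generator emulating Smart-seq3-style
# single-cell alignments: UMI fragments carry UB tags, start near the
# transcript 5' end (geometric offset decay) and are predominantly
# FR-oriented; internal fragments tile the gene body near-uniformly with
# ~50/50 orientation and can be contaminated with intronic/intergenic
# placements, full/partial intron-retention read-throughs, and exact PCR
# duplicates. Outputs are plain-text SAM plus genome FASTA, truth GTF and a
# per-fragment truth TSV.

#' Simulation configuration
#'
#' @param seed Integer seed fixing the full output byte stream.
#' @param n_loci Number of gene loci.
#' @param exons_per_transcript Integer range `c(lo, hi)` of backbone exon
#'   counts (loci with >1 transcript use at least 3).
#' @param transcripts_per_locus Integer range `c(lo, hi)`. Multi-transcript
#'   loci differ in exactly one alternative-splicing event (skipped or
#'   mutually exclusive exon), so each transcript owns at least one unique
#'   junction and junction phasing identifies it.
#' @param umi_fraction Target fraction of fragments that are UMI-linked
#'   (default 0.25).
#' @param umi_5prime_bias Geometric decay rate of the UMI fragment start
#'   offset from the transcript 5' end (default 0.02, mean ~50 bp).
#' @param umi_fr_fraction Fraction of UMI fragments in FR orientation
#'   (default 0.85).
#' @param internal_fr_fraction Same for internal fragments (default 0.5).
#' @param intronic_contamination_rate Contaminant internal fragments added
#'   per locus, as a fraction of its clean internal fragments (default 0.05).
#' @param full_ir_injection_rate,partial_ir_injection_rate Per-locus
#'   probability of injecting internal-read fragments that fully
#'   (respectively partially) cover one intron with read-through into the
#'   flanking exon(s) (defaults 0).
#' @param pcr_duplicate_rate Per-fragment probability of one exact PCR copy
#'   (default 0.1).
#' @param read_length Read length in bp (default 150).
#' @param fragment_length `c(mean, sd, min, max)` of fragment lengths; the
#'   maximum never exceeds twice the read length so mate pairs cover their
#'   fragment without internal gaps (default `c(260, 25, 190, 300)`).
#' @param n_cells Number of cells (default 1). Gene models are shared;
#'   reads are drawn independently per cell.
#' @param internal_stride Spacing in bp of stratified internal-fragment
#'   start positions along the transcript; small enough values guarantee
#'   gap-free exon coverage (default 60).
#' @param min_junction_frags Junction observability floor: extra internal
#'   fragments are centred on any junction seen by fewer fragments
#'   (default 5).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_loci = 20,
                       exons_per_transcript = c(1, 6),
                       transcripts_per_locus = c(1, 3),
                       umi_fraction = 0.25, umi_5prime_bias = 0.02,
                       umi_fr_fraction = 0.85, internal_fr_fraction = 0.5,
                       intronic_contamination_rate = 0.05,
                       full_ir_injection_rate = 0,
                       partial_ir_injection_rate = 0,
                       pcr_duplicate_rate = 0.1,
                       read_length = 150,
                       fragment_length = c(260, 25, 190, 300),
                       n_cells = 1, internal_stride = 60,
                       min_junction_frags = 5) {
  fracs <- c(umi_fraction, umi_fr_fraction, internal_fr_fraction,
             intronic_contamination_rate, full_ir_injection_rate,
             partial_ir_injection_rate, pcr_duplicate_rate)
  stopifnot(all(fracs >= 0 & fracs <= 1), length(fragment_length) == 4,
            fragment_length[4] <= 2 * read_length,
            exons_per_transcript[1] >= 1, transcripts_per_locus[1] >= 1)
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 exons_per_transcript = as.integer(exons_per_transcript),
                 transcripts_per_locus = as.integer(transcripts_per_locus),
                 umi_fraction = umi_fraction,
                 umi_5prime_bias = umi_5prime_bias,
                 umi_fr_fraction = umi_fr_fraction,
                 internal_fr_fraction = internal_fr_fraction,
                 intronic_contamination_rate = intronic_contamination_rate,
                 full_ir_injection_rate = full_ir_injection_rate,
                 partial_ir_injection_rate = partial_ir_injection_rate,
                 pcr_duplicate_rate = pcr_duplicate_rate,
                 read_length = as.integer(read_length),
                 fragment_length = fragment_length,
                 n_cells = as.integer(n_cells),
                 internal_stride = as.integer(internal_stride),
                 min_junction_frags = as.integer(min_junction_frags)),
            class = "sim_config")
}

rsample <- function(rng) if (rng[1] == rng[2]) rng[1] else
  sample(rng[1]:rng[2], 1)

rand_umi <- function(n = 8) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

draw_fraglen <- function(cfg, tx_len) {
  fl <- cfg$fragment_length
  L <- round(stats::rnorm(1, fl[1], fl[2]))
  min(max(L, fl[3]), fl[4], tx_len)
}

# transcript-space interval -> genomic blocks (ascending)
map_tx_to_genome <- function(exons, strand, s, e) {
  widths <- exons[, 2] - exons[, 1]
  txlen <- sum(widths)
  stopifnot(s >= 0, e <= txlen, e > s)
  if (strand == "-") {
    tmp <- txlen - e; e <- txlen - s; s <- tmp
  }
  cum <- c(0L, cumsum(widths))
  out <- NULL
  for (i in seq_len(nrow(exons))) {
    os <- max(s, cum[i]); oe <- min(e, cum[i + 1])
    if (oe > os) {
      out <- rbind(out, c(exons[i, 1] + (os - cum[i]),
                          exons[i, 1] + (oe - cum[i])))
    }
  }
  colnames(out) <- c("start", "end")
  out
}

make_gene_models <- function(cfg) {
  genes <- list()
  cursor <- 2000L
  for (g in seq_len(cfg$n_loci)) {
    strand <- sample(c("+", "-"), 1)
    n_tx <- rsample(cfg$transcripts_per_locus)
    m <- rsample(cfg$exons_per_transcript)
    if (n_tx > 1) m <- max(m, 3L)
    slot <- if (n_tx > 1) rsample(c(2L, m - 1L)) else NA_integer_
    elens <- sample(160:320, m, replace = TRUE)
    ilens <- sample(320:520, max(m - 1, 0), replace = TRUE)
    alt_len <- NA_integer_
    if (!is.na(slot) && n_tx == 3) {
      # mutually exclusive exon lives inside the intron after the slot exon
      alt_len <- sample(160:240, 1)
      ilens[slot] <- alt_len + 2L * sample(100:160, 1)
    }
    starts <- integer(m)
    starts[1] <- cursor
    for (i in seq_len(m - 1)) starts[i + 1] <- starts[i] + elens[i] + ilens[i]
    exons <- cbind(start = starts, end = starts + elens)
    alt_exon <- NULL
    if (!is.na(alt_len)) {
      a0 <- exons[slot, 2] + (ilens[slot] - alt_len) %/% 2L
      alt_exon <- c(a0, a0 + alt_len)
    }
    txs <- list()
    add_tx <- function(ex) {
      txs[[length(txs) + 1L]] <<- ex
    }
    add_tx(exons)
    if (n_tx >= 2) add_tx(exons[-slot, , drop = FALSE])
    if (n_tx == 3) {
      ex2 <- exons
      ex2[slot, ] <- alt_exon
      add_tx(ex2)
    }
    gene_exons <- unique(rbind(exons, if (!is.null(alt_exon))
      matrix(alt_exon, ncol = 2, dimnames = list(NULL, c("start", "end")))))
    genes[[g]] <- list(id = sprintf("gene%03d", g), chrom = "chrS",
                       strand = strand, exons = gene_exons,
                       span = c(min(exons[, 1]), max(exons[, 2])),
                       transcripts = txs)
    cursor <- max(exons[, 2]) + 2000L
  }
  genes
}

# clean fragments (tx-space) for one transcript: forced first-exon UMI
# pair, geometric-offset UMI tail, stratified internal starts with a
# junction-observability top-up
simulate_tx_fragments <- function(cfg, exons, strand) {
  widths <- exons[, 2] - exons[, 1]
  tx_len <- sum(widths)
  first_len <- if (strand == "-") widths[length(widths)] else widths[1]

  frags <- list()
  add <- function(p, L, type, fr) {
    frags[[length(frags) + 1L]] <<- list(p = as.integer(p), L = as.integer(L),
                                         type = type, fr = fr,
                                         umi = if (type == "UMI") rand_umi()
                                         else NA_character_)
  }

  # internal: stratified starts guarantee contiguous coverage of the body
  stride <- cfg$internal_stride
  n_int <- max(1L, as.integer(ceiling((tx_len - 150) / stride)))
  for (i in seq_len(n_int)) {
    L <- draw_fraglen(cfg, tx_len)
    p <- min((i - 1L) * stride + sample.int(stride, 1) - 1L, tx_len - L)
    add(p, L, "internal", stats::runif(1) < cfg$internal_fr_fraction)
  }
  L <- draw_fraglen(cfg, tx_len)
  add(tx_len - L, L, "internal", stats::runif(1) < cfg$internal_fr_fraction)

  # junction observability floor (boundaries in transcript 5'->3' space)
  if (length(widths) > 1) {
    wtx <- if (strand == "-") rev(widths) else widths
    bounds <- cumsum(wtx)[-length(wtx)]
    for (b in bounds) {
      crossing <- sum(vapply(frags, function(f)
        f$p <= b - 1L && f$p + f$L >= b + 1L, logical(1)))
      while (crossing < cfg$min_junction_frags) {
        L <- draw_fraglen(cfg, tx_len)
        p <- min(max(b - L %/% 2L, 0L), tx_len - L)
        add(p, L, "internal", stats::runif(1) < cfg$internal_fr_fraction)
        crossing <- crossing + 1L
      }
    }
  }

  # UMI: two forced FR fragments anchored in the first exon, then a
  # geometric 5'-offset tail; count set against the final internal tally so
  # the configured UMI fraction holds in expectation
  n_internal <- length(frags)
  n_umi <- max(2L, round(n_internal * cfg$umi_fraction /
                           (1 - cfg$umi_fraction)))
  L <- draw_fraglen(cfg, tx_len)
  add(0L, L, "UMI", TRUE)
  L <- draw_fraglen(cfg, tx_len)
  add(min(10L, first_len - 1L, tx_len - L), L, "UMI", TRUE)
  for (i in seq_len(n_umi - 2L)) {
    L <- draw_fraglen(cfg, tx_len)
    off <- min(stats::rgeom(1, cfg$umi_5prime_bias), max(tx_len - L, 0L))
    add(off, L, "UMI", stats::runif(1) < cfg$umi_fr_fraction)
  }
  frags
}

gene_introns <- function(gene) {
  ex <- gene$exons[order(gene$exons[, 1]), , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(ex[, 1] + 1L, ex[, 2]))
  if (length(ir) < 2) {
    return(matrix(integer(0), ncol = 2))
  }
  cbind(BiocGenerics::end(ir)[-length(ir)],
        BiocGenerics::start(ir)[-1] - 1L)
}

# genomic introns of one transcript that contain no exon of any transcript
clean_introns <- function(gene, ex) {
  if (nrow(ex) < 2) return(matrix(integer(0), ncol = 2))
  introns <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
  ok <- vapply(seq_len(nrow(introns)), function(k) {
    !any(gene$exons[, 1] < introns[k, 2] & gene$exons[, 2] > introns[k, 1])
  }, logical(1))
  introns[ok, , drop = FALSE]
}

#' Simulate a Smart-seq3-like dataset
#'
#' Generates gene models and per-cell alignments under `cfg`, writing one
#' coordinate-sorted SAM per cell plus the fabricated genome FASTA (with
#' GT..AG / CT..AC splice motifs), the ground-truth GTF, and a per-fragment
#' truth TSV. Deterministic for a fixed seed; clean fragments are generated
#' before any contamination, so datasets differing only in contamination
#' rates share the identical clean read set.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created).
#' @return List with `dir`, `sam` (named per-cell paths), `genome_fasta`,
#'   `truth_gtf`, `truth_tsv`, `genes` (model list), `truth` (transcript
#'   `data.frame`) and `fragments` (truth table).
#' @export
simulate_dataset <- function(cfg, dir = tempfile("simdata")) {
  fl <- cfg$fragment_length
  set.seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- make_gene_models(cfg)
  cells <- sprintf("cell%02d", seq_len(cfg$n_cells))

  rows <- list()   # per-fragment truth rows incl. genomic blocks
  addrow <- function(cell, gene, tx_id, type, category, umi, fr, blocks) {
    blocks <- matrix(as.integer(blocks), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
    rows[[length(rows) + 1L]] <<- list(
      cell = cell, locus = gene$id, transcript = tx_id, read_type = type,
      category = category, umi = umi, fr = fr, chrom = gene$chrom,
      strand = gene$strand, blocks = blocks)
  }

  # 1) clean fragments (incl. PCR duplicates) for every cell. Distinct
  #    molecules never share an identical alignment (that is what PCR
  #    duplicates are); on a coordinate collision the start is nudged by a
  #    few bp, keeping the fragment's junction set intact.
  bkey <- function(b) paste(b[, 1], b[, 2], sep = "-", collapse = ",")
  for (cell in cells) {
    used <- new.env(parent = emptyenv())
    for (gene in genes) {
      for (t in seq_along(gene$transcripts)) {
        ex <- gene$transcripts[[t]]
        tx_len <- sum(ex[, 2] - ex[, 1])
        tx_id <- sprintf("%s.t%d", gene$id, t)
        for (f in simulate_tx_fragments(cfg, ex, gene$strand)) {
          blocks <- map_tx_to_genome(ex, gene$strand, f$p, f$p + f$L)
          if (exists(bkey(blocks), envir = used)) {
            for (off in c(3L, -3L, 5L, -5L, 7L, -7L, 11L, -11L, 13L)) {
              p2 <- f$p + off
              if (p2 < 0L || p2 + f$L > tx_len) next
              b2 <- map_tx_to_genome(ex, gene$strand, p2, p2 + f$L)
              if (identical(blocks_to_junctions(b2),
                            blocks_to_junctions(blocks)) &&
                  !exists(bkey(b2), envir = used)) {
                blocks <- b2
                break
              }
            }
          }
          assign(bkey(blocks), TRUE, envir = used)
          addrow(cell, gene, tx_id, f$type, "clean", f$umi, f$fr, blocks)
          if (stats::runif(1) < cfg$pcr_duplicate_rate) {
            addrow(cell, gene, tx_id, f$type, "duplicate", f$umi, f$fr,
                   blocks)
          }
        }
      }
    }
  }

  # 2) contamination, drawn after all clean reads so that configs differing
  #    only in rates share the identical clean prefix
  for (cell in cells) {
    for (gene in genes) {
      n_clean_int <- sum(vapply(rows, function(r)
        r$cell == cell && r$locus == gene$id && r$read_type == "internal" &&
          r$category == "clean", logical(1)))
      introns <- gene_introns(gene)
      n_cont <- round(cfg$intronic_contamination_rate * n_clean_int)
      for (k in seq_len(n_cont)) {
        L <- draw_fraglen(cfg, .Machine$integer.max)
        fits <- which(introns[, 2] - introns[, 1] >= L + 20L)
        if (length(fits)) {
          i <- fits[sample.int(length(fits), 1)]
          g0 <- introns[i, 1] + sample.int(introns[i, 2] - introns[i, 1] -
                                             L - 19L, 1) + 9L
          cat_lab <- "intronic_contam"
        } else {
          g0 <- gene$span[2] + 150L + sample.int(100L, 1)
          cat_lab <- "intergenic_contam"
        }
        addrow(cell, gene, NA_character_, "internal", cat_lab,
               NA_character_, stats::runif(1) < 0.5,
               cbind(start = g0, end = g0 + L))
      }

      for (mode in c("full_ir", "partial_ir")) {
        rate <- if (mode == "full_ir") cfg$full_ir_injection_rate else
          cfg$partial_ir_injection_rate
        if (rate <= 0 || stats::runif(1) >= rate) next
        tsel <- sample.int(length(gene$transcripts), 1)
        cin <- clean_introns(gene, gene$transcripts[[tsel]])
        L <- fl[4]
        if (nrow(cin)) {
          cin <- cin[cin[, 2] - cin[, 1] >= L - 40L, , drop = FALSE]
        }
        if (!nrow(cin)) next
        j <- cin[sample.int(nrow(cin), 1), ]
        d <- j[1]; a <- j[2]
        if (mode == "full_ir") {
          starts <- unique(c(seq(d - 40L, a + 40L - L, by = L - 60L),
                             a + 40L - L))
          for (g0 in starts) {
            addrow(cell, gene, NA_character_, "internal", "full_ir",
                   NA_character_, stats::runif(1) < 0.5,
                   cbind(start = as.integer(g0), end = as.integer(g0 + L)))
          }
        } else {
          g0 <- a + 40L - L
          if (g0 - d >= 60L) {
            addrow(cell, gene, NA_character_, "internal", "partial_ir",
                   NA_character_, stats::runif(1) < 0.5,
                   cbind(start = g0, end = g0 + L))
          }
        }
      }
    }
  }

  genome_len <- max(vapply(genes, function(g) g$span[2], integer(1))) + 3000L
  truth <- truth_transcripts(genes)
  paths <- write_sim_outputs(cfg, dir, genes, rows, cells, genome_len,
                             truth)
  c(list(dir = dir, genes = genes, truth = truth,
         fragments = truth_fragment_table(rows)), paths)
}

truth_transcripts <- function(genes) {
  out <- new_transcripts()
  for (gene in genes) {
    for (t in seq_along(gene$transcripts)) {
      out <- rbind(out, new_transcripts(
        chrom = gene$chrom, strand = gene$strand,
        exons = list(gene$transcripts[[t]]), coverage = 0,
        cell_id = NA_character_, source = "single_cell",
        gene_id = gene$id,
        transcript_id = sprintf("%s.t%d", gene$id, t)))
    }
  }
  sort_transcripts(out)
}

truth_fragment_table <- function(rows) {
  data.frame(
    qname = vapply(seq_along(rows), function(i)
      sprintf("f%06d", i), character(1)),
    cell = vapply(rows, `[[`, character(1), "cell"),
    locus = vapply(rows, `[[`, character(1), "locus"),
    transcript = vapply(rows, `[[`, character(1), "transcript"),
    read_type = vapply(rows, `[[`, character(1), "read_type"),
    category = vapply(rows, `[[`, character(1), "category"),
    umi = vapply(rows, `[[`, character(1), "umi"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, function(r) r$blocks[1, 1], integer(1)),
    end = vapply(rows, function(r) r$blocks[nrow(r$blocks), 2], integer(1)),
    blocks = vapply(rows, function(r)
      paste(r$blocks[, 1], r$blocks[, 2], sep = "-", collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
}

blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_len(nrow(blocks))) {
    parts <- c(parts, sprintf("%dM", blocks[i, 2] - blocks[i, 1]))
    if (i < nrow(blocks)) {
      parts <- c(parts, sprintf("%dN", blocks[i + 1, 1] - blocks[i, 2]))
    }
  }
  paste(parts, collapse = "")
}

sam_records_for_fragment <- function(cfg, qname, row) {
  blocks <- row$blocks
  span <- c(blocks[1, 1], blocks[nrow(blocks), 2])
  L <- sum(blocks[, 2] - blocks[, 1])  # fragment length in aligned bases
  rl <- min(cfg$read_length, L)
  # mate intervals in fragment-aligned space (left-based on the genome)
  cut <- function(s, e) {
    out <- NULL; cum <- 0L
    for (i in seq_len(nrow(blocks))) {
      w <- blocks[i, 2] - blocks[i, 1]
      os <- max(s, cum); oe <- min(e, cum + w)
      if (oe > os) out <- rbind(out, c(blocks[i, 1] + (os - cum),
                                       blocks[i, 1] + (oe - cum)))
      cum <- cum + w
    }
    out
  }
  # mate1 carries the transcript 5' end; genomically left for +, right for -
  if ((row$strand == "+") == row$fr) {
    m1 <- cut(0L, rl); m2 <- cut(L - rl, L)
  } else {
    m1 <- cut(L - rl, L); m2 <- cut(0L, rl)
  }
  # aligned strand of mate1: transcript strand for FR, opposite for RF
  ts <- if (is.na(row$strand) || row$strand == "*") "+" else row$strand
  m1s <- if (row$fr) ts else setdiff(c("+", "-"), ts)
  m2s <- setdiff(c("+", "-"), m1s)
  flag1 <- 1L + 2L + 64L + (if (m1s == "-") 16L else 0L) +
    (if (m2s == "-") 32L else 0L)
  flag2 <- 1L + 2L + 128L + (if (m2s == "-") 16L else 0L) +
    (if (m1s == "-") 32L else 0L)
  pos1 <- m1[1, 1] + 1L; pos2 <- m2[1, 1] + 1L
  tlen <- span[2] - span[1]
  tags <- sprintf("BC:Z:%s", row$cell)
  if (!is.na(row$umi)) tags <- paste0(tags, sprintf("\tUB:Z:%s", row$umi))
  mk <- function(flag, m, pos, pnext, tl) {
    cig <- blocks_to_cigar(m)
    tg <- tags
    if (nrow(m) > 1 && row$strand %in% c("+", "-")) {
      tg <- paste0(tg, sprintf("\tXS:A:%s", row$strand))
    }
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*\t%s",
            qname, flag, row$chrom, pos, cig, pnext, tl, tg)
  }
  list(list(pos = pos1, line = mk(flag1, m1, pos1, pos2,
                                  if (pos1 <= pos2) tlen else -tlen)),
       list(pos = pos2, line = mk(flag2, m2, pos2, pos1,
                                  if (pos2 < pos1) tlen else -tlen)))
}

write_sim_outputs <- function(cfg, dir, genes, rows, cells, genome_len,
                              truth) {
  qnames <- sprintf("f%06d", seq_along(rows))
  sam_paths <- stats::setNames(file.path(dir, paste0(cells, ".sam")), cells)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:chrS\tLN:%d", genome_len))
  for (cell in cells) {
    idx <- which(vapply(rows, function(r) r$cell == cell, logical(1)))
    recs <- list()
    for (i in idx) {
      recs <- c(recs, sam_records_for_fragment(cfg, qnames[i], rows[[i]]))
    }
    pos <- vapply(recs, `[[`, numeric(1), "pos")
    lines <- vapply(recs, `[[`, character(1), "line")
    o <- order(pos, lines)
    writeLines(c(header, lines[o]), sam_paths[[cell]])
  }

  # fabricated genome with canonical splice motifs at every gene intron
  base <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  for (gene in genes) {
    ex <- gene$exons[order(gene$exons[, 1]), , drop = FALSE]
    for (t in gene$transcripts) {
      if (nrow(t) < 2) next
      introns <- cbind(t[-nrow(t), 2], t[-1, 1])
      for (k in seq_len(nrow(introns))) {
        d <- introns[k, 1]; a <- introns[k, 2]
        if (gene$strand == "+") {
          base[(d + 1):(d + 2)] <- c("G", "T")
          base[(a - 1):a] <- c("A", "G")
        } else {
          base[(d + 1):(d + 2)] <- c("C", "T")
          base[(a - 1):a] <- c("A", "C")
        }
      }
    }
  }
  fasta <- file.path(dir, "genome.fa")
  seq <- paste(base, collapse = "")
  chunks <- substring(seq, seq(1, nchar(seq), 70),
                      pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))
  writeLines(c(">chrS", chunks), fasta)

  gtf <- file.path(dir, "truth.gtf")
  write_gtf(truth, gtf)
  tsv <- file.path(dir, "truth.tsv")
  utils::write.table(truth_fragment_table(rows), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sam = sam_paths, genome_fasta = fasta, truth_gtf = gtf,
       truth_tsv = tsv)
}
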