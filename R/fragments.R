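# Fragment container: one row per sequenced molecule observation (merged
# mate pair or single read). Coordinates are 0-based half-open throughout
# the package; conversion to/from 1-based closed happens only at SAM/GTF
# boundaries.

#' Construct a fragment table
#'
#' Builds the package's internal fragment representation directly, mainly for
#' tests and the simulator. `blocks` are the aligned genomic intervals
#' (0-based half-open, sorted, non-overlapping); junctions are derived as the
#' gaps between consecutive blocks.
#'
#' @param chrom Character vector of chromosome names.
#' @param blocks List of integer matrices with columns start, end.
#' @param read_type "UMI" or "internal" per fragment; defaults from `umi`.
#' @param umi UMI sequence or `NA` (internal read).
#' @param strand "+", "-" or "*" (unknown).
#' @param strand_hint Aligner/motif transcript-strand hint ("+", "-", `NA`).
#' @param mate1_strand Aligned strand of the first mate (orientation).
#' @param cell_id Cell barcode or `NA`.
#' @param dedup_key Optional precomputed duplicate key; derived from
#'   positions/CIGAR-equivalent block structure when missing.
#' @param junctions Optional list of junction matrices (N-gap intron
#'   intervals); derived as the gaps between consecutive blocks when
#'   missing.
#' @param is_dup Logical: marked duplicate by an upstream tool.
#' @return A `data.frame` with one row per fragment and list-columns
#'   `blocks`/`junctions`.
#' @export
make_fragments <- function(chrom, blocks, umi = NA_character_,
                           strand = NULL, strand_hint = NA_character_,
                           mate1_strand = NA_character_,
                           cell_id = NA_character_,
                           read_type = NULL, dedup_key = NULL,
                           junctions = NULL, is_dup = FALSE) {
  if (is.matrix(blocks)) blocks <- list(blocks)
  n <- length(blocks)
  chrom <- rep_len(as.character(chrom), n)
  umi <- rep_len(as.character(umi), n)
  umi[!is.na(umi) & umi == ""] <- NA_character_
  if (is.null(read_type)) read_type <- ifelse(is.na(umi), "internal", "UMI")
  read_type <- rep_len(read_type, n)
  strand_hint <- rep_len(as.character(strand_hint), n)
  mate1_strand <- rep_len(as.character(mate1_strand), n)
  cell_id <- rep_len(as.character(cell_id), n)
  is_dup <- rep_len(is_dup, n)

  blocks <- lapply(blocks, function(b) {
    b <- matrix(as.integer(b), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    b <- b[order(b[, 1]), , drop = FALSE]
    stopifnot(all(b[, 2] > b[, 1]))
    if (nrow(b) > 1) stopifnot(all(b[-1, 1] >= b[-nrow(b), 2]))
    b
  })
  if (is.null(junctions)) {
    junctions <- lapply(blocks, blocks_to_junctions)
  } else {
    junctions <- lapply(junctions, function(j) {
      j <- matrix(as.integer(j), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
      j[order(j[, 1]), , drop = FALSE]
    })
  }

  if (is.null(strand)) {
    # strand resolution rule: junction hint wins; else a UMI fragment's
    # orientation (FR protocol: first mate on the transcript strand); else
    # unknown.
    strand <- ifelse(!is.na(strand_hint), strand_hint,
                     ifelse(read_type == "UMI" & !is.na(mate1_strand),
                            mate1_strand, "*"))
  } else {
    strand <- rep_len(as.character(strand), n)
  }

  start <- vapply(blocks, function(b) b[1L, 1L], integer(1))
  end <- vapply(blocks, function(b) b[nrow(b), 2L], integer(1))
  if (is.null(dedup_key)) {
    dedup_key <- vapply(seq_len(n), function(i) {
      paste0(chrom[i], ":",
             paste(blocks[[i]][, 1], blocks[[i]][, 2],
                   sep = "-", collapse = ","))
    }, character(1))
  } else {
    dedup_key <- rep_len(as.character(dedup_key), n)
  }

  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, read_type = read_type, umi = umi,
                   strand_hint = strand_hint, mate1_strand = mate1_strand,
                   cell_id = cell_id, dedup_key = dedup_key,
                   is_dup = is_dup, stringsAsFactors = FALSE)
  df$blocks <- blocks
  df$junctions <- junctions
  df
}

blocks_to_junctions <- function(b) {
  if (nrow(b) < 2) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = b[-nrow(b), 2L], end = b[-1L, 1L])
}

empty_fragments <- function() {
  df <- data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), strand = character(0),
                   read_type = character(0), umi = character(0),
                   strand_hint = character(0), mate1_strand = character(0),
                   cell_id = character(0), dedup_key = character(0),
                   is_dup = logical(0), stringsAsFactors = FALSE)
  df$blocks <- list()
  df$junctions <- list()
  df
}

sort_fragments <- function(frags) {
  frags[order(frags$chrom, frags$start, frags$end, frags$dedup_key), ,
        drop = FALSE]
}

#' Load fragments from a coordinate-sorted BAM/SAM file
#'
#' Reads alignments, drops unmapped/secondary/supplementary records and those
#' below the MAPQ floor, merges mates sharing a query name into single
#' fragments (blocks and junctions unioned), classifies each fragment as a
#' UMI read (non-empty UB tag) or an internal read, and resolves strand from
#' the aligner's transcript-strand tag (XS), splice-site motifs when a genome
#' is supplied, or — for UMI fragments — the first mate's orientation.
#'
#' @param path BAM or SAM file. SAM input is converted to sorted BAM in a
#'   temporary directory.
#' @param region Optional `GRanges` of length 1 restricting the scan
#'   (requires an index).
#' @param min_mapq Minimum mapping quality (default 1).
#' @param genome Optional `DNAStringSet`-like genome (or FASTA path) used for
#'   motif-based strand inference of spliced reads lacking an XS tag.
#' @return Fragment `data.frame` sorted by coordinate (see
#'   [make_fragments()]). Records whose CIGAR length disagrees with the
#'   stored sequence are skipped; their count is reported with a warning.
#' @export
load_fragments <- function(path, region = NULL, min_mapq = 1, genome = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- tryCatch(
      Rsamtools::asBam(path, destination = sub("\\.bam$", "", dest),
                       overwrite = TRUE, indexDestination = TRUE),
      error = function(e) stop("unreadable alignment file: ",
                               conditionMessage(e), call. = FALSE))
  } else {
    hdr <- Rsamtools::scanBamHeader(path)[[1]]$text
    so <- grep("^SO:", unlist(hdr[names(hdr) == "@HD"]), value = TRUE)
    if (length(so) && !identical(so, "SO:coordinate")) {
      stop("alignment file must be coordinate-sorted", call. = FALSE)
    }
  }

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  args <- list(flag = flags, what = c("qname", "flag", "mapq", "seq"),
               tag = c("BC", "UB", "XS"), mapqFilter = min_mapq)
  if (!is.null(region)) args$which <- region
  param <- do.call(Rsamtools::ScanBamParam, args)
  ga <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(path),
                                           param = param)
  if (length(ga) == 0) return(empty_fragments())

  md <- S4Vectors::mcols(ga)
  # CIGAR / sequence-length consistency
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(
    GenomicAlignments::cigar(ga))
  sw <- BiocGenerics::width(md$seq)
  bad <- !is.na(sw) & sw > 0 & sw != qw
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: CIGAR and sequence length disagree")
    ga <- ga[!bad]
    md <- S4Vectors::mcols(ga)
  }
  if (length(ga) == 0) return(empty_fragments())

  grl <- GenomicAlignments::grglist(ga)  # aligned blocks, split at N
  chrom <- as.character(GenomeInfoDb::seqnames(ga))
  strand_aln <- as.character(BiocGenerics::strand(ga))
  flag <- md$flag
  first_mate <- bitwAnd(flag, 64L) > 0L | bitwAnd(flag, 1L) == 0L
  dupflag <- bitwAnd(flag, 1024L) > 0L
  ub <- if ("UB" %in% names(md)) as.character(md$UB) else
    rep(NA_character_, length(ga))
  bc <- if ("BC" %in% names(md)) as.character(md$BC) else
    rep(NA_character_, length(ga))
  xs <- if ("XS" %in% names(md)) as.character(md$XS) else
    rep(NA_character_, length(ga))
  ub[!is.na(ub) & ub == ""] <- NA_character_
  cig <- GenomicAlignments::cigar(ga)
  pos <- BiocGenerics::start(ga)

  blk <- lapply(seq_along(ga), function(i) {
    r <- grl[[i]]
    cbind(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
  })
  jnc <- GenomicAlignments::junctions(ga)
  jnc <- lapply(seq_along(ga), function(i) {
    r <- jnc[[i]]
    cbind(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
  })

  key <- split(seq_along(ga), md$qname)
  rows <- lapply(key, function(idx) {
    idx <- idx[order(pos[idx])]
    b <- do.call(rbind, blk[idx])
    ir <- IRanges::reduce(IRanges::IRanges(b[, 1] + 1L, b[, 2]))
    bm <- cbind(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
    hint <- stats::na.omit(unique(xs[idx]))
    hint <- if (length(hint) == 1) hint else NA_character_
    m1 <- idx[first_mate[idx]]
    m1s <- if (length(m1)) strand_aln[m1[1]] else strand_aln[idx[1]]
    u <- stats::na.omit(unique(ub[idx]))
    jm <- unique(do.call(rbind, jnc[idx]))
    list(chrom = chrom[idx[1]],
         blocks = bm,
         junctions = jm,
         umi = if (length(u)) u[1] else NA_character_,
         hint = hint,
         m1s = m1s,
         cell = { cc <- stats::na.omit(unique(bc[idx]))
                  if (length(cc)) cc[1] else NA_character_ },
         key = paste0(chrom[idx[1]], ":",
                      paste(pos[idx], cig[idx], sep = ":", collapse = "|")),
         dup = any(dupflag[idx]))
  })

  frags <- make_fragments(
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    blocks = lapply(rows, `[[`, "blocks"),
    umi = vapply(rows, `[[`, character(1), "umi"),
    strand_hint = vapply(rows, `[[`, character(1), "hint"),
    mate1_strand = vapply(rows, `[[`, character(1), "m1s"),
    cell_id = vapply(rows, `[[`, character(1), "cell"),
    dedup_key = vapply(rows, `[[`, character(1), "key"),
    junctions = lapply(rows, `[[`, "junctions"),
    is_dup = vapply(rows, `[[`, logical(1), "dup"))

  if (!is.null(genome)) frags <- infer_motif_strand(frags, genome)
  sort_fragments(frags)
}

# Splice-site dinucleotide strand inference (GT..AG forward, CT..AC reverse)
# for spliced fragments whose aligner left no transcript-strand tag.
infer_motif_strand <- function(frags, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  need <- which(is.na(frags$strand_hint) &
                  vapply(frags$junctions, nrow, integer(1)) > 0)
  for (i in need) {
    j <- frags$junctions[[i]]
    seqs <- genome[[frags$chrom[i]]]
    votes <- apply(j, 1, function(jj) {
      donor <- as.character(Biostrings::subseq(seqs, jj[1] + 1, jj[1] + 2))
      accep <- as.character(Biostrings::subseq(seqs, jj[2] - 1, jj[2]))
      if (donor == "GT" && accep == "AG") "+"
      else if (donor == "CT" && accep == "AC") "-"
      else NA_character_
    })
    votes <- stats::na.omit(unique(votes))
    if (length(votes) == 1) {
      frags$strand_hint[i] <- votes
      frags$strand[i] <- votes
    }
  }
  frags
}

#' Remove PCR duplicates from one cell's fragments
#'
#' Two fragments are duplicates when their alignments are identical —
#' same chromosome, mate positions and CIGAR-equivalent block structure
#' (captured in `dedup_key`). The first fragment in coordinate order
#' survives. Fragments flagged as duplicates by an upstream tool are also
#' dropped.
#'
#' @param frags Fragment `data.frame` from one cell.
#' @return Deduplicated fragment `data.frame` in coordinate order.
#' @export
dedup_fragments <- function(frags) {
  if (nrow(frags) == 0) return(frags)
  frags <- frags[!frags$is_dup, , drop = FALSE]
  frags <- sort_fragments(frags)
  frags[!duplicated(frags$dedup_key), , drop = FALSE]
}

#' Tally read types and strand orientations
#'
#' Counts UMI and internal fragments and, within each type, how many are
#' FR-oriented (first mate on the inferred transcript strand), RF-oriented,
#' or of unknown orientation (no transcript-strand evidence).
#'
#' @param frags Fragment `data.frame`.
#' @return A `read_type_stats` list with `n_umi`, `n_internal` and per-type
#'   `fr`, `rf`, `unknown` counts.
#' @export
summarize_read_types <- function(frags) {
  tally <- function(sub) {
    known <- !is.na(sub$strand_hint) & !is.na(sub$mate1_strand)
    fr <- sum(known & sub$mate1_strand == sub$strand_hint)
    rf <- sum(known & sub$mate1_strand != sub$strand_hint)
    c(fr = fr, rf = rf, unknown = nrow(sub) - fr - rf)
  }
  u <- frags[frags$read_type == "UMI", , drop = FALSE]
  i <- frags[frags$read_type == "internal", , drop = FALSE]
  structure(list(n_umi = nrow(u), n_internal = nrow(i),
                 umi = tally(u), internal = tally(i)),
            class = "read_type_stats")
}

#' @export
print.read_type_stats <- function(x, ...) {
  n <- x$n_umi + x$n_internal
  cat(sprintf("fragments: %d (UMI %d, internal %d)\n", n, x$n_umi,
              x$n_internal))
  if (n > 0) {
    cat(sprintf("  UMI      FR/RF/unknown: %d/%d/%d\n",
                x$umi["fr"], x$umi["rf"], x$umi["unknown"]))
    cat(sprintf("  internal FR/RF/unknown: %d/%d/%d\n",
                x$internal["fr"], x$internal["rf"], x$internal["unknown"]))
  }
  invisible(x)
}
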