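# Meta-assembly: pool all cells into a "super-cell", assemble it, assign
# pooled transcripts back to individual cells by exon support, and union
# with each cell's single-cell assembly.

load_cell_inputs <- function(inputs, min_mapq = 1, genome = NULL) {
  if (is.data.frame(inputs)) inputs <- list(cell1 = inputs)
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    names(inputs) <- if (is.character(unlist(inputs[1]))) {
      vapply(inputs, function(p)
        sub("\\.(bam|sam)$", "", basename(p), ignore.case = TRUE),
        character(1))
    } else paste0("cell", seq_along(inputs))
  }
  lapply(stats::setNames(names(inputs), names(inputs)), function(nm) {
    x <- inputs[[nm]]
    fr <- if (is.character(x)) {
      load_fragments(x, min_mapq = min_mapq, genome = genome)
    } else x
    fr <- dedup_fragments(fr)  # duplicates collapse within, never across cells
    fr$cell_id <- nm
    fr
  })
}

#' Pool all cells and assemble the super-cell
#'
#' Fragments of every cell are deduplicated per cell (never across cells),
#' labelled with their cell of origin, pooled into one multiset and
#' assembled with the single-cell pipeline. The result is independent of
#' cell input order.
#'
#' @param inputs Named list of BAM/SAM paths or fragment `data.frame`s, one
#'   per cell.
#' @param locus_params,ir,asm Parameter bundles.
#' @param min_mapq,genome Passed to [load_fragments()].
#' @return List with `super` (transcripts of the pooled assembly, `source ==
#'   "meta_assigned"` candidates) and `cell_fragments` (named list of each
#'   cell's deduplicated fragments).
#' @export
meta_assemble <- function(inputs, locus_params = locus_filter_params(),
                          ir = ir_params(), asm = assembly_params(),
                          min_mapq = 1, genome = NULL) {
  cells <- load_cell_inputs(inputs, min_mapq, genome)
  cells <- cells[order(names(cells))]
  pooled <- sort_fragments(do.call(rbind, cells))
  super <- assemble_cell(pooled, cell_id = "super",
                         locus_params = locus_params, ir = ir, asm = asm,
                         dedup = FALSE)
  list(super = super, cell_fragments = cells)
}

#' Does a cell support a pooled transcript?
#'
#' A super-cell transcript is assigned to a cell when a substantial fraction
#' of its exons — at least `frac` (default 30%) — are supported by that
#' cell. With `mode = "count"` (default) an exon counts as supported when
#' any of the cell's fragments overlaps it by at least one aligned base;
#' `mode = "bases"` measures the covered fraction of exonic bases instead.
#'
#' @param tx One-row transcript `data.frame` (or a row index into one).
#' @param cell_frags The cell's fragment `data.frame`.
#' @param frac Minimum supported fraction (default 0.30).
#' @param mode `"count"` (supported exons / exons) or `"bases"`
#'   (covered exonic bases / exonic bases).
#' @return `TRUE` when the transcript is assigned to the cell.
#' @export
assign_transcript_to_cell <- function(tx, cell_frags, frac = 0.30,
                                      mode = c("count", "bases")) {
  mode <- match.arg(mode)
  exons <- tx$exons[[1]]
  sub <- cell_frags[cell_frags$chrom == tx$chrom, , drop = FALSE]
  if (mode == "count") {
    supported <- 0L
    for (k in seq_len(nrow(exons))) {
      hit <- FALSE
      for (b in sub$blocks) {
        if (any(b[, 1] < exons[k, 2] & b[, 2] > exons[k, 1])) {
          hit <- TRUE
          break
        }
      }
      supported <- supported + hit
    }
    return(supported / nrow(exons) >= frac)
  }
  er <- IRanges::IRanges(exons[, 1] + 1L, exons[, 2])
  if (!nrow(sub)) return(FALSE)
  ab <- do.call(rbind, sub$blocks)
  br <- IRanges::reduce(IRanges::IRanges(ab[, 1] + 1L, ab[, 2]))
  covered <- sum(BiocGenerics::width(IRanges::intersect(er, br)))
  covered / sum(BiocGenerics::width(er)) >= frac
}

#' Union keys of transcripts
#'
#' Multi-exon transcripts are keyed by (chrom, strand, intron chain);
#' single-exon transcripts by (chrom, strand, exon interval). This is the
#' identity under which single-cell and meta-assigned transcripts are
#' unioned.
#'
#' @param tx Transcript `data.frame`.
#' @return Character vector of keys.
#' @export
transcript_union_key <- function(tx) {
  vapply(seq_len(nrow(tx)), function(i) {
    e <- tx$exons[[i]]
    if (nrow(e) > 1) {
      j <- cbind(e[-nrow(e), 2], e[-1, 1])
      paste0(tx$chrom[i], tx$strand[i], "|J|",
             paste(j[, 1], j[, 2], sep = "-", collapse = ","))
    } else {
      paste0(tx$chrom[i], tx$strand[i], "|S|", e[1, 1], "-", e[1, 2])
    }
  }, character(1))
}

#' Union a cell's single-cell and meta-assigned transcripts
#'
#' Multi-exon transcripts are keyed by (chrom, strand, intron chain) and
#' single-exon transcripts by (chrom, strand, exon interval); on a key
#' collision the single-cell record (and its coverage) is kept.
#'
#' @param single_cell Transcripts from [assemble_cell()] for the cell.
#' @param assigned Super-cell transcripts assigned to the cell.
#' @return Combined transcript `data.frame` sorted by coordinate.
#' @export
union_transcripts <- function(single_cell, assigned) {
  if (!nrow(single_cell) && !nrow(assigned)) return(single_cell)
  sc_keys <- transcript_union_key(single_cell)
  as_keys <- transcript_union_key(assigned)
  extra <- assigned[!(as_keys %in% sc_keys), , drop = FALSE]
  if (nrow(extra)) extra$source <- "meta_assigned"
  if (nrow(single_cell)) single_cell$source <- "single_cell"
  sort_transcripts(rbind(single_cell, extra))
}

#' Run the full meta-assembly for every cell
#'
#' Assembles the pooled super-cell, assembles each cell individually,
#' assigns super-cell transcripts back to cells by exon support, and unions
#' per cell.
#'
#' @inheritParams meta_assemble
#' @param frac Minimum supported-exon fraction for assignment (default 0.30).
#' @return List with `super` (pooled transcripts) and `cells` (named list of
#'   per-cell unioned transcript `data.frame`s).
#' @export
meta_assemble_cells <- function(inputs, frac = 0.30,
                                locus_params = locus_filter_params(),
                                ir = ir_params(), asm = assembly_params(),
                                min_mapq = 1, genome = NULL) {
  meta <- meta_assemble(inputs, locus_params, ir, asm, min_mapq, genome)
  super <- meta$super
  cells <- lapply(stats::setNames(names(meta$cell_fragments),
                                  names(meta$cell_fragments)),
                  function(nm) {
    frags <- meta$cell_fragments[[nm]]
    sc <- assemble_cell(frags, cell_id = nm, locus_params = locus_params,
                        ir = ir, asm = asm, dedup = FALSE)
    keep <- vapply(seq_len(nrow(super)), function(i)
      assign_transcript_to_cell(super[i, , drop = FALSE], frags, frac),
      logical(1))
    assigned <- super[keep, , drop = FALSE]
    if (nrow(assigned)) assigned$cell_id <- nm
    union_transcripts(sc, assigned)
  })
  list(super = super, cells = cells)
}
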