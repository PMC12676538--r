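# GTF reading/writing. Internal coordinates are 0-based half-open and are
# converted to the 1-based closed GTF convention here and only here.
# The attribute dialect is gffcompare-compatible: transcript_id first,
# then gene_id.

#' Write transcripts as GTF
#'
#' Emits one `transcript` line and its `exon` lines per transcript with
#' 1-based closed coordinates and a stable attribute order
#' (`transcript_id`, `gene_id`, `cov`, `cell_id`), so output is
#' byte-deterministic for a fixed input.
#'
#' @param tx Transcript `data.frame`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(tx, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write GTF to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines("##format: gtf", con)
  src <- "umisplice"
  for (i in seq_len(nrow(tx))) {
    e <- tx$exons[[i]]
    attrs <- sprintf('transcript_id "%s"; gene_id "%s"; cov "%.4f";',
                     tx$transcript_id[i], tx$gene_id[i], tx$coverage[i])
    if (!is.na(tx$cell_id[i])) {
      attrs <- paste0(attrs, sprintf(' cell_id "%s";', tx$cell_id[i]))
    }
    writeLines(sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom[i], src, e[1, 1] + 1L, e[nrow(e), 2],
                       tx$strand[i], attrs), con)
    for (k in seq_len(nrow(e))) {
      writeLines(sprintf(
        "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        tx$chrom[i], src, e[k, 1] + 1L, e[k, 2], tx$strand[i], attrs, k),
        con)
    }
  }
  invisible(path)
}

#' Read transcripts from GTF
#'
#' Parses exon features grouped by `transcript_id`, sorts exons within each
#' transcript, and converts to the package's 0-based half-open coordinates.
#' Records lacking optional attributes are tolerated; an exon without a
#' `transcript_id` is a record-level error.
#'
#' @param path GTF file.
#' @return Transcript `data.frame` (see [assemble_cell()] for the layout).
#' @export
read_gtf <- function(path) {
  if (!any(!startsWith(readLines(path), "#"))) return(new_transcripts())
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (!length(gr)) return(new_transcripts())
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  if (any(is.na(tid))) {
    stop("exon record(s) without transcript_id at index ",
         paste(which(is.na(tid)), collapse = ", "), call. = FALSE)
  }
  gid <- if ("gene_id" %in% names(md)) as.character(md$gene_id) else tid
  cov <- if ("cov" %in% names(md)) {
    suppressWarnings(as.numeric(as.character(md$cov)))
  } else rep(NA_real_, length(gr))
  cell <- if ("cell_id" %in% names(md)) as.character(md$cell_id) else
    rep(NA_character_, length(gr))
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  st <- BiocGenerics::start(gr) - 1L
  en <- BiocGenerics::end(gr)

  idx <- split(seq_along(gr), tid)
  ord <- names(idx)
  exons <- lapply(idx, function(ii) {
    ii <- ii[order(st[ii])]
    cbind(start = st[ii], end = en[ii])
  })
  tx <- new_transcripts(
    chrom = vapply(idx, function(ii) chrom[ii[1]], character(1)),
    strand = vapply(idx, function(ii) strand[ii[1]], character(1)),
    exons = exons,
    coverage = vapply(idx, function(ii) cov[ii[1]], numeric(1)),
    cell_id = vapply(idx, function(ii) cell[ii[1]], character(1)),
    source = "single_cell",
    gene_id = vapply(idx, function(ii) gid[ii[1]], character(1)),
    transcript_id = ord)
  sort_transcripts(tx)
}
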