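# Gene loci: strand-resolved clusters of fragments, the unit of splice-graph
# construction.

new_locus <- function(chrom, strand, start, end, fragments) {
  structure(list(chrom = chrom, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 fragments = fragments,
                 umi_count = sum(fragments$read_type == "UMI"),
                 internal_count = sum(fragments$read_type == "internal")),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus %s:%d-%d(%s) UMI=%d internal=%d>\n", x$chrom, x$start,
              x$end, x$strand, x$umi_count, x$internal_count))
  invisible(x)
}

#' Cluster strand-determined fragments into gene loci
#'
#' Fragments whose strand is known are partitioned, per chromosome and
#' strand, into maximal chains in which consecutive spans overlap or lie
#' within `cluster_gap` bp of each other. Strand-unknown fragments are
#' ignored here; see [resolve_internal_strand()].
#'
#' @param frags Fragment `data.frame` sorted by chromosome and start.
#' @param params [locus_filter_params()].
#' @return List of `locus` objects sorted by coordinate.
#' @export
cluster_loci <- function(frags, params = locus_filter_params()) {
  if (nrow(frags) > 1) {
    o <- order(frags$chrom, frags$start)
    if (!identical(o, seq_len(nrow(frags)))) {
      stop("fragments must be sorted by chromosome and start coordinate",
           call. = FALSE)
    }
  }
  det <- frags[frags$strand %in% c("+", "-"), , drop = FALSE]
  loci <- list()
  if (nrow(det)) {
    for (grp in split(seq_len(nrow(det)),
                      paste(det$chrom, det$strand))) {
      sub <- det[grp, , drop = FALSE]
      ir <- IRanges::IRanges(sub$start + 1L, sub$end)
      merged <- IRanges::reduce(ir, min.gapwidth = params$cluster_gap + 1L)
      # every span is contained in exactly one merged range
      hit <- IRanges::findOverlaps(ir, merged, type = "within")
      memb <- S4Vectors::subjectHits(hit)[match(seq_along(ir),
                                                S4Vectors::queryHits(hit))]
      for (k in seq_along(merged)) {
        fsub <- sub[memb == k, , drop = FALSE]
        loci[[length(loci) + 1L]] <- new_locus(
          chrom = fsub$chrom[1], strand = fsub$strand[1],
          start = min(fsub$start), end = max(fsub$end), fragments = fsub)
      }
    }
  }
  sort_loci(loci)
}

sort_loci <- function(loci) {
  if (!length(loci)) return(loci)
  o <- order(vapply(loci, `[[`, character(1), "chrom"),
             vapply(loci, `[[`, integer(1), "start"),
             vapply(loci, `[[`, integer(1), "end"),
             vapply(loci, `[[`, character(1), "strand"))
  loci[o]
}

interval_distance <- function(s1, e1, s2, e2) {
  # distance between closest edges of two half-open intervals; 0 on overlap
  if (e1 > s2 && e2 > s1) return(0L)
  if (e1 <= s2) s2 - e1 else s1 - e2
}

#' Assign strand-unknown internal fragments to nearby UMI-supported loci
#'
#' A junction-free internal fragment with unresolved strand inherits the
#' strand of every locus whose span overlaps or lies within `window` bp of
#' the fragment and that is supported by at least one UMI read. When loci on
#' both strands qualify the fragment is duplicated into each. Unassigned
#' fragments are held out of graph construction.
#'
#' @param unknown_frags Fragments with `strand == "*"`.
#' @param loci List of `locus` objects (from [cluster_loci()]).
#' @param window Maximum distance in bp (default 100).
#' @return List with `loci` (updated: fragments appended, spans extended,
#'   counts refreshed) and `unassigned` (fragment `data.frame`).
#' @export
resolve_internal_strand <- function(unknown_frags, loci, window = 100) {
  if (!length(loci) || nrow(unknown_frags) == 0) {
    return(list(loci = loci, unassigned = unknown_frags))
  }
  eligible <- vapply(loci, function(l) l$umi_count >= 1L, logical(1))
  added <- vector("list", length(loci))
  assigned <- logical(nrow(unknown_frags))
  for (i in seq_len(nrow(unknown_frags))) {
    f <- unknown_frags[i, , drop = FALSE]
    for (k in seq_along(loci)) {
      if (!eligible[k]) next
      l <- loci[[k]]
      if (l$chrom != f$chrom) next
      if (interval_distance(f$start, f$end, l$start, l$end) <= window) {
        f2 <- f
        f2$strand <- l$strand
        added[[k]] <- c(added[[k]], list(f2))
        assigned[i] <- TRUE
      }
    }
  }
  for (k in seq_along(loci)) {
    if (is.null(added[[k]])) next
    extra <- do.call(rbind, added[[k]])
    l <- loci[[k]]
    frags <- sort_fragments(rbind(l$fragments, extra))
    loci[[k]] <- new_locus(l$chrom, l$strand,
                           min(l$start, extra$start),
                           max(l$end, extra$end), frags)
  }
  list(loci = sort_loci(loci),
       unassigned = unknown_frags[!assigned, , drop = FALSE])
}

#' Purge loci that look like internal-read contamination
#'
#' A locus is purged when it has fewer than `min_umi_count` UMI fragments or
#' a UMI fraction below `min_umi_ratio`; such loci are likely intergenic or
#' intronic contamination by internal reads and are reported rather than
#' assembled.
#'
#' @param loci List of `locus` objects.
#' @param params [locus_filter_params()].
#' @return List with elements `kept` and `purged`.
#' @export
filter_contaminant_loci <- function(loci, params = locus_filter_params()) {
  purge <- vapply(loci, function(l) {
    tot <- l$umi_count + l$internal_count
    l$umi_count < params$min_umi_count ||
      (tot > 0 && l$umi_count / tot < params$min_umi_ratio)
  }, logical(1))
  list(kept = loci[!purge], purged = loci[purge])
}

#' Write purged loci as a BED audit file
#'
#' @param purged List of purged `locus` objects.
#' @param path Output BED path. Score column holds the locus UMI count and
#'   the name column `umi:internal` fragment counts.
#' @return Invisibly, the path.
#' @export
write_purged_bed <- function(purged, path) {
  lines <- vapply(purged, function(l) {
    sprintf("%s\t%d\t%d\t%d:%d\t%d\t%s", l$chrom, l$start, l$end,
            l$umi_count, l$internal_count, l$umi_count, l$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
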