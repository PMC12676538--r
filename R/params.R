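#' Locus clustering and contamination-filter parameters
#'
#' Controls how fragments are grouped into gene loci, how far a
#' junction-free internal fragment may sit from a UMI-supported locus and
#' still inherit its strand, and when a locus is purged as likely
#' intergenic/intronic contamination by internal reads.
#'
#' @param min_umi_count Minimum number of UMI fragments a locus must hold to
#'   survive filtering (default 2).
#' @param min_umi_ratio Minimum fraction of UMI fragments among all fragments
#'   of a locus (default 0.05).
#' @param nearby_window Maximum distance in bp between a strand-unknown
#'   fragment and a locus for strand rescue (default 100).
#' @param cluster_gap Maximum gap in bp between fragment spans that are still
#'   merged into one locus (default 50).
#' @return An object of class `locus_filter_params`.
#' @export
locus_filter_params <- function(min_umi_count = 2, min_umi_ratio = 0.05,
                                nearby_window = 100, cluster_gap = 50) {
  stopifnot(nearby_window >= 0, min_umi_ratio >= 0, min_umi_ratio <= 1,
            min_umi_count >= 0, cluster_gap >= 0)
  structure(list(min_umi_count = as.integer(min_umi_count),
                 min_umi_ratio = min_umi_ratio,
                 nearby_window = as.integer(nearby_window),
                 cluster_gap = as.integer(cluster_gap)),
            class = "locus_filter_params")
}

#' Intron-retention pruning thresholds
#'
#' Thresholds for the three splice-graph pruning rules. A vertex `v` with a
#' single predecessor `v-` and successor `v+`, immediately joint to both and
#' skipped by an edge `(v-, v+)`, is removed as a *full* intron retention
#' when (`w_v(v) <= a1 * w_skip` or `w_e(v-,v) <= a2 * w_skip` or
#' `w_e(v,v+) <= a3 * w_skip`) and `w_m(v) <= a4`, or — the intron-lariat
#' case — when `w_v(v) >= a5 * max(w_e(v-,v), w_e(v,v+))`. A vertex adjacent
#' to the source (mirror: sink), immediately joint to its single successor
#' `v+` that has at least two in-edges with maximum in-weight `w'`, is
#' removed as a *partial* intron retention (false alternative first/last
#' exon) when (`w_v(v) <= b1 * w'` or `w_e(v,v+) <= b2 * w'`) and
#' `w_m(v) <= b3`. An isolated vertex touching only source and sink is kept
#' as a putative single-exon transcript only when its UMI support reaches
#' `single_exon_min_umi`.
#'
#' All thresholds are user-tunable; the defaults below are the package's
#' own calibration (see the methods vignette).
#'
#' @param a1,a2,a3 Full-retention weight ratios against the skipping edge
#'   (defaults 0.25 each).
#' @param a4 Maximum UMI support of a removable full retention (default 1).
#' @param a5 Lariat rule: minimum ratio of vertex coverage over its strongest
#'   incident read-through edge (default 5.0).
#' @param b1,b2 Partial-retention weight ratios against the strongest
#'   competing edge (defaults 0.2 each).
#' @param b3 Maximum UMI support of a removable partial retention (default 1).
#' @param single_exon_min_umi Minimum UMI support for an isolated vertex to
#'   survive as a single-exon candidate (default 2).
#' @return An object of class `ir_params`.
#' @export
ir_params <- function(a1 = 0.25, a2 = 0.25, a3 = 0.25, a4 = 1, a5 = 5.0,
                      b1 = 0.2, b2 = 0.2, b3 = 1, single_exon_min_umi = 2) {
  v <- c(a1, a2, a3, a4, a5, b1, b2, b3, single_exon_min_umi)
  stopifnot(all(is.finite(v)), all(v >= 0))
  structure(list(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5,
                 b1 = b1, b2 = b2, b3 = b3,
                 single_exon_min_umi = as.integer(single_exon_min_umi)),
            class = "ir_params")
}

#' Decomposition and transcript-selection parameters
#'
#' @param first_exon_min_umi Minimum UMI support (max `w_m` over the vertices
#'   merged into the 5'-terminal exon) for a candidate transcript to be kept
#'   (default 1).
#' @param min_transcript_coverage Minimum predicted coverage (path abundance)
#'   of an emitted transcript; 0 disables (default 1.0).
#' @param min_transcript_length Minimum summed exon length in bp; 0 disables
#'   (default 150).
#' @param phasing_min_support Minimum multiplicity for a phasing path to
#'   constrain the decomposition (default 1).
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(first_exon_min_umi = 1,
                            min_transcript_coverage = 1.0,
                            min_transcript_length = 150,
                            phasing_min_support = 1) {
  stopifnot(first_exon_min_umi >= 0, min_transcript_coverage >= 0,
            min_transcript_length >= 0, phasing_min_support >= 0)
  structure(list(first_exon_min_umi = as.integer(first_exon_min_umi),
                 min_transcript_coverage = min_transcript_coverage,
                 min_transcript_length = as.integer(min_transcript_length),
                 phasing_min_support = as.integer(phasing_min_support)),
            class = "assembly_params")
}
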