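# Evaluation by intron-chain matching, following the convention of
# gffcompare's "=" class: a multi-exon prediction matches when its ordered
# intron chain is identical to that of a reference transcript on the same
# chromosome and strand. Single-exon predictions are excluded from the
# multi-exon statistics.

intron_chain <- function(exons) {
  if (nrow(exons) < 2) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = exons[-nrow(exons), 2], end = exons[-1, 1])
}

#' Intron-chain keys of transcripts
#'
#' One string per transcript combining chromosome, strand and the ordered
#' intron list; `NA` for single-exon transcripts. Two multi-exon
#' transcripts match exactly when their keys are equal.
#'
#' @param tx Transcript `data.frame`.
#' @return Character vector, `NA` for single-exon entries.
#' @export
chain_key <- function(tx) {
  vapply(seq_len(nrow(tx)), function(i) {
    ic <- intron_chain(tx$exons[[i]])
    if (!nrow(ic)) return(NA_character_)
    paste0(tx$chrom[i], tx$strand[i], "|",
           paste(ic[, 1], ic[, 2], sep = "-", collapse = ","))
  }, character(1))
}

check_stranded <- function(reference) {
  un <- !reference$strand %in% c("+", "-")
  if (any(un)) {
    warning(sum(un), " unstranded reference transcript(s) excluded from ",
            "matching")
  }
  reference[!un, , drop = FALSE]
}

#' Does a predicted transcript match the reference by intron chain?
#'
#' @param predicted One-row transcript `data.frame`.
#' @param reference Reference transcript `data.frame` (e.g. from
#'   [read_gtf()]).
#' @return `TRUE` iff `predicted` is multi-exon and its ordered intron list
#'   is identical to that of some same-chromosome, same-strand reference
#'   transcript. Single-exon predictions never match (they are excluded
#'   from the multi-exon statistics).
#' @export
match_intron_chain <- function(predicted, reference) {
  reference <- check_stranded(reference)
  key <- chain_key(predicted)
  if (is.na(key)) return(FALSE)
  key %in% chain_key(reference)
}

#' Transcript-level evaluation against a reference annotation
#'
#' @param predicted,reference Transcript `data.frame`s.
#' @return List with `n_matching` (multi-exon predictions whose intron chain
#'   occurs in the reference), `n_predicted_multiexon`, and `precision`
#'   (`n_matching / n_predicted_multiexon`, 0 when the denominator is 0).
#' @export
evaluate_assembly <- function(predicted, reference) {
  reference <- check_stranded(reference)
  pk <- if (nrow(predicted)) chain_key(predicted) else character(0)
  rk <- stats::na.omit(chain_key(reference))
  multi <- !is.na(pk)
  n_match <- sum(pk[multi] %in% rk)
  n_multi <- sum(multi)
  list(n_matching = n_match, n_predicted_multiexon = n_multi,
       precision = if (n_multi > 0) n_match / n_multi else 0)
}

#' Adjusted precision at a controlled sensitivity
#'
#' Implements coverage-ascending filtering: predictions are removed one at a
#' time in ascending order of predicted coverage (ties broken by
#' coordinate) until the number of matching transcripts equals
#' `baseline_matching`, and the precision of the surviving set is returned.
#' This enables precision comparison between methods at an equal number of
#' recovered true transcripts.
#'
#' @param predicted Transcript `data.frame` with a `coverage` column.
#' @param reference Reference transcript `data.frame`.
#' @param baseline_matching Target number of matching transcripts.
#' @return List with `precision`, `n_matching`, `n_kept`, and the surviving
#'   `predicted` set. When the baseline already exceeds the current
#'   matching count the unadjusted precision is returned with a warning.
#' @export
adjusted_precision <- function(predicted, reference, baseline_matching) {
  ev <- evaluate_assembly(predicted, reference)
  if (baseline_matching > ev$n_matching) {
    warning("baseline exceeds current matching count; returning unadjusted ",
            "precision")
    return(list(precision = ev$precision, n_matching = ev$n_matching,
                n_kept = nrow(predicted), predicted = predicted))
  }
  keep <- predicted
  o <- order(keep$coverage, keep$chrom, tx_start(keep), tx_end(keep),
             keep$transcript_id)
  keep <- keep[o, , drop = FALSE]
  ev <- evaluate_assembly(keep, reference)
  while (ev$n_matching > baseline_matching && nrow(keep) > 0) {
    keep <- keep[-1, , drop = FALSE]
    ev <- evaluate_assembly(keep, reference)
  }
  list(precision = ev$precision, n_matching = ev$n_matching,
       n_kept = nrow(keep), predicted = keep)
}

#' Write a per-cell evaluation metrics table
#'
#' @param metrics Named list or data.frame of metric rows.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  df <- as.data.frame(metrics)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
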