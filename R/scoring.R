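## Contig and assembly scores, abundance weighting, mapping-rate
## computation, automated cutoff learning and assembly filtering.

#' Combine the four component scores into a contig score
#'
#' The product of the four components, each first floored at `floor` so that
#' a single failed component saturates at a minimum value instead of
#' annihilating the assembly-level geometric mean.
#'
#' @param s_nuc,s_cov,s_ord,s_seg Component scores in `[0, 1]` (vectorized).
#' @param floor Component floor in `(0, 1)` (default 0.01).
#' @return Contig score(s) in `[floor^4, 1]`.
#' @export
contig_score <- function(s_nuc, s_cov, s_ord, s_seg, floor = 0.01) {
  stopifnot(floor > 0, floor < 1)
  pmax(s_nuc, floor) * pmax(s_cov, floor) * pmax(s_ord, floor) *
    pmax(s_seg, floor)
}

#' Abundance-weighted contig score
#'
#' Raises the contig score to the power `1 + log(tpm + 1)/log(n_contigs)`,
#' so that abundant contigs are penalized more heavily for the same defects
#' and a contig with zero abundance keeps its unweighted score.
#'
#' @param s Contig score(s) in `(0, 1]`.
#' @param tpm Transcripts-per-million value(s) of the contig(s).
#' @param n_contigs Number of contigs in the assembly (the logarithm base);
#'   must be at least 2.
#' @param log_base Optional explicit logarithm base overriding `n_contigs`
#'   (e.g. `exp(1)` for a natural-log weighting).
#' @return Weighted score(s) `s_w <= s`.
#' @export
weighted_contig_score <- function(s, tpm, n_contigs, log_base = NULL) {
  base <- if (is.null(log_base)) n_contigs else log_base
  if (base < 2) stop("log base must be >= 2 (n_contigs < 2 leaves the ",
                     "abundance weighting undefined)")
  s^(1 + log(tpm + 1) / log(base))
}

#' Proportion of input read pairs mapped to the assembly
#'
#' @param aln A `pair_alignments` object built from the complete input read
#'   set (unmapped pairs included).
#' @return Fraction of pairs with both mates aligned somewhere in `[0, 1]`.
#' @export
compute_r_valid <- function(aln) {
  n <- nrow(aln$pairs)
  if (n == 0L) stop("no read pairs")
  sum(aln$pairs$both_mapped) / n
}

#' Assembly score from contig scores and the mapping rate
#'
#' The product of the geometric mean of the contig scores and the proportion
#' of read pairs mapped, computed in log space.
#'
#' @param scores Numeric vector of contig scores (use the weighted scores for
#'   the abundance-weighted assembly score).
#' @param r_valid Mapping rate in `[0, 1]`.
#' @return Assembly score in `[0, 1]`.
#' @export
assembly_score <- function(scores, r_valid) {
  if (length(scores) == 0L) stop("no contig scores")
  stopifnot(r_valid >= 0, r_valid <= 1, all(scores >= 0), all(scores <= 1))
  exp(mean(log(scores))) * r_valid
}

#' Learn the contig-score cutoff that maximizes the assembly score
#'
#' Evaluates, for every candidate cutoff in the sorted set of distinct contig
#' scores (plus 0), the assembly score of the retained subset
#' `{s >= cutoff}`, with the mapping rate recomputed as the fraction of all
#' input pairs that are both-mates-mapped *and* assigned to a retained
#' contig. The objective is piecewise-constant in the cutoff, so the sweep
#' is the global optimization, performed exactly. Ties are broken toward the
#' smaller cutoff (retain more contigs). Pairs are not re-assigned after
#' filtering.
#'
#' @param scores data.frame with columns `contig_id` and `s` (contig scores).
#' @param aln The `pair_alignments` object used to score the assembly, with
#'   assignments set.
#' @return list with `cutoff`, `optimized_score`, and the full `sweep`
#'   data.frame (`cutoff`, `n_retained`, `r_valid`, `score`).
#' @export
learn_cutoff <- function(scores, aln) {
  stopifnot(nrow(scores) > 0L)
  n_total <- nrow(aln$pairs)
  ok <- aln$pairs$both_mapped & !is.na(aln$pairs$assigned_contig)
  pair_counts <- table(factor(aln$pairs$assigned_contig[ok],
                              levels = scores$contig_id))
  o <- order(scores$s)
  s_sorted <- scores$s[o]
  cnt_sorted <- as.numeric(pair_counts)[o]
  ## suffix aggregates: retaining contigs with s >= cutoff
  suf_log_s <- rev(cumsum(rev(log(s_sorted))))
  suf_n <- rev(seq_along(s_sorted)) # contigs retained from position i on
  suf_pairs <- rev(cumsum(rev(cnt_sorted)))
  cutoffs <- c(0, unique(s_sorted))
  first_kept <- findInterval(cutoffs, s_sorted, left.open = TRUE) + 1L
  n_c <- length(s_sorted)
  obj <- vapply(seq_along(cutoffs), function(i) {
    fk <- first_kept[i]
    if (fk > n_c) return(NA_real_)  # nothing retained
    exp(suf_log_s[fk] / suf_n[fk]) * suf_pairs[fk] / n_total
  }, numeric(1))
  if (all(is.na(obj))) return(list(cutoff = 0, optimized_score = NA_real_,
                                   sweep = NULL))
  best <- which(obj == max(obj, na.rm = TRUE))[1L]  # cutoffs ascending
  sweep <- data.frame(cutoff = cutoffs,
                      n_retained = ifelse(first_kept > n_c, 0L,
                                          suf_n[pmin(first_kept, n_c)]),
                      r_valid = ifelse(first_kept > n_c, 0,
                                       suf_pairs[pmin(first_kept, n_c)] /
                                         n_total),
                      score = obj)
  list(cutoff = cutoffs[best], optimized_score = obj[best], sweep = sweep)
}

#' Partition an assembly by contig score
#'
#' @param contigs Named `DNAStringSet`.
#' @param scores data.frame with `contig_id` and `s`.
#' @param cutoff Score cutoff in `[0, 1]`; contigs with `s >= cutoff` are
#'   kept.
#' @param kept_path,discarded_path Optional FASTA output paths.
#' @return list with `kept` and `discarded` `DNAStringSet`s (also written to
#'   the given paths).
#' @export
filter_assembly <- function(contigs, scores, cutoff,
                            kept_path = NULL, discarded_path = NULL) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  s <- scores$s[match(names(contigs), scores$contig_id)]
  if (anyNA(s)) stop("missing score for contig ",
                     names(contigs)[which(is.na(s))[1L]])
  keep <- s >= cutoff
  kept <- contigs[keep]
  discarded <- contigs[!keep]
  if (!is.null(kept_path)) write_fasta(kept, kept_path)
  if (!is.null(discarded_path)) write_fasta(discarded, discarded_path)
  message(sprintf("kept %d contigs, discarded %d (cutoff %.6g)",
                  length(kept), length(discarded), cutoff))
  list(kept = kept, discarded = discarded)
}
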