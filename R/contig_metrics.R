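## Per-contig score components computed from assigned-pair evidence:
## s_nuc (per-base read support), s_cov (covered fraction) and s_ord
## (read-pair order consistency). s_seg lives in segmentation.R.

#' Nucleotide-support score of a contig
#'
#' The mean, over every (read, covered nucleotide) combination, of the read's
#' support value `1 - nm/max_edit_distance`: equivalently the ratio of the
#' summed per-base support to the summed per-base depth. A contig with no
#' covered base scores 0.
#'
#' @param ev A `contig_evidence` element from [build_evidence()].
#' @return A value in `[0, 1]`.
#' @export
score_nuc <- function(ev) {
  d <- sum(as.numeric(ev$depth))
  if (d == 0) return(0)
  sum(ev$support_sum) / d
}

#' Coverage score of a contig
#'
#' Fraction of the contig's nucleotides covered by at least one aligned mate,
#' irrespective of agreement between read and contig.
#'
#' @param ev A `contig_evidence` element from [build_evidence()].
#' @return A value in `[0, 1]`.
#' @export
score_cov <- function(ev) {
  mean(ev$depth >= 1L)
}

#' Classify assigned read pairs against the library model
#'
#' A pair is `good` when both mates align to its assigned contig, their
#' relative orientation matches the library model, and the implied fragment
#' size lies within `fragment_mean +/- k_sd * fragment_sd`. Failing pairs take
#' the first failing category: `different-contigs` (mates on two contigs, the
#' fragmentation/bridging signal), `bad-orientation`, `bad-distance`.
#' Pairs with exactly one aligned mate are `half-mapped`; pairs with no
#' alignment are `unmapped`.
#'
#' @param aln A `pair_alignments` object with assignments set.
#' @param lib A `library_model`.
#' @param k_sd Width of the fragment-size window in standard deviations
#'   (default 3.5; chosen so that the window strictly contains a +/-3 sd
#'   size-selection band even after estimating the sd from a subsample).
#' @return data.frame with one row per read pair: `pair_id`, `status`,
#'   `contig` (assigned contig), `contig2` (the second contig for bridging
#'   pairs, else `NA`).
#' @export
classify_pairs <- function(aln, lib, k_sd = 3.5) {
  pr <- aln$pairs
  status <- rep("unmapped", nrow(pr))
  contig <- pr$assigned_contig
  contig2 <- rep(NA_character_, nrow(pr))
  has <- which(!is.na(pr$assigned_placement))
  if (length(has)) {
    plc <- aln$placements[pr$assigned_placement[has], , drop = FALSE]
    m1a <- !is.na(plc$m1_contig)
    m2a <- !is.na(plc$m2_contig)
    both <- m1a & m2a
    same <- both & plc$m1_contig == plc$m2_contig
    st <- rep("half-mapped", length(has))
    st[both & !same] <- "different-contigs"
    idx <- which(same)
    if (length(idx)) {
      ori <- .orientation(plc$m1_start[idx], plc$m1_strand[idx],
                          plc$m2_start[idx], plc$m2_strand[idx])
      frag <- pmax(plc$m1_end[idx], plc$m2_end[idx]) -
        pmin(plc$m1_start[idx], plc$m2_start[idx])
      lo <- lib$fragment_mean - k_sd * lib$fragment_sd
      hi <- lib$fragment_mean + k_sd * lib$fragment_sd
      st[idx] <- ifelse(ori != lib$orientation, "bad-orientation",
                        ifelse(frag >= lo & frag <= hi, "good",
                               "bad-distance"))
    }
    status[has] <- st
    other <- ifelse(both & !same,
                    ifelse(plc$m1_contig == contig[has],
                           plc$m2_contig, plc$m1_contig),
                    NA_character_)
    contig2[has] <- other
  }
  data.frame(pair_id = pr$pair_id, status = status, contig = contig,
             contig2 = contig2, stringsAsFactors = FALSE)
}

#' Order score of one contig from pair classifications
#'
#' The proportion of pairs touching the contig that are `good`. The
#' denominator counts every pair with at least one assigned mate on the
#' contig; a pair bridging two contigs is counted against both.
#'
#' @param classifications The rows of [classify_pairs()] output relevant to
#'   one contig (see [score_ord_by_contig()] for the assembly-wide version).
#' @return A value in `[0, 1]`; 0 when no pair touches the contig.
#' @export
score_ord <- function(classifications) {
  n <- nrow(classifications)
  if (n == 0L) return(0)
  sum(classifications$status == "good") / n
}

#' Order scores for every contig of an assembly
#'
#' @param cls Output of [classify_pairs()].
#' @param contig_ids Character vector of all contig ids (contigs untouched by
#'   any pair score 0).
#' @return data.frame `contig_id`, `n_pairs`, `good_pairs`, `s_ord`.
#' @export
score_ord_by_contig <- function(cls, contig_ids) {
  touch <- rbind(
    data.frame(contig = cls$contig, good = cls$status == "good",
               stringsAsFactors = FALSE),
    data.frame(contig = cls$contig2, good = FALSE, stringsAsFactors = FALSE))
  touch <- touch[!is.na(touch$contig), , drop = FALSE]
  idx <- match(touch$contig, contig_ids)
  n <- tabulate(idx, nbins = length(contig_ids))
  g <- tabulate(idx[touch$good], nbins = length(contig_ids))
  data.frame(contig_id = contig_ids, n_pairs = n, good_pairs = g,
             s_ord = ifelse(n > 0, g / n, 0), stringsAsFactors = FALSE)
}
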