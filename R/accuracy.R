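## Reference-based contig accuracy: reciprocal best hits between assembly
## and reference transcripts by Smith-Waterman local alignment, and the
## precision/recall/F-score of each matched contig. Used to validate the
## reference-free contig score, not by the scoring pipeline itself.

## shared-kmer candidate pairs: a seed-and-extend style prefilter so that
## only plausible contig/reference pairs are aligned. Any local alignment
## worth reporting at the default scoring shares a seed k-mer in practice;
## exhaustive mode is available and tested against the filtered mode.
.kmer_candidates <- function(query, subject, k = 15L, min_shared = 1L) {
  kmers <- function(seqs) {
    s <- as.character(seqs)
    n <- nchar(s)
    idx <- rep.int(seq_along(s), pmax(n - k + 1L, 0L))
    off <- unlist(lapply(pmax(n - k + 1L, 0L), seq_len), use.names = FALSE)
    data.table::data.table(seq = idx, kmer = substring(s[idx], off,
                                                       off + k - 1L))
  }
  kq <- unique(kmers(query))
  ks <- unique(kmers(subject))
  hits <- merge(kq, ks, by = "kmer", allow.cartesian = TRUE,
                suffixes = c("_q", "_s"))
  if (nrow(hits) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  cnt <- hits[, .N, by = c("seq_q", "seq_s")]
  cnt <- cnt[cnt$N >= min_shared, ]
  data.frame(query = cnt$seq_q, subject = cnt$seq_s)
}

#' Reciprocal best hits between assembly contigs and reference transcripts
#'
#' Scores candidate contig/reference pairs with Smith-Waterman local
#' alignment (match +1, mismatch -2, gap open 5, gap extend 2); each contig's
#' best-scoring reference and each reference's best-scoring contig are
#' determined, and pairs that are mutual bests with alignment score at least
#' `min_score` are retained. `min_score` stands in for a database-size-
#' dependent e-value cutoff. By default only pairs sharing at least one
#' 15-mer are aligned (`exhaustive = FALSE`); ties are broken toward the
#' lexicographically first id.
#'
#' @param contigs,references Named `DNAStringSet`s.
#' @param min_score Minimum local alignment score (default 50).
#' @param exhaustive Align all pairs instead of shared-kmer candidates.
#' @return data.frame with one row per reciprocal best hit: `contig_id`,
#'   `reference_id`, `aligned_identical_bases`, `contig_len`,
#'   `reference_len`, `alignment_score`.
#' @export
reciprocal_best_hits <- function(contigs, references, min_score = 50,
                                 exhaustive = FALSE) {
  stopifnot(length(contigs) > 0L, length(references) > 0L)
  empty <- data.frame(contig_id = character(), reference_id = character(),
                      aligned_identical_bases = integer(),
                      contig_len = integer(), reference_len = integer(),
                      alignment_score = numeric(), stringsAsFactors = FALSE)
  if (exhaustive) {
    cand <- expand.grid(query = seq_along(contigs),
                        subject = seq_along(references))
  } else {
    cand <- .kmer_candidates(contigs, references)
  }
  if (nrow(cand) == 0L) return(empty)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  score <- Biostrings::pairwiseAlignment(
    contigs[cand$query], references[cand$subject], type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
    scoreOnly = TRUE)
  cand$score <- score
  cand <- cand[cand$score >= min_score, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  ## deterministic tie-break: order by score desc then partner id
  qid <- names(contigs)[cand$query]
  sid <- names(references)[cand$subject]
  oq <- order(cand$query, -cand$score, sid)
  best_q <- cand[oq, ][!duplicated(cand$query[oq]), , drop = FALSE]
  os <- order(cand$subject, -cand$score, qid)
  best_s <- cand[os, ][!duplicated(cand$subject[os]), , drop = FALSE]
  mutual <- merge(best_q, best_s, by = c("query", "subject"))
  if (nrow(mutual) == 0L) return(empty)
  aln <- Biostrings::pairwiseAlignment(
    contigs[mutual$query], references[mutual$subject], type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
  out <- data.frame(
    contig_id = names(contigs)[mutual$query],
    reference_id = names(references)[mutual$subject],
    aligned_identical_bases = Biostrings::nmatch(aln),
    contig_len = Biostrings::width(contigs)[mutual$query],
    reference_len = Biostrings::width(references)[mutual$subject],
    alignment_score = mutual$score.x,
    stringsAsFactors = FALSE)
  out[order(out$contig_id), , drop = FALSE]
}

#' Reciprocal best hits from external tabular alignment results
#'
#' For assemblies too large for the built-in aligner, accepts the standard
#' 12-column tabular output of an external local-alignment search run in both
#' directions (columns `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore`, no header). The best hit per query in
#' each file (highest bitscore, ties toward the lexicographically first
#' subject) is taken, mutual bests are retained, and the identical-base count
#' is `round(pident/100 * length)` of the forward hit.
#'
#' @param forward_path Tabular results of contigs searched against the
#'   references.
#' @param reverse_path Tabular results of references searched against the
#'   contigs.
#' @param contigs,references Named `DNAStringSet`s (supply the lengths).
#' @param max_evalue Hits above this e-value are ignored (default 1e-5).
#' @return data.frame in the same shape as [reciprocal_best_hits()].
#' @export
rbh_from_tabular <- function(forward_path, reverse_path, contigs,
                             references, max_evalue = 1e-5) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  read_tab <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 12L) stop("expected 12 tabular columns in ", path)
    names(tab)[1:12] <- cols
    tab <- tab[tab$evalue <= max_evalue, , drop = FALSE]
    tab <- tab[order(tab$qseqid, -tab$bitscore, tab$sseqid), , drop = FALSE]
    tab[!duplicated(tab$qseqid), , drop = FALSE]
  }
  fwd <- read_tab(forward_path)
  rev <- read_tab(reverse_path)
  back <- rev$sseqid[match(fwd$sseqid, rev$qseqid)]
  keep <- !is.na(back) & back == fwd$qseqid
  fwd <- fwd[keep, , drop = FALSE]
  out <- data.frame(
    contig_id = fwd$qseqid,
    reference_id = fwd$sseqid,
    aligned_identical_bases = as.integer(round(fwd$pident / 100 *
                                                 fwd$length)),
    contig_len = Biostrings::width(contigs)[match(fwd$qseqid,
                                                  names(contigs))],
    reference_len = Biostrings::width(references)[match(fwd$sseqid,
                                                        names(references))],
    alignment_score = fwd$bitscore,
    stringsAsFactors = FALSE)
  if (anyNA(out$contig_len) || anyNA(out$reference_len)) {
    stop("tabular hit names do not match the supplied sequence sets")
  }
  out[order(out$contig_id), , drop = FALSE]
}

#' Precision, recall and F-score of matched contigs
#'
#' Precision is the number of identical aligned bases over the contig length,
#' recall the same count over the reference length, and the F-score their
#' harmonic mean (0 when both are 0).
#'
#' @param rbh data.frame from [reciprocal_best_hits()].
#' @return data.frame `contig_id`, `reference_id`, `precision`, `recall`,
#'   `f_score`.
#' @export
contig_f_score <- function(rbh) {
  precision <- rbh$aligned_identical_bases / rbh$contig_len
  recall <- rbh$aligned_identical_bases / rbh$reference_len
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  data.frame(contig_id = rbh$contig_id, reference_id = rbh$reference_id,
             precision = precision, recall = recall, f_score = f,
             stringsAsFactors = FALSE)
}

#' Rank correlation between contig scores and reference-based accuracy
#'
#' Spearman's rank correlation between the reference-free contig score and
#' the reciprocal-best-hit F-score, joined on contig id. Contigs without a
#' reciprocal best hit are included with F-score 0 when `include_misses` is
#' set; contigs at the floored minimum score can be excluded first, since
#' they are typically redundant contigs that lost all their reads to a better
#' copy during assignment rather than misassemblies.
#'
#' @param scores data.frame with `contig_id` and `s`.
#' @param accuracies data.frame from [contig_f_score()].
#' @param drop_minimum Exclude contigs at the floored minimum score
#'   (default FALSE).
#' @param include_misses Treat score rows absent from `accuracies` as
#'   F-score 0 (default FALSE: inner join).
#' @param floor Component floor used when scoring (default 0.01), defining
#'   the minimum contig score `floor^4`.
#' @return Spearman's rho.
#' @export
score_accuracy_correlation <- function(scores, accuracies,
                                       drop_minimum = FALSE,
                                       include_misses = FALSE,
                                       floor = 0.01) {
  if (include_misses) {
    f <- accuracies$f_score[match(scores$contig_id, accuracies$contig_id)]
    f[is.na(f)] <- 0
    joined <- data.frame(s = scores$s, f_score = f)
  } else {
    joined <- merge(scores[, c("contig_id", "s")],
                    accuracies[, c("contig_id", "f_score")],
                    by = "contig_id")
  }
  if (drop_minimum) {
    joined <- joined[joined$s > floor^4 + 1e-12, , drop = FALSE]
  }
  if (nrow(joined) < 3L) stop("need at least 3 score/accuracy pairs")
  stats::cor(joined$s, joined$f_score, method = "spearman")
}
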