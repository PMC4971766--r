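## End-to-end scoring pipeline: library inference -> EM abundances ->
## sampled assignment -> evidence -> four components -> contig scores ->
## assembly scores -> learned cutoff.

#' Score a transcriptome assembly from read alignments
#'
#' Runs the full reference-free evaluation: infers the library model from a
#' subsample of mapped pairs, estimates contig abundances by EM over
#' multi-mapping pairs, samples the all-or-nothing assignment of every pair,
#' builds per-contig evidence, computes the four per-contig components
#' (nucleotide support, coverage, pair order, single-segment posterior),
#' combines them into contig scores and raw/abundance-weighted assembly
#' scores, and learns the score cutoff maximizing the assembly score.
#'
#' For the segmentation component the per-base depth is trimmed by
#' `edge_trim` nucleotides at each contig end (coverage ramps there reflect
#' fragment geometry, not abundance change) and binned to about
#' `segment_bins` symbols; the symbol alphabet is shared across the assembly
#' so that `s_seg` values are comparable between contigs.
#'
#' @param contigs Named `DNAStringSet` (see [read_fasta()]).
#' @param aln A `pair_alignments` object over `contigs` built from the
#'   complete input read set.
#' @param k_sd Fragment-size window width in standard deviations for pair
#'   classification (default 3.5).
#' @param k_max Maximum segment count for the chimera test (default 2).
#' @param alpha Dirichlet concentration (default 1).
#' @param floor Component floor (default 0.01).
#' @param segment_bins Target symbol count per contig (default 20);
#'   `bin_width = max(1, ceiling(L/segment_bins))`. Set to `Inf` (with
#'   `edge_trim = 0`) for per-nucleotide encoding.
#' @param edge_trim Nucleotides ignored at each contig end when encoding the
#'   coverage profile; `"auto"` (default) uses one inferred fragment length
#'   (the zone where paired-end coverage is non-stationary for geometric
#'   reasons), capped at a quarter of the contig.
#' @param subsample_fraction Mapped-pair fraction for library inference
#'   (default 0.01).
#' @param weight_log_base Optional log base override for the abundance
#'   weighting (default: number of contigs).
#' @param seed Integer seed driving the library subsample and the assignment
#'   draws.
#' @return An object of class `assembly_report`: list with `summary` (one-row
#'   data.frame: `n_contigs`, `r_valid`, `geomean_contig_score`, `score`,
#'   `weighted_score`, `optimal_cutoff`, `optimized_score`), `contigs`
#'   (per-contig table), `library` (the inferred model), `cutoff_sweep`,
#'   and `alignments` (the assigned `pair_alignments`).
#' @export
score_assembly <- function(contigs, aln,
                           k_sd = 3.5, k_max = 2L, alpha = 1,
                           floor = 0.01, segment_bins = 20L,
                           edge_trim = "auto",
                           subsample_fraction = 0.01,
                           weight_log_base = NULL,
                           seed = 1L) {
  ids <- names(contigs)
  lens <- Biostrings::width(contigs)
  lib <- infer_library(aln, fraction = subsample_fraction, seed = seed)
  ab <- estimate_abundances(contigs, aln, lib)
  aln <- assign_pairs(aln, ab, seed = seed + 1L)
  ev <- build_evidence(contigs, aln)
  cls <- classify_pairs(aln, lib, k_sd = k_sd)
  ord <- score_ord_by_contig(cls, ids)
  s_nuc <- vapply(ev, score_nuc, numeric(1))
  s_cov <- vapply(ev, score_cov, numeric(1))
  trim <- if (identical(edge_trim, "auto")) {
    as.integer(round(lib$fragment_mean))
  } else as.integer(edge_trim)
  profiles <- lapply(seq_along(ids), function(i) {
    d <- ev[[i]]$depth
    t_i <- min(trim, (lens[i] - 1L) %/% 4L)
    if (t_i > 0L) d <- d[(t_i + 1L):(lens[i] - t_i)]
    bw <- if (is.finite(segment_bins)) {
      max(1L, as.integer(ceiling(length(d) / segment_bins)))
    } else 1L
    encode_profile(d, bw)
  })
  A <- max(2L, max(vapply(profiles, function(p) max(p$symbols), integer(1)))
           + 1L)
  s_seg <- vapply(profiles, function(p) {
    p_single_segment(p, k_max = k_max, alpha = alpha,
                     alphabet_size = A)$p_single
  }, numeric(1))
  ## contigs that acquired no evidence at all score 0 on every component
  none <- vapply(ev, function(e) e$assigned_pairs == 0L &&
                   all(e$depth == 0L), logical(1)) & ord$n_pairs == 0L
  s_nuc[none] <- 0; s_cov[none] <- 0; s_seg[none] <- 0
  s <- contig_score(s_nuc, s_cov, ord$s_ord, s_seg, floor = floor)
  tpm <- ab$tpm[match(ids, ab$contig_id)]
  s_w <- if (length(ids) >= 2L || !is.null(weight_log_base)) {
    weighted_contig_score(s, tpm, length(ids), log_base = weight_log_base)
  } else s
  ctab <- data.frame(contig_id = ids, length = lens,
                     s_nuc = s_nuc, s_cov = s_cov, s_ord = ord$s_ord,
                     s_seg = s_seg, score = s, weighted_score = s_w,
                     tpm = tpm,
                     est_fragments = ab$est_fragments[match(ids,
                                                            ab$contig_id)],
                     assigned_pairs = vapply(ev, function(e)
                       e$assigned_pairs, integer(1)),
                     n_pairs = ord$n_pairs, good_pairs = ord$good_pairs,
                     stringsAsFactors = FALSE)
  rownames(ctab) <- NULL
  r_valid <- compute_r_valid(aln)
  score <- assembly_score(s, r_valid)
  w_score <- assembly_score(s_w, r_valid)
  opt <- learn_cutoff(data.frame(contig_id = ids, s = s,
                                 stringsAsFactors = FALSE), aln)
  summary <- data.frame(n_contigs = length(ids), r_valid = r_valid,
                        geomean_contig_score = exp(mean(log(s))),
                        score = score, weighted_score = w_score,
                        optimal_cutoff = opt$cutoff,
                        optimized_score = opt$optimized_score)
  structure(list(summary = summary, contigs = ctab, library = lib,
                 cutoff_sweep = opt$sweep, alignments = aln,
                 evidence = ev, classifications = cls,
                 floor = floor),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  s <- x$summary
  cat("assembly_report\n")
  cat(sprintf("  contigs:          %d\n", s$n_contigs))
  cat(sprintf("  r_valid:          %.6g\n", s$r_valid))
  cat(sprintf("  geomean contig:   %.6g\n", s$geomean_contig_score))
  cat(sprintf("  assembly score:   %.6g\n", s$score))
  cat(sprintf("  weighted score:   %.6g\n", s$weighted_score))
  cat(sprintf("  optimal cutoff:   %.6g\n", s$optimal_cutoff))
  cat(sprintf("  optimized score:  %.6g\n", s$optimized_score))
  invisible(x)
}

.fmt6 <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write an assembly report to a directory
#'
#' Writes `assembly_report.tsv` (one row of assembly-level quantities),
#' `contig_scores.tsv` (per-contig components and scores) and, when the
#' assembly is given, the score-partitioned `good.fa`/`bad.fa` at the learned
#' cutoff. Floats are printed with 6 significant digits.
#'
#' @param report An `assembly_report`.
#' @param dir Output directory (created if needed).
#' @param contigs Optional `DNAStringSet` to partition at the learned cutoff.
#' @return `dir`, invisibly.
#' @export
write_assembly_report <- function(report, dir, contigs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(.fmt6(report$summary),
                     file.path(dir, "assembly_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(.fmt6(report$contigs),
                     file.path(dir, "contig_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(contigs)) {
    filter_assembly(contigs,
                    data.frame(contig_id = report$contigs$contig_id,
                               s = report$contigs$score),
                    report$summary$optimal_cutoff,
                    kept_path = file.path(dir, "good.fa"),
                    discarded_path = file.path(dir, "bad.fa"))
  }
  invisible(dir)
}
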