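## Fixture builders and independent oracles shared across the test files.
## Oracles are deliberately written as plain loops / enumerations so they do
## not share code paths with the package implementation.

toy_contigs <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

## one placement row in the alignment interchange schema (0-based half-open)
plc_row <- function(pair_id, contig, s1, e1, st1 = "+", nm1 = 0L,
                    s2 = NA, e2 = NA, st2 = NA, nm2 = NA,
                    contig2 = contig) {
  data.frame(pair_id = pair_id, contig_id = contig,
             m1_start = s1, m1_end = e1, m1_strand = st1, m1_nm = nm1,
             m2_start = s2, m2_end = e2, m2_strand = st2, m2_nm = nm2,
             m2_contig = contig2, stringsAsFactors = FALSE)
}

## a standard inward pair on one contig with given fragment span
proper_pair <- function(pair_id, contig, start, fragment, read_len = 100L,
                        nm1 = 0L, nm2 = 0L) {
  plc_row(pair_id, contig,
          s1 = start, e1 = start + read_len, st1 = "+", nm1 = nm1,
          s2 = start + fragment - read_len, e2 = start + fragment,
          st2 = "-", nm2 = nm2)
}

## naive per-base depth oracle: loops over every mate and every base
naive_depth <- function(contig_len, starts, ends) {
  d <- integer(contig_len)
  for (i in seq_along(starts)) {
    for (k in seq(starts[i] + 1L, ends[i])) d[k] <- d[k] + 1L
  }
  d
}

## independent EM reference: plain-loop implementation over an explicit
## candidate list (one entry per pair: data.frame(contig, mult))
naive_em <- function(cands, eff_len, n_contigs, iters = 10000,
                     tol = 1e-12) {
  theta <- rep(1 / n_contigs, n_contigs)
  n <- length(cands)
  for (it in seq_len(iters)) {
    est <- rep(0, n_contigs)
    for (p in seq_len(n)) {
      w <- cands[[p]]$mult * theta[cands[[p]]$contig] /
        eff_len[cands[[p]]$contig]
      if (sum(w) == 0) w <- rep(1, length(w))
      w <- w / sum(w)
      for (j in seq_along(w)) {
        c <- cands[[p]]$contig[j]
        est[c] <- est[c] + w[j]
      }
    }
    theta_new <- est / n
    if (max(abs(theta_new - theta)) < tol) {
      theta <- theta_new
      break
    }
    theta <- theta_new
  }
  theta * n
}

## log-likelihood of the EM mixture for the same candidate list
em_loglik <- function(cands, theta, eff_len) {
  sum(vapply(cands, function(cc) {
    log(sum(cc$mult * theta[cc$contig] / eff_len[cc$contig]))
  }, numeric(1)))
}

## exhaustive segmentation oracle: enumerate all placements of k-1 change
## points, average the product of Dirichlet-multinomial segment marginals
enum_log_evidence <- function(symbols, k, A, alpha) {
  L <- length(symbols)
  if (L < k) return(-Inf)
  seg_ml <- function(x) {
    counts <- tabulate(x + 1L, nbins = A)
    lgamma(A * alpha) - lgamma(length(x) + A * alpha) +
      sum(lgamma(counts + alpha) - lgamma(alpha))
  }
  if (k == 1L) return(seg_ml(symbols))
  cuts <- utils::combn(L - 1L, k - 1L)
  vals <- apply(cuts, 2L, function(cp) {
    bounds <- c(0L, cp, L)
    sum(vapply(seq_len(k), function(j) {
      seg_ml(symbols[(bounds[j] + 1L):bounds[j + 1L]])
    }, numeric(1)))
  })
  m <- max(vals)
  m + log(mean(exp(vals - m)))
}

## exhaustive cutoff-learning oracle: recompute the filtered assembly score
## from scratch for every candidate cutoff
naive_best_cutoff <- function(s, pair_counts, n_total) {
  cutoffs <- sort(unique(c(0, s)))
  best <- c(cutoff = NA_real_, score = -Inf)
  for (ct in cutoffs) {
    keep <- s >= ct
    if (!any(keep)) next
    sc <- exp(mean(log(s[keep]))) * sum(pair_counts[keep]) / n_total
    if (sc > best["score"] + 1e-15) best <- c(cutoff = ct, score = sc)
  }
  best
}

## tiny complete scoring run used by several tests
quick_report <- function(n_tx = 10, n_pairs = 4000, error_rate = 0,
                         seed = 7, ...) {
  tx <- simulate_transcriptome(n_tx, seed = seed)
  rd <- simulate_reads(tx$transcripts, tx$abundances, n_pairs,
                       error_rate = error_rate, seed = seed + 1)
  aln <- alignments_from_table(rd$truth, tx$transcripts)
  list(tx = tx, rd = rd, aln = aln,
       report = score_assembly(tx$transcripts, aln, seed = seed + 2, ...))
}
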