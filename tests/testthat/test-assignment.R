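ctg2 <- function(len = 1000L) {
  toy_contigs(c1 = strrep("A", len), c2 = strrep("C", len))
}

test_that("library model recovers orientation and fragment statistics", {
  ## 1000 inward pairs, constant fragment 400
  tab <- do.call(rbind, lapply(1:1000, function(i) {
    proper_pair(sprintf("p%04d", i), "c1", (i %% 400), 400)
  }))
  aln <- alignments_from_table(tab, ctg2())
  lib <- infer_library(aln, seed = 3)
  expect_equal(lib$orientation, "inward")
  expect_equal(lib$fragment_mean, 400)
  expect_equal(lib$fragment_sd, 0)

  ## orientation tie: deterministic lexicographic winner with a warning
  tab_out <- do.call(rbind, lapply(1:1000, function(i) {
    p <- proper_pair(sprintf("q%04d", i), "c1", (i %% 400), 400)
    if (i <= 500) {
      p$m1_strand <- "-"
      p$m2_strand <- "+"
    }
    p
  }))
  aln_tie <- alignments_from_table(tab_out, ctg2())
  expect_warning(lib_tie <- infer_library(aln_tie, seed = 3),
                 "orientation tie")
  expect_equal(lib_tie$orientation, "inward")

  ## no same-contig pair anywhere
  tab_diff <- plc_row("p1", "c1", 0, 100, "+", 0L,
                      s2 = 0, e2 = 100, st2 = "-", nm2 = 0L,
                      contig2 = "c2")
  expect_error(infer_library(alignments_from_table(tab_diff, ctg2())),
               "cannot infer library model")
})

test_that("library model is recovered from simulated reads", {
  tx <- simulate_transcriptome(30, seed = 121)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 20000,
                       error_rate = 0, seed = 122)
  aln <- alignments_from_table(rd$truth, tx$transcripts)
  lib <- infer_library(aln, seed = 123)
  expect_equal(lib$orientation, "inward")
  expect_lt(abs(lib$fragment_mean - 400), 3)
  expect_lt(abs(lib$fragment_sd - 50), 3)
  expect_gte(lib$n_sampled, 1000L)
})

test_that("EM reduces to counts without multi-mapping and splits symmetrically", {
  ctg <- ctg2()
  tab <- rbind(do.call(rbind, lapply(1:30, function(i) {
    proper_pair(sprintf("a%02d", i), "c1", i, 400)
  })), do.call(rbind, lapply(1:10, function(i) {
    proper_pair(sprintf("b%02d", i), "c2", i, 400)
  })))
  aln <- alignments_from_table(tab, ctg)
  lib <- infer_library(aln, seed = 1)
  ab <- estimate_abundances(ctg, aln, lib)
  expect_equal(ab$est_fragments[ab$contig_id == "c1"], 30)
  expect_equal(ab$est_fragments[ab$contig_id == "c2"], 10)
  expect_equal(sum(ab$tpm), 1e6, tolerance = 1e-9)

  ## every pair multimaps to the two identical contigs: 50/50 fixed point
  tab_mm <- do.call(rbind, lapply(1:40, function(i) {
    rbind(proper_pair(sprintf("m%02d", i), "c1", i, 400),
          proper_pair(sprintf("m%02d", i), "c2", i, 400))
  }))
  aln_mm <- alignments_from_table(tab_mm, ctg)
  ab_mm <- estimate_abundances(ctg, aln_mm, lib)
  expect_equal(ab_mm$est_fragments, c(20, 20), tolerance = 1e-9)
  expect_equal(sum(ab_mm$est_fragments), 40, tolerance = 1e-9)
})

test_that("EM matches an independent plain-loop reference on a 3-contig toy", {
  ctg <- toy_contigs(c1 = strrep("A", 600), c2 = strrep("C", 800),
                     c3 = strrep("G", 1200))
  ## constructed multi-mappings: 12 unique to c1, 8 split c1/c2, 6 split
  ## c2/c3, 4 split over all three
  rows <- list()
  add <- function(id, contigs) {
    for (cc in contigs) rows[[length(rows) + 1L]] <<-
      proper_pair(id, cc, 5, 400)
  }
  for (i in 1:12) add(sprintf("u%02d", i), "c1")
  for (i in 1:8) add(sprintf("v%02d", i), c("c1", "c2"))
  for (i in 1:6) add(sprintf("w%02d", i), c("c2", "c3"))
  for (i in 1:4) add(sprintf("x%02d", i), c("c1", "c2", "c3"))
  aln <- alignments_from_table(do.call(rbind, rows), ctg)
  lib <- infer_library(aln, seed = 1)
  ab <- estimate_abundances(ctg, aln, lib, tol = 1e-12, max_iter = 10000)

  eff <- pmax(Biostrings::width(ctg) - lib$fragment_mean + 1, 1)
  cands <- c(replicate(12, data.frame(contig = 1L, mult = 1), simplify = FALSE),
             replicate(8, data.frame(contig = 1:2, mult = 1), simplify = FALSE),
             replicate(6, data.frame(contig = 2:3, mult = 1), simplify = FALSE),
             replicate(4, data.frame(contig = 1:3, mult = 1), simplify = FALSE))
  oracle <- naive_em(cands, eff, 3)
  expect_equal(ab$est_fragments, oracle, tolerance = 1e-6)
  expect_equal(sum(ab$est_fragments), 30, tolerance = 1e-9)

  ## EM log-likelihood is non-decreasing along the iteration path
  theta <- rep(1 / 3, 3)
  ll_prev <- em_loglik(cands, theta, eff)
  for (it in 1:50) {
    est <- rep(0, 3)
    for (p in seq_along(cands)) {
      w <- cands[[p]]$mult * theta[cands[[p]]$contig] / eff[cands[[p]]$contig]
      w <- w / sum(w)
      est[cands[[p]]$contig] <- est[cands[[p]]$contig] + w
    }
    theta <- est / length(cands)
    ll <- em_loglik(cands, theta, eff)
    expect_gte(ll, ll_prev - 1e-10)
    ll_prev <- ll
  }
})

test_that("assignment conserves pairs, is deterministic and tracks responsibilities", {
  ctg <- ctg2()
  tab <- rbind(
    do.call(rbind, lapply(1:50, function(i) {
      proper_pair(sprintf("u%03d", i), "c1", i, 400)
    })),
    do.call(rbind, lapply(1:30, function(i) {
      rbind(proper_pair(sprintf("m%03d", i), "c1", i, 400),
            proper_pair(sprintf("m%03d", i), "c2", i, 400))
    })))
  aln <- alignments_from_table(tab, ctg)
  lib <- infer_library(aln, seed = 1)
  ab <- estimate_abundances(ctg, aln, lib)
  a1 <- assign_pairs(aln, ab, seed = 5)
  ## conservation: every mapped pair assigned exactly once
  expect_true(all(!is.na(a1$pairs$assigned_contig[a1$pairs$any_mapped])))
  ## unique placements assigned deterministically
  u <- grepl("^u", a1$pairs$pair_id)
  expect_true(all(a1$pairs$assigned_contig[u] == "c1"))
  ## bit-reproducible under the same seed
  a2 <- assign_pairs(aln, ab, seed = 5)
  expect_identical(a1$pairs$assigned_contig, a2$pairs$assigned_contig)
  expect_identical(a1$pairs$assigned_placement,
                   a2$pairs$assigned_placement)
})

test_that("assignment samples candidates in proportion to responsibilities", {
  ## two candidate contigs with responsibilities ~ (0.999, 0.001)
  len <- 1000L
  ctg <- toy_contigs(big = strrep("A", len), small = strrep("C", len))
  n <- 10000
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(proper_pair(sprintf("m%05d", i), "big", i %% 600, 400),
          proper_pair(sprintf("m%05d", i), "small", i %% 600, 400))
  }))
  ## plus unique pairs pinning abundance onto "big"
  tab <- rbind(tab, do.call(rbind, lapply(1:500, function(i) {
    proper_pair(sprintf("u%05d", i), "big", i %% 600, 400)
  })))
  aln <- alignments_from_table(tab, ctg)
  lib <- infer_library(aln, seed = 1)
  ab <- estimate_abundances(ctg, aln, lib)
  theta <- attr(ab, "theta")
  ## construct the exact responsibility of "big" for a multimapping pair
  r_big <- theta[1] / (theta[1] + theta[2])
  aln <- assign_pairs(aln, ab, seed = 11)
  mm <- grepl("^m", aln$pairs$pair_id)
  frac <- mean(aln$pairs$assigned_contig[mm] == "big")
  expect_gt(frac, r_big - 3 * sqrt(r_big * (1 - r_big) / n))
  expect_lte(frac, 1)
  ## with responsibilities this skewed the binomial bound is tight
  if (r_big > 0.999) expect_gte(frac, 0.996)
})

test_that("collapsed abundances fall back to a uniform draw", {
  ctg <- ctg2()
  tab <- rbind(proper_pair("p1", "c1", 0, 400),
               proper_pair("p1", "c2", 0, 400))
  aln <- alignments_from_table(tab, ctg)
  ab <- data.frame(contig_id = c("c1", "c2"), est_fragments = c(0, 0),
                   tpm = c(0, 0))
  attr(ab, "theta") <- c(0, 0)
  attr(ab, "eff_len") <- c(601, 601)
  counts <- table(vapply(1:200, function(s) {
    assign_pairs(aln, ab, seed = s)$pairs$assigned_contig
  }, ""))
  expect_true(all(c("c1", "c2") %in% names(counts)))
  expect_gt(min(counts) / 200, 0.3)  # roughly uniform
})

test_that("estimated fragments track simulated per-transcript truth", {
  tx <- simulate_transcriptome(50, seed = 31)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 20000,
                       error_rate = 0, seed = 32)
  aln <- alignments_from_table(rd$truth, tx$transcripts)
  lib <- infer_library(aln, seed = 33)
  ab <- estimate_abundances(tx$transcripts, aln, lib)
  truth_counts <- table(factor(rd$truth$contig_id,
                               levels = names(tx$transcripts)))
  ## no multi-mapping here: est_fragments must equal the true counts, and
  ## rank-correlate perfectly
  expect_equal(as.numeric(ab$est_fragments), as.numeric(truth_counts),
               tolerance = 1e-6)
  expect_gt(stats::cor(ab$est_fragments, as.numeric(truth_counts),
                       method = "spearman"), 0.95)
})
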