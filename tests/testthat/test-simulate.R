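test_that("transcriptome generation is reproducible and normalized", {
  a <- simulate_transcriptome(100, seed = 5)
  b <- simulate_transcriptome(100, seed = 5)
  expect_identical(as.character(a$transcripts), as.character(b$transcripts))
  expect_identical(a$abundances, b$abundances)
  expect_equal(length(a$transcripts), 100L)
  expect_equal(sum(a$abundances$abundance), 1, tolerance = 1e-9)
  ## degenerate length distribution
  d <- simulate_transcriptome(10, length_log_mean = log(800),
                              length_log_sd = 0, seed = 5)
  expect_true(all(Biostrings::width(d$transcripts) == 800L))
  ## byte-identical FASTA output under a fixed seed
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$transcripts, p1)
  write_fasta(b$transcripts, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("read simulation respects the fragment model and error bookkeeping", {
  tx <- simulate_transcriptome(20, seed = 6)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 2000,
                       error_rate = 0, seed = 7)
  tr <- rd$truth
  expect_equal(nrow(tr), 2000L)
  ## error-free: all truth edit distances 0
  expect_true(all(tr$m1_nm == 0L) && all(tr$m2_nm == 0L))
  ## inward orientation and coordinates inside the transcript
  expect_true(all(tr$m1_strand == "+") && all(tr$m2_strand == "-"))
  lens <- Biostrings::width(tx$transcripts)[match(tr$contig_id,
                                                  names(tx$transcripts))]
  expect_true(all(tr$m1_start >= 0 & tr$m2_end <= lens))
  frag <- tr$m2_end - tr$m1_start
  expect_true(all(frag >= 200 & frag <= 550))
  ## read sequences match the transcript at the recorded placement
  seqs <- as.character(tx$transcripts)
  i <- match(tr$contig_id, names(tx$transcripts))
  m1_true <- unname(substring(seqs[i], tr$m1_start + 1, tr$m1_end))
  expect_identical(rd$reads1, m1_true)
  m2_true <- unname(substring(seqs[i], tr$m2_start + 1, tr$m2_end))
  rc <- unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(m2_true))))
  expect_identical(rd$reads2, rc)

  ## constant fragment size when sd = 0 (up to transcript-length capping)
  rd0 <- simulate_reads(tx$transcripts, tx$abundances, 500,
                        fragment_sd = 0, error_rate = 0, seed = 8)
  frag0 <- rd0$truth$m2_end - rd0$truth$m1_start
  expect_true(all(frag0 == 400))

  ## injected errors are counted exactly in NM
  rd_e <- simulate_reads(tx$transcripts, tx$abundances, 1500,
                         error_rate = 0.02, seed = 9)
  tr_e <- rd_e$truth
  i <- match(tr_e$contig_id, names(tx$transcripts))
  m1_true <- unname(substring(seqs[i], tr_e$m1_start + 1, tr_e$m1_end))
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, rd_e$reads1, m1_true, USE.NAMES = FALSE)
  expect_identical(as.integer(mism), tr_e$m1_nm)
  expect_gt(sum(tr_e$m1_nm), 0)
})

test_that("per-transcript pair counts follow the sampling weights", {
  tx <- simulate_transcriptome(50, seed = 16)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 20000,
                       error_rate = 0, seed = 17)
  w <- tx$abundances$abundance * Biostrings::width(tx$transcripts)
  w <- w / sum(w)
  expected <- 20000 * w
  observed <- as.numeric(table(factor(rd$truth$contig_id,
                                      levels = names(tx$transcripts))))
  ## multinomial 3-sigma envelope plus slack for tiny expectations
  sd3 <- 3 * sqrt(pmax(expected, 1))
  expect_true(all(abs(observed - expected) <= sd3 + 3))
})

test_that("fastq output is well-formed", {
  tx <- simulate_transcriptome(5, seed = 26)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 50,
                       error_rate = 0.01, seed = 27)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$reads1, paste0(rd$truth$pair_id, "/1"), fq)
  lines <- readLines(fq)
  expect_equal(length(lines), 200L)
  expect_true(all(startsWith(lines[seq(1, 200, 4)], "@")))
  expect_identical(lines[seq(2, 200, 4)], rd$reads1)
  expect_true(all(nchar(lines[seq(4, 200, 4)]) == nchar(rd$reads1)))
})

test_that("chimera construction replaces constituents and records junctions", {
  tx <- simulate_transcriptome(40, seed = 36)
  ## identity when nothing is fused
  ch0 <- make_chimeras(tx$transcripts, tx$abundances, 0)
  expect_identical(names(ch0$transcripts), names(tx$transcripts))

  ch <- make_chimeras(tx$transcripts, tx$abundances, 8,
                      abundance_ratio = 2, pairing = "ratio", seed = 37)
  expect_equal(length(ch$transcripts), 40L - 16L + 8L)
  m <- ch$manifest
  expect_equal(nrow(m), 8L)
  ## constituents removed, fusions present
  expect_false(any(c(m$part1, m$part2) %in% names(ch$transcripts)))
  expect_true(all(m$fusion_id %in% names(ch$transcripts)))
  ## fusion sequence is part1 then part2, junction at part1 length
  f1 <- m$fusion_id[1]
  expect_equal(as.character(ch$transcripts[[f1]]),
               paste0(as.character(tx$transcripts[[m$part1[1]]]),
                      as.character(tx$transcripts[[m$part2[1]]])))
  expect_equal(m$junction[1],
               Biostrings::width(tx$transcripts[m$part1[1]]))
  expect_true(all(m$realized_ratio >= 1))

  ## tolerance flags are consistent with the realized ratios
  expect_identical(m$within_tolerance,
                   abs(log(m$realized_ratio / m$target_ratio)) <=
                     log(1.25))
  ## ratio-1 pairing yields systematically smaller realized ratios than
  ## ratio-8 pairing on the same pool
  ch1 <- make_chimeras(tx$transcripts, tx$abundances, 8,
                       abundance_ratio = 1, pairing = "ratio", seed = 38)
  ch8 <- make_chimeras(tx$transcripts, tx$abundances, 8,
                       abundance_ratio = 8, pairing = "ratio", seed = 38)
  expect_lt(stats::median(ch1$manifest$realized_ratio),
            stats::median(ch8$manifest$realized_ratio))

  ## record count identity at the scale of a realistic transcript set
  big <- simulate_transcriptome(5917, length_log_mean = log(60),
                                length_log_sd = 0.1, min_length = 30,
                                seed = 39)
  chb <- make_chimeras(big$transcripts, big$abundances, 500, seed = 40)
  expect_equal(length(chb$transcripts), 5417L)
})

test_that("lifting truth alignments into fusion coordinates shifts part 2", {
  tx <- simulate_transcriptome(10, seed = 46)
  ch <- make_chimeras(tx$transcripts, tx$abundances, 2, seed = 47)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 2000,
                       error_rate = 0, seed = 48)
  lifted <- lift_to_chimeras(rd$truth, ch$manifest)
  m <- ch$manifest
  for (r in 1:2) {
    from2 <- rd$truth$contig_id == m$part2[r]
    if (any(from2)) {
      expect_equal(lifted$m1_start[from2],
                   rd$truth$m1_start[from2] + m$junction[r])
      expect_true(all(lifted$contig_id[from2] == m$fusion_id[r]))
    }
    from1 <- rd$truth$contig_id == m$part1[r]
    if (any(from1)) {
      expect_equal(lifted$m1_start[from1], rd$truth$m1_start[from1])
    }
  }
  ## lifted truth is a valid alignment input for the fused assembly
  aln <- alignments_from_table(lifted, ch$transcripts)
  expect_equal(nrow(aln$pairs), 2000L)
  expect_true(all(aln$pairs$both_mapped))
})

test_that("assembly corruption and alignment lifting emulate a mapper", {
  tx <- simulate_transcriptome(12, seed = 56)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 4000,
                       error_rate = 0, seed = 57)
  cr <- corrupt_assembly(tx$transcripts,
                         c(insertion = 2, truncation = 2, fusion = 1,
                           duplication = 1), seed = 58)
  man <- cr$manifest
  expect_setequal(unique(man$op),
                  c("insertion", "truncation", "fusion", "duplication"))
  lifted <- lift_alignments(rd$truth, man, alignment_config())
  aln <- alignments_from_table(lifted, cr$contigs)
  expect_equal(nrow(aln$pairs), 4000L)

  ## truncation: no lifted mate extends past the cut
  for (r in which(man$op == "truncation")) {
    id <- man$contig_id[r]
    L <- Biostrings::width(cr$contigs[id])
    plc <- aln$placements
    on_id <- !is.na(plc$m1_contig) & plc$m1_contig == id
    expect_true(all(plc$m1_end[on_id] <= L))
    ## and some pairs lost a mate to the cut
  }
  trunc_ids <- man$contig_id[man$op == "truncation"]
  half <- !aln$pairs$both_mapped & aln$pairs$any_mapped
  expect_gt(sum(half), 0)

  ## insertion: edit distance increased for reads spanning the insert
  ## (duplication placements are appended, so index the original rows)
  lifted_main <- lifted[seq_len(nrow(rd$truth)), ]
  ins <- man[man$op == "insertion", ][1, ]
  src_rows <- rd$truth$contig_id == ins$source_id
  over <- src_rows & rd$truth$m1_start < ins$pos &
    rd$truth$m1_end > ins$pos
  expect_gt(sum(over), 0)
  lift_over <- lifted_main[over, ]
  ok <- !is.na(lift_over$m1_nm)
  expect_true(all(lift_over$m1_nm[ok] > 0))
  ## mates charged beyond the reporting cap are dropped
  expect_true(all(is.na(lift_over$m1_nm) |
                    lift_over$m1_nm <= 30 + 0))

  ## duplication: pairs inside the window gain a second placement
  dup <- man[man$op == "duplication", ][1, ]
  inside <- rd$truth$contig_id == dup$source_id &
    rd$truth$m1_start >= dup$pos &
    rd$truth$m2_end <= dup$pos + dup$length
  if (any(inside)) {
    pid <- rd$truth$pair_id[which(inside)[1]]
    rows <- aln$placements$pair == match(pid, aln$pairs$pair_id)
    expect_equal(sum(rows), 2L)
    expect_setequal(aln$placements$m1_contig[rows],
                    c(dup$source_id, dup$contig_id))
  }
})

test_that("mate-strand shuffling flips exactly the requested fraction", {
  tx <- simulate_transcriptome(5, seed = 66)
  rd <- simulate_reads(tx$transcripts, tx$abundances, 1000,
                       error_rate = 0, seed = 67)
  sh <- shuffle_mate_strands(rd$truth, fraction = 0.3, seed = 68)
  expect_equal(sum(sh$m2_strand != rd$truth$m2_strand), 300L)
  expect_identical(sh$m1_strand, rd$truth$m1_strand)
})
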