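## Synthetic-data generators: transcriptomes with exponentially distributed
## abundances, paired-end reads with a size-selected fragment model and
## ground-truth placements, in-silico transcript fusions (chimeras), and
## assembly corruptions with coordinate lifting of the truth alignments.
## These close the no-external-aligner loop: every scoring stage can be
## exercised end-to-end on alignments the simulator itself emits.

.BASES <- c("A", "C", "G", "T")

.random_seqs <- function(lengths) {
  total <- sum(lengths)
  chars <- sample(.BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  vapply(seq_along(lengths),
         function(i) paste(chars[starts[i]:ends[i]], collapse = ""), "")
}

#' Simulate a transcriptome with exponentially distributed abundances
#'
#' Random nucleotide sequences with log-normal lengths and relative
#' abundances drawn from an exponential distribution and normalized to sum
#' to 1. Lengths below `min_length` are resampled so that every transcript
#' can carry fragments from the default size-selection band.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_log_mean,length_log_sd Parameters of the log-normal length
#'   distribution (defaults `log(1600)` and 0.35: transcripts of roughly
#'   700-4000 nt, about four fragment lengths at the default library, the
#'   ratio typical of real transcriptomes and paired-end inserts).
#' @param abundance_rate Rate of the exponential abundance draw (the
#'   normalized abundances are scale-free in this rate; default 1).
#' @param min_length Minimum transcript length, resampled if violated
#'   (default 250 nt = default fragment mean minus three standard
#'   deviations).
#' @param seed Integer seed; output is byte-reproducible.
#' @return list with `transcripts` (named `DNAStringSet`) and `abundances`
#'   (data.frame `id`, `abundance` summing to 1).
#' @export
simulate_transcriptome <- function(n_transcripts,
                                   length_log_mean = log(1600),
                                   length_log_sd = 0.35,
                                   abundance_rate = 1,
                                   min_length = 250L,
                                   seed = 1L) {
  stopifnot(n_transcripts >= 1L, abundance_rate > 0, min_length >= 1L)
  .with_seed(seed, {
    lens <- as.integer(round(stats::rlnorm(n_transcripts, length_log_mean,
                                           length_log_sd)))
    tries <- 0L
    while (any(bad <- lens < min_length)) {
      tries <- tries + 1L
      if (tries > 1000L) {
        stop("length distribution cannot reach min_length = ", min_length)
      }
      lens[bad] <- as.integer(round(stats::rlnorm(sum(bad), length_log_mean,
                                                  length_log_sd)))
    }
    seqs <- .random_seqs(lens)
    ab <- stats::rexp(n_transcripts, rate = abundance_rate)
    ids <- sprintf("tx%04d", seq_len(n_transcripts))
    tx <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    list(transcripts = tx,
         abundances = data.frame(id = ids, abundance = ab / sum(ab),
                                 stringsAsFactors = FALSE))
  })
}

## vectorized truncated-normal fragment lengths on per-element intervals
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[bad] <- stats::runif(sum(bad), lo[bad], hi[bad])  # degenerate windows
  x
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## inject i.i.d. substitution errors at distinct positions per read;
## vectorized over reads (rounds over the small per-read error count).
## Returns list(seqs, n_err) with n_err the exact injected edit distance.
.add_errors <- function(seqs, read_length, error_rate) {
  n <- length(seqs)
  n_err <- stats::rbinom(n, read_length, error_rate)
  kmax <- max(n_err, 0L)
  if (kmax > 0L) {
    alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    taken <- matrix(NA_integer_, n, kmax)
    for (k in seq_len(kmax)) {
      act <- which(n_err >= k)
      pos <- sample.int(read_length, length(act), replace = TRUE)
      if (k > 1L) {  # redraw collisions with earlier rounds
        repeat {
          clash <- rowSums(taken[act, seq_len(k - 1L), drop = FALSE] == pos,
                           na.rm = TRUE) > 0
          if (!any(clash)) break
          pos[clash] <- sample.int(read_length, sum(clash), replace = TRUE)
        }
      }
      taken[act, k] <- pos
      tmp <- seqs[act]
      cur <- substr(tmp, pos, pos)
      pick <- sample.int(3L, length(act), replace = TRUE)
      substr(tmp, pos, pos) <- alt[cbind(match(cur, rownames(alt)), pick)]
      seqs[act] <- tmp
    }
  }
  list(seqs = seqs, n_err = n_err)
}

#' Simulate paired-end reads with ground-truth alignments
#'
#' Models uniform random fragmentation of transcripts followed by gel size
#' selection: the source transcript of each fragment is chosen with
#' probability proportional to abundance times length (fragment mass),
#' fragment lengths are normal truncated to the selection band
#' `[max(2*read_length, mean - 3 sd), min(mean + 3 sd, transcript length)]`,
#' and fragment start positions are uniform over the transcript.
#' Mates are read inward (mate 1 forward from the fragment
#' start, mate 2 reverse-complement from the fragment end) and substitution
#' errors are injected i.i.d. per base. The truth table records each pair's
#' placement and per-mate injected-substitution count in the alignment
#' interchange schema accepted by [alignments_from_table()].
#'
#' @param transcripts Named `DNAStringSet`.
#' @param abundances data.frame `id`, `abundance` (as from
#'   [simulate_transcriptome()]).
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in nt (default 100).
#' @param fragment_mean,fragment_sd Fragment size-selection target (defaults
#'   400 and 50 nt).
#' @param error_rate Per-base substitution probability (default 0.01).
#' @param seed Integer seed.
#' @return list with `reads1`, `reads2` (character vectors), `truth`
#'   (data.frame in the interchange schema), and the echoed parameters.
#' @export
simulate_reads <- function(transcripts, abundances, n_pairs,
                           read_length = 100L, fragment_mean = 400,
                           fragment_sd = 50, error_rate = 0.01, seed = 1L) {
  stopifnot(n_pairs >= 1L, read_length >= 1L,
            read_length <= fragment_mean, error_rate >= 0, error_rate < 1)
  lens <- Biostrings::width(transcripts)
  ab <- abundances$abundance[match(names(transcripts), abundances$id)]
  if (anyNA(ab)) stop("abundance missing for some transcripts")
  f_lo <- max(2 * read_length, fragment_mean - 3 * fragment_sd)
  usable <- lens >= f_lo
  if (!all(usable)) {
    warning(sum(!usable), " transcript(s) shorter than the minimum ",
            "fragment (", f_lo, " nt) excluded from read simulation")
  }
  if (!any(usable)) stop("no transcript long enough for the fragment model")
  w <- ifelse(usable, ab * lens, 0)
  seqs <- as.character(transcripts)
  .with_seed(seed, {
    ti <- sample.int(length(lens), n_pairs, replace = TRUE, prob = w)
    L <- lens[ti]
    flen <- round(.rtruncnorm(n_pairs, fragment_mean, fragment_sd,
                              rep(f_lo, n_pairs),
                              pmin(fragment_mean + 3 * fragment_sd, L)))
    slack <- L - flen
    s <- as.integer(floor(stats::runif(n_pairs) * (slack + 1)))
    m1 <- unname(substring(seqs[ti], s + 1L, s + read_length))
    m2 <- unname(.revcomp(substring(seqs[ti], s + flen - read_length + 1L,
                                    s + flen)))
    e1 <- .add_errors(m1, read_length, error_rate)
    e2 <- .add_errors(m2, read_length, error_rate)
    truth <- data.frame(
      pair_id = sprintf("p%07d", seq_len(n_pairs)),
      contig_id = names(transcripts)[ti],
      m1_start = s, m1_end = s + read_length, m1_strand = "+",
      m1_nm = e1$n_err,
      m2_start = s + flen - read_length, m2_end = s + flen,
      m2_strand = "-", m2_nm = e2$n_err,
      stringsAsFactors = FALSE)
    list(reads1 = e1$seqs, reads2 = e2$seqs, truth = truth,
         read_length = as.integer(read_length),
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         error_rate = error_rate, seed = as.integer(seed))
  })
}

#' Write simulated reads to FASTQ
#'
#' @param reads Character vector of read sequences.
#' @param ids Read ids (written as `@id`).
#' @param path Output FASTQ path.
#' @param quality_char Constant base-quality character (default `"I"`,
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, ids, path, quality_char = "I") {
  qual <- strrep(quality_char, nchar(reads))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), path)
  invisible(path)
}

#' Fuse transcript pairs head-to-tail into chimeras
#'
#' Selects `2 * n_fusions` transcripts without replacement, pairs them, and
#' concatenates each pair head-to-tail. The fusions replace both their
#' constituents in the returned transcriptome. With `pairing = "random"`
#' (the default) partners are paired uniformly at random and the realized
#' abundance ratio is recorded afterwards; with `pairing = "ratio"` partners
#' are matched greedily so their abundance ratios approximate
#' `abundance_ratio` (recycled across fusions), and pairs that miss the
#' target by more than 25% are flagged in the manifest (not fatal).
#'
#' @param transcripts Named `DNAStringSet`.
#' @param abundances data.frame `id`, `abundance`.
#' @param n_fusions Number of fusions.
#' @param abundance_ratio Target fold-difference(s) `>= 1` between fused
#'   partners (used when `pairing = "ratio"`).
#' @param pairing `"random"` or `"ratio"`.
#' @param seed Integer seed.
#' @return list with `transcripts` (fused transcriptome), `manifest`
#'   (data.frame `fusion_id`, `part1`, `part2`, `junction` = 0-based start
#'   of part2, `abundance1`, `abundance2`, `realized_ratio`, `target_ratio`,
#'   `within_tolerance`).
#' @export
make_chimeras <- function(transcripts, abundances, n_fusions,
                          abundance_ratio = 1,
                          pairing = c("random", "ratio"), seed = 1L) {
  pairing <- match.arg(pairing)
  stopifnot(n_fusions >= 0L, 2L * n_fusions <= length(transcripts),
            all(abundance_ratio >= 1))
  if (n_fusions == 0L) {
    return(list(transcripts = transcripts,
                manifest = data.frame(fusion_id = character(),
                                      part1 = character(),
                                      part2 = character(),
                                      junction = integer(),
                                      abundance1 = numeric(),
                                      abundance2 = numeric(),
                                      realized_ratio = numeric(),
                                      target_ratio = numeric(),
                                      within_tolerance = logical(),
                                      stringsAsFactors = FALSE)))
  }
  ab <- stats::setNames(abundances$abundance, abundances$id)
  target <- rep_len(abundance_ratio, n_fusions)
  .with_seed(seed, {
    chosen <- sample(names(transcripts), 2L * n_fusions)
    if (pairing == "random") {
      p1 <- chosen[seq_len(n_fusions)]
      p2 <- chosen[n_fusions + seq_len(n_fusions)]
    } else {
      ## greedy nearest-ratio matching on the selected pool
      pool <- chosen[order(-ab[chosen])]
      p1 <- character(n_fusions)
      p2 <- character(n_fusions)
      for (i in seq_len(n_fusions)) {
        a <- pool[1L]
        pool <- pool[-1L]
        dev <- abs(log(ab[a] / ab[pool]) - log(target[i]))
        j <- which.min(dev)
        p1[i] <- a
        p2[i] <- pool[j]
        pool <- pool[-j]
      }
    }
    hi <- ifelse(ab[p1] >= ab[p2], p1, p2)
    lo <- ifelse(ab[p1] >= ab[p2], p2, p1)
    realized <- as.numeric(ab[hi] / ab[lo])
    manifest <- data.frame(
      fusion_id = sprintf("fusion%04d", seq_len(n_fusions)),
      part1 = p1, part2 = p2,
      junction = Biostrings::width(transcripts)[match(p1,
                                                      names(transcripts))],
      abundance1 = as.numeric(ab[p1]), abundance2 = as.numeric(ab[p2]),
      realized_ratio = realized,
      target_ratio = target,
      within_tolerance = abs(log(realized / target)) <= log(1.25),
      stringsAsFactors = FALSE)
    fused <- Biostrings::DNAStringSet(stats::setNames(
      paste0(as.character(transcripts[p1]), as.character(transcripts[p2])),
      manifest$fusion_id))
    keep <- setdiff(names(transcripts), c(p1, p2))
    list(transcripts = c(transcripts[keep], fused), manifest = manifest)
  })
}

#' Lift truth alignments from constituent transcripts into fusion coordinates
#'
#' Reads simulated from the original transcripts are re-addressed to the
#' chimeric assembly: alignments to a fusion's first part keep their
#' coordinates, alignments to the second part are shifted by the junction
#' offset. This reproduces the coverage change-point a mapper would report
#' for a chimera without requiring an external aligner.
#'
#' @param truth Truth table from [simulate_reads()].
#' @param manifest Manifest from [make_chimeras()].
#' @return The lifted truth table.
#' @export
lift_to_chimeras <- function(truth, manifest) {
  i1 <- match(truth$contig_id, manifest$part1)
  i2 <- match(truth$contig_id, manifest$part2)
  shift <- ifelse(!is.na(i2), manifest$junction[i2], 0L)
  newid <- ifelse(!is.na(i1), manifest$fusion_id[i1],
                  ifelse(!is.na(i2), manifest$fusion_id[i2],
                         truth$contig_id))
  truth$contig_id <- newid
  for (col in c("m1_start", "m1_end", "m2_start", "m2_end")) {
    truth[[col]] <- truth[[col]] + shift
  }
  truth
}

#' Corrupt an assembly with the canonical error classes
#'
#' Applies the named operations to randomly chosen, disjoint target contigs:
#' `insertion` (random sequence of `ins_length` nt inserted at a random
#' interior position), `truncation` (removal of the 3' `trunc_frac`
#' fraction), `fusion` (two contigs concatenated head-to-tail, replacing
#' both), and `duplication` (a random substring of `dup_frac` of the contig
#' added back as a new redundant contig). The manifest records the ground
#' truth needed to lift alignments and to test score monotonicity.
#'
#' @param contigs Named `DNAStringSet`.
#' @param operations Named integer vector, e.g.
#'   `c(insertion = 5, truncation = 5, fusion = 3, duplication = 4)`.
#' @param ins_length Inserted-sequence length (default 50).
#' @param trunc_frac Fraction of the 3' end removed (default 0.3).
#' @param dup_frac Fraction of the contig copied as a redundant contig
#'   (default 0.6).
#' @param seed Integer seed.
#' @return list with `contigs` (corrupted assembly) and `manifest`
#'   (data.frame `contig_id`, `source_id`, `source2_id`, `op`, `pos`,
#'   `length`).
#' @export
corrupt_assembly <- function(contigs,
                             operations = c(insertion = 0L, truncation = 0L,
                                            fusion = 0L, duplication = 0L),
                             ins_length = 50L, trunc_frac = 0.3,
                             dup_frac = 0.6, seed = 1L) {
  ops <- operations[operations > 0L]
  bad <- setdiff(names(ops),
                 c("insertion", "truncation", "fusion", "duplication"))
  if (length(bad)) stop("unknown corruption operation: ", bad[1L])
  need <- sum(ops) + sum(ops[names(ops) == "fusion"])
  if (need > length(contigs)) stop("not enough contigs for the requested ",
                                   "corruptions")
  .with_seed(seed, {
    pool <- sample(names(contigs))
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    man <- list()
    out <- contigs
    if (!is.na(ops["insertion"]) && ops["insertion"] > 0L) {
      ids <- take(ops[["insertion"]])
      for (id in ids) {
        L <- Biostrings::width(out[id])
        pos <- sample(seq_len(L - 1L), 1L)  # insert after `pos` (0-based pos)
        ins <- paste(sample(.BASES, ins_length, replace = TRUE),
                     collapse = "")
        sq <- as.character(out[[id]])
        out[id] <- Biostrings::DNAStringSet(
          paste0(substr(sq, 1L, pos), ins, substr(sq, pos + 1L, L)))
        man[[length(man) + 1L]] <- data.frame(
          contig_id = id, source_id = id, source2_id = NA_character_,
          op = "insertion", pos = pos, length = ins_length,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.na(ops["truncation"]) && ops["truncation"] > 0L) {
      ids <- take(ops[["truncation"]])
      for (id in ids) {
        L <- Biostrings::width(out[id])
        newlen <- max(1L, as.integer(floor(L * (1 - trunc_frac))))
        out[id] <- Biostrings::DNAStringSet(
          substr(as.character(out[[id]]), 1L, newlen))
        man[[length(man) + 1L]] <- data.frame(
          contig_id = id, source_id = id, source2_id = NA_character_,
          op = "truncation", pos = newlen, length = L - newlen,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.na(ops["fusion"]) && ops["fusion"] > 0L) {
      n <- ops[["fusion"]]
      a <- take(n)
      b <- take(n)
      for (i in seq_len(n)) {
        fid <- sprintf("fused%04d", i)
        junction <- Biostrings::width(out[a[i]])
        fused <- Biostrings::DNAStringSet(stats::setNames(
          paste0(as.character(out[[a[i]]]), as.character(out[[b[i]]])), fid))
        out <- c(out[setdiff(names(out), c(a[i], b[i]))], fused)
        man[[length(man) + 1L]] <- data.frame(
          contig_id = fid, source_id = a[i], source2_id = b[i],
          op = "fusion", pos = junction, length = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (!is.na(ops["duplication"]) && ops["duplication"] > 0L) {
      ids <- take(ops[["duplication"]])
      for (i in seq_along(ids)) {
        id <- ids[i]
        L <- Biostrings::width(out[id])
        dlen <- max(1L, as.integer(floor(L * dup_frac)))
        dstart <- sample(seq_len(L - dlen + 1L), 1L) - 1L  # 0-based
        did <- paste0("dup_", id)
        dup <- Biostrings::DNAStringSet(stats::setNames(
          substr(as.character(out[[id]]), dstart + 1L, dstart + dlen), did))
        out <- c(out, dup)
        man[[length(man) + 1L]] <- data.frame(
          contig_id = did, source_id = id, source2_id = NA_character_,
          op = "duplication", pos = dstart, length = dlen,
          stringsAsFactors = FALSE)
      }
    }
    list(contigs = out, manifest = do.call(rbind, man))
  })
}

#' Lift truth alignments onto a corrupted assembly
#'
#' Re-addresses ground-truth alignments (in original transcript coordinates)
#' to the output of [corrupt_assembly()], emulating what a mapper would
#' report: for an insertion, a mate overlapping the insert keeps its start
#' and is charged one edit per base extending into the insert (and is dropped
#' if that exceeds the edit-distance cap); mates fully right of the insert
#' shift by its length. For a truncation, a mate extending past the cut is
#' unaligned. Fusions shift part-2 coordinates by the junction. Duplications
#' add an extra candidate placement on the duplicate contig for every pair
#' falling inside the copied window.
#'
#' @param truth Truth table from [simulate_reads()].
#' @param manifest Manifest from [corrupt_assembly()].
#' @param cfg An [alignment_config()] supplying the edit-distance cap.
#' @return A lifted truth table (possibly with several rows per pair; rows
#'   where both mates became unaligned keep `contig_id = "*"`).
#' @export
lift_alignments <- function(truth, manifest, cfg = alignment_config()) {
  tr <- truth
  tr$m2_contig <- tr$contig_id
  lift_mate <- function(tab, m, row) {
    st <- paste0(m, "_start"); en <- paste0(m, "_end")
    nm <- paste0(m, "_nm"); sd <- paste0(m, "_strand")
    ct <- if (m == "m1") "contig_id" else "m2_contig"
    hit <- tab[[ct]] == row$source_id
    if (row$op == "insertion") {
      right <- hit & tab[[st]] >= row$pos
      tab[[st]][right] <- tab[[st]][right] + row$length
      tab[[en]][right] <- tab[[en]][right] + row$length
      over <- hit & tab[[st]] < row$pos & tab[[en]] > row$pos
      extra <- pmin(tab[[en]][over] - row$pos, row$length)
      tab[[nm]][over] <- tab[[nm]][over] + extra
      drop <- over & tab[[nm]] > cfg$max_edit_distance
      tab[[st]][drop] <- NA_integer_; tab[[en]][drop] <- NA_integer_
      tab[[nm]][drop] <- NA_integer_; tab[[sd]][drop] <- NA_character_
      tab[[ct]][drop] <- "*"
    } else if (row$op == "truncation") {
      drop <- hit & tab[[en]] > row$pos
      tab[[st]][drop] <- NA_integer_; tab[[en]][drop] <- NA_integer_
      tab[[nm]][drop] <- NA_integer_; tab[[sd]][drop] <- NA_character_
      tab[[ct]][drop] <- "*"
    }
    tab
  }
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    if (row$op %in% c("insertion", "truncation")) {
      tr <- lift_mate(tr, "m1", row)
      tr <- lift_mate(tr, "m2", row)
    } else if (row$op == "fusion") {
      for (part in c("source_id", "source2_id")) {
        shift <- if (part == "source2_id") row$pos else 0L
        for (m in c("m1", "m2")) {
          ct <- if (m == "m1") "contig_id" else "m2_contig"
          hit <- tr[[ct]] == row[[part]]
          for (col in paste0(m, c("_start", "_end"))) {
            tr[[col]][hit] <- tr[[col]][hit] + shift
          }
          tr[[ct]][hit] <- row$contig_id
        }
      }
    } else if (row$op == "duplication") {
      inside <- tr$contig_id == row$source_id & tr$m2_contig == row$source_id &
        !is.na(tr$m1_start) & !is.na(tr$m2_start) &
        pmin(tr$m1_start, tr$m2_start) >= row$pos &
        pmax(tr$m1_end, tr$m2_end) <= row$pos + row$length
      if (any(inside)) {
        extra <- tr[inside, , drop = FALSE]
        for (col in c("m1_start", "m1_end", "m2_start", "m2_end")) {
          extra[[col]] <- extra[[col]] - row$pos
        }
        extra$contig_id <- row$contig_id
        extra$m2_contig <- row$contig_id
        tr <- rbind(tr, extra)
      }
    }
  }
  tr
}

#' Flip the strand of one mate for a fraction of pairs
#'
#' A truth-table corruption used to exercise the order score: pairs with a
#' flipped mate no longer match the library orientation.
#'
#' @param truth Truth table.
#' @param fraction Fraction of pairs to corrupt.
#' @param seed Integer seed.
#' @return The corrupted truth table.
#' @export
shuffle_mate_strands <- function(truth, fraction = 0.5, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  .with_seed(seed, {
    n <- nrow(truth)
    idx <- sample.int(n, round(fraction * n))
    truth$m2_strand[idx] <- ifelse(truth$m2_strand[idx] == "+", "-", "+")
    truth
  })
}
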