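#' Read an assembly or reference transcript set from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the validation the rest of the
#' package relies on: record ids are unique, sequences are upper-cased and
#' non-empty, and ids are truncated at the first whitespace (the usual FASTA
#' description convention).
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no contigs in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- anyDuplicated(names(seqs))
  if (dup) stop("duplicate contig id \"", names(seqs)[dup], "\" in ", path)
  if (any(Biostrings::width(seqs) < 1L)) stop("zero-length contig in ", path)
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write contigs to FASTA
#'
#' @param contigs A named [Biostrings::DNAStringSet] (or named character
#'   vector, which is coerced).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

#' Alignment-processing configuration
#'
#' Reporting limits applied when collecting candidate placements for a read
#' pair, mirroring the reporting contract of a short-read aligner: alignments
#' are kept up to `max_edit_distance` mismatches, at most `max_placements`
#' candidate placements are retained per pair, and placements worse than the
#' best by more than `placement_edit_window` (summed over mates) are dropped.
#'
#' @param max_edit_distance Maximum per-mate edit distance reported (default
#'   30). Also the normalizer of the per-base support statistic.
#' @param max_placements Maximum candidate placements retained per pair
#'   (default 10).
#' @param placement_edit_window Placements whose summed mate edit distance
#'   exceeds the best placement's by more than this are discarded (default 5).
#' @return An object of class `alignment_config`.
#' @export
alignment_config <- function(max_edit_distance = 30L,
                             max_placements = 10L,
                             placement_edit_window = 5L) {
  stopifnot(max_edit_distance >= 1L, max_placements >= 1L,
            placement_edit_window >= 0L,
            placement_edit_window <= max_edit_distance)
  structure(list(max_edit_distance = as.integer(max_edit_distance),
                 max_placements = as.integer(max_placements),
                 placement_edit_window = as.integer(placement_edit_window)),
            class = "alignment_config")
}

#' Construct a pair-alignment set
#'
#' The container every downstream stage consumes. `placements` holds one row
#' per candidate placement of a read pair; `pairs` holds one row per input
#' read pair (including pairs with no alignment at all). Coordinates are
#' 0-based half-open throughout; SAM input is converted on read.
#'
#' @param placements data.frame with columns `pair` (integer row index into
#'   `pairs`), `m1_contig`, `m1_start`, `m1_end`, `m1_strand`, `m1_nm`,
#'   `m2_contig`, `m2_start`, `m2_end`, `m2_strand`, `m2_nm`, `nm_total`.
#'   Unaligned mates carry `NA` in all their fields.
#' @param pairs data.frame with columns `pair_id`, `any_mapped`,
#'   `both_mapped`, `assigned_contig`, `assigned_placement`.
#' @param contigs Optional `DNAStringSet`; when given, placements are
#'   validated against contig ids and bounds.
#' @param cfg An [alignment_config()]; placements are validated against its
#'   edit-distance cap.
#' @return An object of class `pair_alignments`.
#' @export
pair_alignments <- function(placements, pairs, contigs = NULL,
                            cfg = alignment_config()) {
  placements$pair <- as.integer(placements$pair)
  if (!is.null(contigs)) {
    lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    for (m in c("m1", "m2")) {
      cid <- placements[[paste0(m, "_contig")]]
      ok <- is.na(cid)
      bad <- !ok & !(cid %in% names(contigs))
      if (any(bad)) {
        stop("alignment target \"", cid[which(bad)[1L]],
             "\" is not a contig in the assembly")
      }
      st <- placements[[paste0(m, "_start")]]
      en <- placements[[paste0(m, "_end")]]
      aligned <- !is.na(cid)
      if (any(aligned & (st < 0L | en <= st | en > lens[cid]))) {
        stop("mate alignment outside contig bounds")
      }
      nm <- placements[[paste0(m, "_nm")]]
      if (any(aligned & nm > cfg$max_edit_distance)) {
        stop("mate edit distance exceeds max_edit_distance (",
             cfg$max_edit_distance, ")")
      }
    }
  }
  structure(list(placements = placements, pairs = pairs, config = cfg),
            class = "pair_alignments")
}

#' @export
print.pair_alignments <- function(x, ...) {
  cat("pair_alignments:", nrow(x$pairs), "pairs,",
      nrow(x$placements), "candidate placements\n")
  cat("  both mates mapped:", sum(x$pairs$both_mapped),
      "| assigned:", sum(!is.na(x$pairs$assigned_contig)), "\n")
  invisible(x)
}

#' Number of input read pairs in a pair-alignment set
#' @param aln A `pair_alignments` object.
#' @return Integer count, including fully unmapped pairs.
#' @export
n_pairs <- function(aln) nrow(aln$pairs)

## Shared finishing step: per-pair truncation of candidate placements and
## construction of the pairs table. `plc` must already have the 12 canonical
## columns plus pair_id.
.finish_placements <- function(plc, pair_ids_all, cfg) {
  pair_ids_all <- as.character(pair_ids_all)
  if (nrow(plc) > 0L) {
    m1a <- !is.na(plc$m1_contig)
    m2a <- !is.na(plc$m2_contig)
    plc$nm_total <- ifelse(m1a, plc$m1_nm, 0L) + ifelse(m2a, plc$m2_nm, 0L)
    ## truncate: keep best placements within the edit window, up to the cap
    o <- order(match(plc$pair_id, pair_ids_all), plc$nm_total)
    plc <- plc[o, , drop = FALSE]
    grp <- match(plc$pair_id, pair_ids_all)
    first <- !duplicated(grp)
    best <- plc$nm_total[first][cumsum(first)]
    keep <- plc$nm_total <= best + cfg$placement_edit_window
    plc <- plc[keep, , drop = FALSE]
    grp <- grp[keep]
    rank_in_grp <- stats::ave(seq_along(grp), grp, FUN = seq_along)
    plc <- plc[rank_in_grp <= cfg$max_placements, , drop = FALSE]
  }
  pairs <- data.frame(pair_id = pair_ids_all, stringsAsFactors = FALSE)
  pairs$any_mapped <- pairs$pair_id %in% plc$pair_id
  bm <- unique(plc$pair_id[!is.na(plc$m1_contig) & !is.na(plc$m2_contig)])
  pairs$both_mapped <- pairs$pair_id %in% bm
  pairs$assigned_contig <- NA_character_
  pairs$assigned_placement <- NA_integer_
  plc$pair <- match(plc$pair_id, pairs$pair_id)
  plc$pair_id <- NULL
  rownames(plc) <- NULL
  list(placements = plc, pairs = pairs)
}

.placement_cols <- c("pair_id",
                     "m1_contig", "m1_start", "m1_end", "m1_strand", "m1_nm",
                     "m2_contig", "m2_start", "m2_end", "m2_strand", "m2_nm")

#' Read pair alignments from the TSV interchange format
#'
#' The internal alignment interchange format written by the read simulator
#' (and accepted from any producer): one row per candidate placement with
#' columns `pair_id`, `contig_id`, `m1_start`, `m1_end`, `m1_strand`,
#' `m1_nm`, `m2_start`, `m2_end`, `m2_strand`, `m2_nm`, and optionally
#' `m2_contig` when the two mates align to different contigs. Coordinates are
#' 0-based half-open. An unaligned mate has `NA` start/end/nm and strand `*`;
#' a fully unmapped pair is a row with `contig_id` `*`.
#'
#' @param path TSV path.
#' @param contigs Named `DNAStringSet` of the assembly the alignments target.
#' @param cfg An [alignment_config()].
#' @return A [pair_alignments()] object.
#' @export
read_alignments_tsv <- function(path, contigs, cfg = alignment_config()) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         na.strings = c("NA", "")))
  alignments_from_table(tab, contigs, cfg)
}

#' Build pair alignments from an in-memory placement table
#'
#' Same schema as [read_alignments_tsv()] but starting from a data.frame,
#' e.g. the truth table returned by [simulate_reads()].
#'
#' @inheritParams read_alignments_tsv
#' @param tab data.frame of candidate placements.
#' @return A [pair_alignments()] object.
#' @export
alignments_from_table <- function(tab, contigs, cfg = alignment_config()) {
  need <- setdiff(.placement_cols, c("pair_id", "m1_contig"))
  need <- sub("^m1_contig$", "contig_id", need)
  missing_cols <- setdiff(c("pair_id", "contig_id", need), names(tab))
  missing_cols <- setdiff(missing_cols, "m2_contig")
  if (length(missing_cols)) {
    stop("alignment table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$m2_contig)) tab$m2_contig <- tab$contig_id
  plc <- data.frame(pair_id = as.character(tab$pair_id),
                    m1_contig = as.character(tab$contig_id),
                    m1_start = as.integer(tab$m1_start),
                    m1_end = as.integer(tab$m1_end),
                    m1_strand = as.character(tab$m1_strand),
                    m1_nm = as.integer(tab$m1_nm),
                    m2_contig = as.character(tab$m2_contig),
                    m2_start = as.integer(tab$m2_start),
                    m2_end = as.integer(tab$m2_end),
                    m2_strand = as.character(tab$m2_strand),
                    m2_nm = as.integer(tab$m2_nm),
                    stringsAsFactors = FALSE)
  ## normalise unaligned-mate encoding
  plc$m1_contig[plc$m1_contig == "*" | is.na(plc$m1_start)] <- NA_character_
  plc$m2_contig[plc$m2_contig == "*" | is.na(plc$m2_start)] <- NA_character_
  for (m in c("m1", "m2")) {
    un <- is.na(plc[[paste0(m, "_contig")]])
    plc[[paste0(m, "_start")]][un] <- NA_integer_
    plc[[paste0(m, "_end")]][un] <- NA_integer_
    plc[[paste0(m, "_strand")]][un] <- NA_character_
    plc[[paste0(m, "_nm")]][un] <- NA_integer_
  }
  pair_ids_all <- unique(plc$pair_id)
  ## drop rows that are placeholders for unmapped pairs
  plc <- plc[!(is.na(plc$m1_contig) & is.na(plc$m2_contig)), , drop = FALSE]
  parts <- .finish_placements(plc, pair_ids_all, cfg)
  pair_alignments(parts$placements, parts$pairs, contigs, cfg)
}

#' Read pair alignments from SAM/BAM
#'
#' Records must carry the `NM` edit-distance tag and paired-end flags.
#' Multi-mapping placements are collected per (pair, contig): the
#' best-edit-distance alignment of each mate on a contig forms one candidate
#' placement (SAM does not pair up secondary records, so pairing within a
#' target is the only well-defined grouping). SAM 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path Path to a `.bam` or plain-text `.sam` file (SAM text is
#'   converted via [Rsamtools::asBam()]).
#' @param contigs Named `DNAStringSet` of the assembly.
#' @param cfg An [alignment_config()].
#' @param missing_nm Policy when an aligned record lacks the NM tag:
#'   `"error"` (default) or `"zero"` (treat the edit distance as 0).
#' @return A [pair_alignments()] object.
#' @export
read_alignments <- function(path, contigs, cfg = alignment_config(),
                            missing_nm = c("error", "zero")) {
  missing_nm <- match.arg(missing_nm)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = "NM")
  b <- Rsamtools::scanBam(path, param = prm)[[1L]]
  qname <- b$qname
  flag <- b$flag
  mapped <- !bitwAnd(flag, 4L)
  first <- bitwAnd(flag, 64L) > 0L
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(qname))
  if (anyNA(nm[mapped])) {
    if (missing_nm == "error") {
      stop("aligned record without NM tag (pair ",
           qname[mapped & is.na(nm)][1L], "); set missing_nm = \"zero\" ",
           "to treat missing edit distances as 0")
    }
    nm[mapped & is.na(nm)] <- 0L
  }
  rn <- as.character(b$rname)
  bad <- mapped & !(rn %in% names(contigs))
  if (any(bad)) {
    stop("alignment target \"", rn[which(bad)[1L]],
         "\" is not a contig in the assembly")
  }
  width <- rep(NA_integer_, length(qname))
  width[mapped] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[mapped])
  start0 <- b$pos - 1L           # SAM 1-based -> 0-based
  end0 <- start0 + width         # half-open
  rec <- data.frame(pair_id = qname,
                    mate = ifelse(first, "m1", "m2"),
                    contig = ifelse(mapped, rn, NA_character_),
                    start = ifelse(mapped, start0, NA_integer_),
                    end = ifelse(mapped, end0, NA_integer_),
                    strand = ifelse(mapped,
                                    ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                                    NA_character_),
                    nm = ifelse(mapped, nm, NA_integer_),
                    stringsAsFactors = FALSE)
  rec <- rec[is.na(rec$nm) | rec$nm <= cfg$max_edit_distance, , drop = FALSE]
  pair_ids_all <- unique(qname)
  ## best alignment per (pair, mate, contig)
  amap <- rec[!is.na(rec$contig), , drop = FALSE]
  o <- order(amap$pair_id, amap$mate, amap$contig, amap$nm)
  amap <- amap[o, , drop = FALSE]
  keyed <- paste(amap$pair_id, amap$mate, amap$contig, sep = "\r")
  amap <- amap[!duplicated(keyed), , drop = FALSE]
  m1 <- amap[amap$mate == "m1", , drop = FALSE]
  m2 <- amap[amap$mate == "m2", , drop = FALSE]
  key1 <- paste(m1$pair_id, m1$contig, sep = "\r")
  key2 <- paste(m2$pair_id, m2$contig, sep = "\r")
  allk <- union(key1, key2)
  i1 <- match(allk, key1)
  i2 <- match(allk, key2)
  plc <- data.frame(
    pair_id = ifelse(is.na(i1), m2$pair_id[i2], m1$pair_id[i1]),
    m1_contig = m1$contig[i1], m1_start = m1$start[i1],
    m1_end = m1$end[i1], m1_strand = m1$strand[i1], m1_nm = m1$nm[i1],
    m2_contig = m2$contig[i2], m2_start = m2$start[i2],
    m2_end = m2$end[i2], m2_strand = m2$strand[i2], m2_nm = m2$nm[i2],
    stringsAsFactors = FALSE)
  parts <- .finish_placements(plc, pair_ids_all, cfg)
  pair_alignments(parts$placements, parts$pairs, contigs, cfg)
}

#' Write pair alignments to the TSV interchange format
#'
#' @param aln A `pair_alignments` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  plc <- aln$placements
  out <- data.frame(pair_id = aln$pairs$pair_id[plc$pair],
                    contig_id = plc$m1_contig,
                    m1_start = plc$m1_start, m1_end = plc$m1_end,
                    m1_strand = plc$m1_strand, m1_nm = plc$m1_nm,
                    m2_start = plc$m2_start, m2_end = plc$m2_end,
                    m2_strand = plc$m2_strand, m2_nm = plc$m2_nm,
                    m2_contig = plc$m2_contig,
                    stringsAsFactors = FALSE)
  ## carry fully unmapped pairs as placeholder rows so totals round-trip
  un <- aln$pairs$pair_id[!aln$pairs$any_mapped]
  if (length(un)) {
    ph <- out[rep(NA_integer_, length(un)), , drop = FALSE]
    ph$pair_id <- un
    ph$contig_id <- "*"
    out <- rbind(out, ph)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Build per-contig read evidence from assigned pairs
#'
#' For every pair with an assignment, each aligned mate of the assigned
#' placement contributes 1 to the per-base depth and `1 - nm/max_edit_distance`
#' to the per-base support sum over its aligned span. A mate always
#' contributes to the contig it is aligned to (for pairs bridging two
#' contigs, each side receives its own mate).
#'
#' @param contigs Named `DNAStringSet`.
#' @param aln A `pair_alignments` object with assignments set (see
#'   [assign_pairs()]).
#' @param cfg An [alignment_config()]; its `max_edit_distance` normalizes the
#'   support values.
#' @return A named list (one element per contig) of `contig_evidence`
#'   objects: `depth` (integer vector, length = contig length),
#'   `support_sum` (numeric vector), `assigned_pairs` (count of pairs
#'   assigned to the contig).
#' @export
build_evidence <- function(contigs, aln, cfg = aln$config) {
  lens <- Biostrings::width(contigs)
  ids <- names(contigs)
  assigned <- which(!is.na(aln$pairs$assigned_placement))
  bad <- !(aln$pairs$assigned_contig[assigned] %in% ids)
  if (any(bad)) {
    stop("assigned contig \"",
         aln$pairs$assigned_contig[assigned][which(bad)[1L]],
         "\" is not in the assembly")
  }
  plc <- aln$placements[aln$pairs$assigned_placement[assigned], , drop = FALSE]
  mates <- rbind(
    data.frame(contig = plc$m1_contig, start = plc$m1_start,
               end = plc$m1_end, nm = plc$m1_nm, stringsAsFactors = FALSE),
    data.frame(contig = plc$m2_contig, start = plc$m2_start,
               end = plc$m2_end, nm = plc$m2_nm, stringsAsFactors = FALSE))
  mates <- mates[!is.na(mates$contig), , drop = FALSE]
  mates$w <- 1 - mates$nm / cfg$max_edit_distance
  cidx <- match(mates$contig, ids)
  npairs_assigned <- tabulate(match(aln$pairs$assigned_contig[assigned], ids),
                              nbins = length(ids))
  ev <- vector("list", length(ids))
  names(ev) <- ids
  split_rows <- split(seq_len(nrow(mates)), cidx)
  for (i in seq_along(ids)) {
    n <- lens[i]
    rows <- split_rows[[as.character(i)]]
    dd <- numeric(n + 1L)
    ss <- numeric(n + 1L)
    if (length(rows)) {
      st <- mates$start[rows] + 1L   # diff-array positions
      en <- mates$end[rows] + 1L
      dd <- tabulate(st, nbins = n + 1L) - tabulate(en, nbins = n + 1L)
      w <- mates$w[rows]
      ## weighted diff-array via rowsum on event positions
      ev_pos <- c(st, en)
      ev_w <- c(w, -w)
      agg <- rowsum(ev_w, ev_pos)
      ss[as.integer(rownames(agg))] <- agg[, 1L]
    }
    depth <- cumsum(dd)[seq_len(n)]
    support <- cumsum(ss)[seq_len(n)]
    support[depth == 0] <- 0  # guard fp residue on uncovered bases
    ev[[i]] <- structure(list(contig_id = ids[i],
                              depth = as.integer(round(depth)),
                              support_sum = support,
                              assigned_pairs = npairs_assigned[i]),
                         class = "contig_evidence")
  }
  ev
}
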