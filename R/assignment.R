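## Library-model inference and probabilistic assignment of multi-mapping
## read pairs. The evaluation model follows the two-stage strategy of the
## read-mapping contract: fractional EM assignment for abundance estimation,
## then a single sampled all-or-nothing assignment per pair for contig
## evaluation.

## run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

## best same-contig placement per pair (both mates aligned to one contig);
## returns a subset of the placements table, one row per eligible pair
.best_proper_placements <- function(aln) {
  plc <- aln$placements
  same <- !is.na(plc$m1_contig) & !is.na(plc$m2_contig) &
    plc$m1_contig == plc$m2_contig
  plc <- plc[same, , drop = FALSE]
  if (nrow(plc) == 0L) return(plc)
  o <- order(plc$pair, plc$nm_total)
  plc <- plc[o, , drop = FALSE]
  plc[!duplicated(plc$pair), , drop = FALSE]
}

## relative orientation of two aligned mates on one contig
.orientation <- function(s1, st1, s2, st2) {
  left_fwd <- ifelse(s1 <= s2, st1 == "+", st2 == "+")
  right_fwd <- ifelse(s1 <= s2, st2 == "+", st1 == "+")
  ifelse(left_fwd & !right_fwd, "inward",
         ifelse(!left_fwd & right_fwd, "outward", "same-strand"))
}

#' Infer the library-preparation model from a subsample of mapped pairs
#'
#' From a seeded uniform subsample of read pairs whose two mates align to a
#' single contig, determines the dominant relative mate orientation and the
#' mean and standard deviation of the implied fragment size (rightmost mate
#' end minus leftmost mate start). The subsample contains
#' `min(N_same, max(ceiling(fraction * N_mapped), 1000))` pairs so that small
#' libraries are analyzed in full.
#'
#' @param aln A `pair_alignments` object.
#' @param fraction Subsample fraction of mapped pairs (default 0.01).
#' @param seed Integer seed for the subsample.
#' @return An object of class `library_model`: `orientation` (one of
#'   `"inward"`, `"outward"`, `"same-strand"`), `fragment_mean`,
#'   `fragment_sd`, `n_sampled`.
#' @export
infer_library <- function(aln, fraction = 0.01, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  best <- .best_proper_placements(aln)
  if (nrow(best) == 0L) {
    stop("cannot infer library model: no read pair has both mates ",
         "aligned to a single contig")
  }
  n_mapped <- sum(aln$pairs$any_mapped)
  n_target <- max(ceiling(fraction * n_mapped), 1000L)
  n_sub <- min(nrow(best), n_target)
  idx <- .with_seed(seed, sample.int(nrow(best), n_sub))
  sub <- best[idx, , drop = FALSE]
  ori <- .orientation(sub$m1_start, sub$m1_strand, sub$m2_start,
                      sub$m2_strand)
  counts <- table(ori)
  top <- counts[counts == max(counts)]
  if (length(top) > 1L) {
    warning("orientation tie (", paste(names(top), collapse = ", "),
            "); keeping the lexicographically first label")
  }
  orientation <- sort(names(top))[1L]
  frag <- pmax(sub$m1_end, sub$m2_end) - pmin(sub$m1_start, sub$m2_start)
  fsd <- if (n_sub > 1L) stats::sd(frag) else 0
  structure(list(orientation = orientation,
                 fragment_mean = mean(frag),
                 fragment_sd = fsd,
                 n_sampled = n_sub,
                 subsample_fraction = fraction,
                 subsample_seed = as.integer(seed)),
            class = "library_model")
}

#' @export
print.library_model <- function(x, ...) {
  cat(sprintf("library_model: %s, fragment %.1f +/- %.1f nt (n = %d)\n",
              x$orientation, x$fragment_mean, x$fragment_sd, x$n_sampled))
  invisible(x)
}

## candidate (pair, contig) table with multiplicities: one unit per candidate
## placement per distinct contig it touches
.candidates <- function(aln, contig_ids) {
  plc <- aln$placements
  long <- rbind(data.frame(pair = plc$pair, row = seq_len(nrow(plc)),
                           contig = plc$m1_contig, stringsAsFactors = FALSE),
                data.frame(pair = plc$pair, row = seq_len(nrow(plc)),
                           contig = plc$m2_contig, stringsAsFactors = FALSE))
  long <- long[!is.na(long$contig), , drop = FALSE]
  long <- long[!duplicated(paste(long$row, long$contig)), , drop = FALSE]
  cidx <- match(long$contig, contig_ids)
  if (anyNA(cidx)) stop("alignment targets a contig not in the assembly")
  agg <- rowsum(rep(1L, nrow(long)),
                paste(long$pair, cidx, sep = "\r"), reorder = FALSE)
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(pair = as.integer(vapply(key, `[`, "", 1L)),
             contig = as.integer(vapply(key, `[`, "", 2L)),
             mult = as.numeric(agg[, 1L]))
}

## one E-step: responsibilities for each candidate row given theta.
## `grp` is a dense 1..G integer regrouping of cand$pair.
.responsibilities <- function(cand, theta, eff_len,
                              grp = match(cand$pair, unique(cand$pair))) {
  num <- cand$mult * theta[cand$contig] / eff_len[cand$contig]
  d <- rowsum(num, grp)[grp]
  r <- ifelse(d > 0, num / d, NA_real_)
  if (anyNA(r)) {
    ## theta collapsed for every candidate of some pair: uniform fallback
    n <- rowsum(rep(1, nrow(cand)), grp)[grp]
    r[is.na(r)] <- 1 / n[is.na(r)]
  }
  r
}

#' Estimate contig abundances by EM over multi-mapping pairs
#'
#' Fractionally assigns every mapped pair to its candidate contigs:
#' the responsibility of contig `c` for a pair is proportional to
#' `theta_c / efflen_c` for each candidate placement on `c`, where
#' `efflen_c = max(length_c - fragment_mean + 1, 1)` is the effective number
#' of fragment start positions. The M-step sets `theta` proportional to the
#' summed responsibilities; iteration stops when the largest absolute change
#' in `theta` falls below `tol`. `theta` starts uniform.
#'
#' @param contigs Named `DNAStringSet`.
#' @param aln A `pair_alignments` object.
#' @param lib A [infer_library()] model (supplies the fragment mean).
#' @param tol Convergence tolerance on `max |delta theta|` (default 1e-6).
#' @param max_iter Iteration cap (default 1000).
#' @return data.frame with columns `contig_id`, `est_fragments` (expected
#'   pairs, summing to the number of mapped pairs), `tpm` (transcripts per
#'   million, summing to 1e6). The final `theta` and effective lengths are
#'   attached as attributes for downstream sampling.
#' @export
estimate_abundances <- function(contigs, aln, lib, tol = 1e-6,
                                max_iter = 1000L) {
  stopifnot(length(contigs) > 0L, tol > 0)
  ids <- names(contigs)
  eff_len <- pmax(Biostrings::width(contigs) - lib$fragment_mean + 1, 1)
  cand <- .candidates(aln, ids)
  grp <- match(cand$pair, unique(cand$pair))
  n_mapped <- length(unique(cand$pair))
  nc <- length(ids)
  theta <- rep(1 / nc, nc)
  if (n_mapped > 0L) {
    for (it in seq_len(max_iter)) {
      r <- .responsibilities(cand, theta, eff_len, grp)
      est <- numeric(nc)
      agg <- rowsum(r, cand$contig, reorder = FALSE)
      est[as.integer(rownames(agg))] <- agg[, 1L]
      theta_new <- est / n_mapped
      delta <- max(abs(theta_new - theta))
      theta <- theta_new
      if (delta < tol) break
    }
    est_fragments <- theta * n_mapped
  } else {
    est_fragments <- numeric(nc)
  }
  rate <- est_fragments / eff_len
  tpm <- if (sum(rate) > 0) 1e6 * rate / sum(rate) else rep(0, nc)
  out <- data.frame(contig_id = ids, est_fragments = est_fragments,
                    tpm = tpm, stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  attr(out, "eff_len") <- eff_len
  out
}

#' Sample the all-or-nothing assignment of each pair
#'
#' Every mapped pair receives exactly one `assigned_contig`, drawn from its
#' candidate contigs with probability proportional to the final EM
#' responsibilities (abundance over effective length, counted once per
#' candidate placement). Uniquely mapping pairs are therefore assigned
#' deterministically; if the abundance of every candidate collapsed to zero
#' the draw is uniform. The assigned placement on the sampled contig is the
#' candidate with both mates on that contig where possible, best summed edit
#' distance breaking ties.
#'
#' @param aln A `pair_alignments` object.
#' @param abundances Result of [estimate_abundances()].
#' @param seed Integer seed for the categorical draws.
#' @return `aln` with `assigned_contig` and `assigned_placement` filled in
#'   on its `pairs` table.
#' @export
assign_pairs <- function(aln, abundances, seed = 1L) {
  ids <- abundances$contig_id
  theta <- attr(abundances, "theta")
  eff_len <- attr(abundances, "eff_len")
  if (is.null(theta)) {
    theta <- abundances$est_fragments / max(sum(abundances$est_fragments), 1)
    eff_len <- rep(1, length(ids))
  }
  cand <- .candidates(aln, ids)
  if (nrow(cand) == 0L) return(aln)
  r <- .responsibilities(cand, theta, eff_len)
  o <- order(cand$pair)
  cand <- cand[o, , drop = FALSE]
  r <- r[o]
  first <- !duplicated(cand$pair)
  grp <- cumsum(first)
  cum <- cumsum(r)
  run_start <- which(first)
  offset <- c(0, cum[run_start - 1L])[grp]     # restart cumsum per pair
  cum <- cum - offset
  tot <- cum[c(run_start[-1L] - 1L, length(cum))][grp]
  u <- .with_seed(seed, stats::runif(length(run_start)))[grp]
  ok <- cum >= u * tot
  sel <- which(ok)[!duplicated(grp[ok])]       # first ok index per pair
  chosen <- cand[sel, , drop = FALSE]
  ## best placement backing each (pair, contig) choice: prefer a placement
  ## with both mates on that contig, then lowest summed edit distance
  plc <- aln$placements
  long <- rbind(data.frame(pair = plc$pair, row = seq_len(nrow(plc)),
                           contig = plc$m1_contig, stringsAsFactors = FALSE),
                data.frame(pair = plc$pair, row = seq_len(nrow(plc)),
                           contig = plc$m2_contig, stringsAsFactors = FALSE))
  long <- long[!is.na(long$contig), , drop = FALSE]
  long <- long[!duplicated(paste(long$row, long$contig)), , drop = FALSE]
  proper <- !is.na(plc$m1_contig[long$row]) &
    !is.na(plc$m2_contig[long$row]) &
    plc$m1_contig[long$row] == plc$m2_contig[long$row]
  long$cidx <- match(long$contig, ids)
  ord <- order(long$pair, long$cidx, !proper, plc$nm_total[long$row],
               long$row)
  long <- long[ord, , drop = FALSE]
  best <- long[!duplicated(paste(long$pair, long$cidx)), , drop = FALSE]
  hit <- match(paste(chosen$pair, chosen$contig),
               paste(best$pair, best$cidx))
  aln$pairs$assigned_contig[chosen$pair] <- ids[chosen$contig]
  aln$pairs$assigned_placement[chosen$pair] <- best$row[hit]
  aln
}
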