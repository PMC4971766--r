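## Chimera detection by Bayesian change-point segmentation of the coverage
## profile. Per-base depth is encoded as symbols (rounded log2 of depth) in
## an unordered alphabet; the marginal likelihood of modelling the symbol
## sequence with k contiguous segments, each an independent
## Dirichlet-multinomial, is computed exactly by dynamic programming, and the
## posterior mass on k = 1 under a uniform prior over k is the single-
## transcript score s_seg.

#' Encode a coverage profile as a symbol sequence
#'
#' Depth is averaged over consecutive windows of `bin_width` nucleotides (the
#' last window may be short) and each window becomes the symbol
#' `round(log2(mean_depth + 1))`, so zero coverage maps to symbol 0 and the
#' alphabet is unordered thereafter.
#'
#' @param depth Integer vector of per-base read depth.
#' @param bin_width Nucleotides per symbol (default 1).
#' @return An object of class `symbol_profile`: `symbols` (integer vector),
#'   `bin_width`, `alphabet_size` (max symbol + 1, at least 2).
#' @export
encode_profile <- function(depth, bin_width = 1L) {
  stopifnot(length(depth) >= 1L, bin_width >= 1L)
  grp <- (seq_along(depth) - 1L) %/% as.integer(bin_width)
  means <- rowsum(as.numeric(depth), grp)[, 1L] / tabulate(grp + 1L)
  symbols <- as.integer(round(log2(means + 1)))
  structure(list(symbols = symbols,
                 bin_width = as.integer(bin_width),
                 alphabet_size = max(max(symbols) + 1L, 2L)),
            class = "symbol_profile")
}

#' Log marginal likelihood of one segment under a symmetric Dirichlet prior
#'
#' The probability of an ordered symbol sequence with per-symbol counts
#' `counts` after integrating the multinomial parameters against a symmetric
#' Dirichlet(alpha) prior over an alphabet of `length(counts)` symbols:
#' `log( Gamma(A*alpha)/Gamma(m + A*alpha) * prod_a Gamma(c_a + alpha)/Gamma(alpha) )`.
#'
#' @param counts Non-negative integer vector of symbol counts (length = the
#'   alphabet size A; total must be >= 1).
#' @param alpha Dirichlet concentration (> 0, default 1 = uniform).
#' @return Log marginal likelihood (0 for a single-symbol alphabet).
#' @export
segment_log_ml <- function(counts, alpha = 1) {
  stopifnot(alpha > 0, all(counts >= 0), sum(counts) >= 1)
  a <- length(counts)
  lgamma(a * alpha) - lgamma(sum(counts) + a * alpha) +
    sum(lgamma(counts + alpha) - lgamma(alpha))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

## L x L upper-triangular matrix of segment log marginal likelihoods:
## seg[i, j] = log ML of symbols i..j. Computed from prefix counts, one
## vectorized sweep per start position.
.segment_ml_matrix <- function(symbols, A, alpha) {
  L <- length(symbols)
  onehot <- matrix(0L, L, A)
  onehot[cbind(seq_len(L), symbols + 1L)] <- 1L
  prefix <- apply(onehot, 2L, cumsum)          # L x A
  prefix <- rbind(matrix(0L, 1L, A), prefix)   # (L+1) x A
  base <- lgamma(A * alpha) - A * lgamma(alpha)
  seg <- matrix(-Inf, L, L)
  for (i in seq_len(L)) {
    cnt <- prefix[(i + 1L):(L + 1L), , drop = FALSE] -
      rep(prefix[i, ], each = L - i + 1L)
    m <- seq_len(L - i + 1L)                   # segment lengths
    seg[i, i:L] <- base + rowSums(lgamma(cnt + alpha)) -
      lgamma(m + A * alpha)
  }
  seg
}

#' Posterior probability that a coverage profile is a single segment
#'
#' For each k in `1..k_max`, computes the log marginal likelihood of the
#' symbol sequence under a model with k contiguous segments, each an
#' independent Dirichlet-multinomial over the shared unordered alphabet, with
#' a uniform prior over the `choose(L-1, k-1)` change-point placements. The
#' returned `p_single` is the posterior mass on k = 1 under a uniform prior
#' over k, and is used directly as the contig's s_seg component.
#'
#' @param profile A `symbol_profile` from [encode_profile()] (or a bare
#'   integer vector of symbols).
#' @param k_max Largest number of segments considered (default 2: single
#'   transcript versus one fusion junction).
#' @param alpha Dirichlet concentration (default 1).
#' @param alphabet_size Optional alphabet size override; set it to the
#'   assembly-wide maximum symbol + 1 so that scores are comparable across
#'   contigs.
#' @return An object of class `segmentation_result`: `p_single`,
#'   `per_k_log_evidence` (length `k_max`), `posterior_k`, `k_max`, `alpha`.
#' @export
p_single_segment <- function(profile, k_max = 2L, alpha = 1,
                             alphabet_size = NULL) {
  stopifnot(k_max >= 2L, alpha > 0)
  symbols <- if (inherits(profile, "symbol_profile")) profile$symbols
             else as.integer(profile)
  A <- if (!is.null(alphabet_size)) as.integer(alphabet_size)
       else max(max(symbols) + 1L, 2L)
  if (max(symbols) + 1L > A) stop("symbol outside alphabet")
  L <- length(symbols)
  seg <- .segment_ml_matrix(symbols, A, alpha)
  ## dp[k, j]: log sum over placements of k segments covering 1..j of the
  ## product of segment MLs (placement prior applied afterwards)
  logev <- rep(-Inf, k_max)
  prev <- seg[1L, ]                            # k = 1 row: ML(1..j)
  logev[1L] <- prev[L]
  for (k in 2:k_max) {
    cur <- rep(-Inf, L)
    if (L >= k) {
      for (j in k:L) {
        ## last segment i..j, previous k-1 segments cover 1..(i-1)
        i <- k:j
        cur[j] <- .logsumexp(prev[i - 1L] + seg[cbind(i, j)])
      }
    }
    logev[k] <- if (L >= k) cur[L] - lchoose(L - 1L, k - 1L) else -Inf
    prev <- cur
  }
  post <- exp(logev - .logsumexp(logev))
  post <- post / sum(post)
  structure(list(p_single = post[1L],
                 per_k_log_evidence = logev,
                 posterior_k = post,
                 k_max = as.integer(k_max),
                 alpha = alpha,
                 alphabet_size = A),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: p_single = %.4g (k_max = %d, A = %d)\n",
              x$p_single, x$k_max, x$alphabet_size))
  invisible(x)
}
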