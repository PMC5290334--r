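#' Smith-Waterman local alignment with linear gap penalty
#'
#' Optimal local alignment score by dynamic programming with a per-symbol
#' (linear) gap penalty and the usual zero floor, plus the
#' match/mismatch/gap decomposition of one optimal traceback. With the unit
#' weights (+1 / -1 / -1) used for miRNA similarity, the score is
#' `n_match - n_mismatch - n_gap`.
#'
#' @param a,b RNA sequences (canonicalized with [canonicalize_rna()]; an
#'   underscore or other stray character in a printed sequence is stripped).
#' @param match,mismatch,gap alignment weights: `match > 0`,
#'   `mismatch <= 0`, `gap <= 0` (per gap symbol).
#' @return object of class `sw_alignment`: `score`, `n_match`,
#'   `n_mismatch`, `n_gap`, and the aligned subsequences of one optimal
#'   traceback.
#' @examples
#' smith_waterman("ACAGUAGUCUGCACAUUGGUUA", "CACCCGGCUGUGUGCACAUGUGC")$score
#' @export
smith_waterman <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- canonicalize_rna(a); b <- canonicalize_rna(b)
  if (!nzchar(a) || !nzchar(b))
    stop("both sequences must be nonempty after canonicalization",
         call. = FALSE)
  stopifnot(match > 0, mismatch <= 0, gap <= 0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0, H[i, j] + sub[j],
                             H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  # traceback: diagonal preferred, then gap in b, then gap in a
  i <- best[1] - 1; j <- best[2] - 1
  nm <- nmm <- ng <- 0L
  al_a <- al_b <- character(0)
  while (i > 0 || j > 0) {
    h <- H[i + 1, j + 1]
    if (h == 0) break
    if (i > 0 && j > 0 &&
        h == H[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      if (av[i] == bv[j]) nm <- nm + 1L else nmm <- nmm + 1L
      al_a <- c(av[i], al_a); al_b <- c(bv[j], al_b)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && h == H[i, j + 1] + gap) {
      ng <- ng + 1L
      al_a <- c(av[i], al_a); al_b <- c("-", al_b)
      i <- i - 1
    } else {
      ng <- ng + 1L
      al_a <- c("-", al_a); al_b <- c(bv[j], al_b)
      j <- j - 1
    }
  }
  structure(list(score = max(H), n_match = nm, n_mismatch = nmm, n_gap = ng,
                 aligned_a = paste(al_a, collapse = ""),
                 aligned_b = paste(al_b, collapse = "")),
            class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("Smith-Waterman local alignment: score %g (%d match, %d mismatch, %d gap)\n",
              x$score, x$n_match, x$n_mismatch, x$n_gap))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Average pairwise Smith-Waterman score of a sequence set
#'
#' @param seqs character vector of k >= 2 sequences (names kept).
#' @param match,mismatch,gap alignment weights, as in [smith_waterman()].
#' @return list with `mean` (off-diagonal mean of the C(k,2) pair scores)
#'   and `scores` (symmetric score matrix, diagonal NA).
#' @export
pairwise_average <- function(seqs, match = 1, mismatch = -1, gap = -1) {
  k <- length(seqs)
  if (k < 2) stop("need at least two sequences", call. = FALSE)
  S <- matrix(NA_real_, k, k, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    S[i, j] <- S[j, i] <- smith_waterman(seqs[[i]], seqs[[j]], match,
                                         mismatch, gap)$score
  list(mean = mean(S[upper.tri(S)]), scores = S)
}

#' Monte Carlo test of sequence similarity among selected miRNAs
#'
#' Tests whether a selected marker set is more mutually similar (by average
#' pairwise Smith-Waterman score) than random same-size draws from a
#' background pool. Null draws are without replacement; exceedance is
#' inclusive (null mean >= observed mean) and the p-value uses the add-one
#' Monte Carlo formula.
#'
#' @param selected named character vector of k selected sequences.
#' @param pool named character vector of background sequences, disjoint
#'   from `selected`, with length >= k.
#' @param n_trials number of random draws.
#' @param seed integer seed.
#' @param match,mismatch,gap alignment weights.
#' @return list with `observed_mean`, `null_means`, `k_exceed`, `p`.
#' @export
similarity_null_test <- function(selected, pool, n_trials = 1000, seed = 1L,
                                 match = 1, mismatch = -1, gap = -1) {
  k <- length(selected)
  if (k < 2) stop("need at least two selected sequences", call. = FALSE)
  if (length(pool) < k)
    stop("pool smaller than the selected set", call. = FALSE)
  if (length(intersect(canonicalize_rna(selected),
                       canonicalize_rna(pool))))
    stop("pool must be disjoint from the selected set", call. = FALSE)
  observed <- pairwise_average(selected, match, mismatch, gap)$mean
  # precompute all pairwise pool scores once; each draw is then a lookup
  pool <- canonicalize_rna(pool)
  np <- length(pool)
  S <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np)
    S[i, j] <- S[j, i] <- smith_waterman(pool[[i]], pool[[j]], match,
                                         mismatch, gap)$score
  set.seed(seed)
  null_means <- vapply(seq_len(n_trials), function(t) {
    d <- sample.int(np, k)
    M <- S[d, d]
    mean(M[upper.tri(M)])
  }, numeric(1))
  k_exceed <- sum(null_means >= observed)
  list(observed_mean = observed, null_means = null_means,
       k_exceed = k_exceed, p = monte_carlo_pvalue(k_exceed, n_trials))
}
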