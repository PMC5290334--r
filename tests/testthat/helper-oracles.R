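# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately use the most naive formulation of each
# quantity, not the algorithms under test.

# all-offsets substring scan: does q occur in read as a contiguous substring?
brute_substring_count <- function(reads, queries) {
  vapply(queries, function(q) {
    lq <- nchar(q)
    sum(vapply(reads, function(r) {
      lr <- nchar(r)
      if (lr < lq) return(FALSE)
      any(vapply(seq_len(lr - lq + 1), function(i)
        substr(r, i, i + lq - 1) == q, logical(1)))
    }, logical(1)))
  }, numeric(1))
}

# brute-force AUC: explicit pair counting with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force local alignment: exhaustive recursive enumeration of every
# alignment of every pair of substrings (no dynamic programming, no memo);
# feasible only for very short sequences
brute_local_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  glob <- function(i1, i2, j1, j2) {       # best global score of a[i1..i2] vs b[j1..j2]
    if (i1 > i2 && j1 > j2) return(0)
    if (i1 > i2) return(gap * (j2 - j1 + 1))
    if (j1 > j2) return(gap * (i2 - i1 + 1))
    max(glob(i1 + 1, i2, j1 + 1, j2) +
          (if (av[i1] == bv[j1]) match else mismatch),
        glob(i1 + 1, i2, j1, j2) + gap,
        glob(i1, i2, j1 + 1, j2) + gap)
  }
  best <- 0
  n <- length(av); m <- length(bv)
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m)
      best <- max(best, glob(i1, i2, j1, j2))
  best
}

# brute-force Spearman: correlation of explicit average ranks
brute_spearman <- function(x, y) {
  avg_rank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  stats::cor(avg_rank(x), avg_rank(y))
}

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small normalized cohort for classifier-level tests
make_small_z <- function(seed = 1, ...) {
  co <- generate_cohort(cohort_config(seed = seed, ...))
  q <- quotient_normalize(co$counts)
  z <- zscore_reference(q, co$metadata)
  two <- co$metadata$group != "unaffected"
  list(cohort = co, z = z,
       z2 = z[, co$metadata$sample_id[two], drop = FALSE],
       labels = co$metadata$group[two])
}
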