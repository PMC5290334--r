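#' Keep robustly expressed miRNAs
#'
#' A miRNA is robust when its total read count over all samples reaches
#' `min_total` (inclusive, default 10000 — the study's robustness cut that
#' left 137 of 2588 miRNAs).
#'
#' @param counts miRNA x sample matrix.
#' @param min_total minimum row sum.
#' @return character vector of kept miRNA ids, input order preserved.
#' @export
filter_robust <- function(counts, min_total = 10000) {
  stopifnot(nrow(counts) > 0)
  rownames(counts)[rowSums(counts) >= min_total]
}

#' Drop superabundant miRNAs
#'
#' Removes any miRNA holding more than `max_fraction` of the grand total of
#' reads (the study discarded one miRNA carrying 62% of all reads). The rule
#' is per miRNA: several rows each below the cut are all kept.
#'
#' @param counts miRNA x sample matrix.
#' @param max_fraction maximal tolerated share of the grand total (0..1).
#' @return list with `kept` (ids) and `dropped` (named numeric of fractions).
#' @export
drop_superabundant <- function(counts, max_fraction = 0.5) {
  stopifnot(max_fraction > 0, max_fraction < 1)
  frac <- rowSums(counts) / sum(counts)
  drop <- frac > max_fraction
  list(kept = rownames(counts)[!drop], dropped = frac[drop])
}

#' Top-k quotient normalization
#'
#' Divides each sample's counts by the mean of that sample's `top_k` largest
#' counts (default 30), removing per-sample multiplicative scale exactly.
#' Ties at the k-th rank are resolved deterministically (count descending,
#' then miRNA id ascending).
#'
#' @param counts miRNA x sample matrix.
#' @param top_k how many top counts enter the per-sample denominator.
#' @return numeric matrix of quotients, same shape and dimnames.
#' @export
quotient_normalize <- function(counts, top_k = 30) {
  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  q <- counts
  storage.mode(q) <- "double"
  for (s in seq_len(ncol(counts))) {
    x <- counts[, s]
    if (sum(x > 0) < top_k)
      stop(sprintf(
        "sample '%s' has fewer than %d miRNAs with positive counts",
        colnames(counts)[s], top_k), call. = FALSE)
    ord <- order(-x, ids)
    denom <- mean(x[ord[seq_len(top_k)]])
    q[, s] <- x / denom
  }
  q
}

#' Reference-group z-scores
#'
#' Standardizes every miRNA row by the mean and s.d. (n-1 denominator) of
#' that miRNA's quotients over the reference-group samples only, so the
#' reference group has row mean 0 and s.d. 1 and the other groups are read
#' on that scale.
#'
#' @param q quotient matrix (miRNA x sample).
#' @param metadata data frame with `sample_id` and `group` covering the
#'   columns of `q`.
#' @param reference reference group label (default `"unaffected"`).
#' @return z-score matrix, same shape and dimnames, with the reference group
#'   recorded in attribute `reference_group`.
#' @export
zscore_reference <- function(q, metadata, reference = "unaffected") {
  ref <- metadata$sample_id[metadata$group == reference]
  ref <- intersect(colnames(q), ref)
  if (length(ref) < 2)
    stop(sprintf("need >= 2 samples in reference group '%s'", reference),
         call. = FALSE)
  mu <- rowMeans(q[, ref, drop = FALSE])
  sd <- apply(q[, ref, drop = FALSE], 1, stats::sd)
  if (any(sd == 0))
    stop(sprintf("zero reference s.d. for miRNA(s): %s",
                 paste(rownames(q)[sd == 0], collapse = ", ")), call. = FALSE)
  z <- (q - mu) / sd
  attr(z, "reference_group") <- reference
  z
}

#' Concordance of a technical duplicate pair
#'
#' Pearson correlation of two samples' z-score profiles, and its percentile
#' rank among all n(n-1)/2 sample-pair correlations (100 x proportion of
#' pairs with correlation <= the pair's).
#'
#' @param z z-score matrix.
#' @param s1,s2 sample ids of the duplicate pair.
#' @return list with `r`, `percentile`, `n_pairs`.
#' @export
duplicate_concordance <- function(z, s1, s2) {
  for (s in c(s1, s2))
    if (!s %in% colnames(z))
      stop(sprintf("unknown sample id '%s'", s), call. = FALSE)
  if (nrow(z) < 3) stop("need >= 3 miRNAs", call. = FALSE)
  if (stats::sd(z[, s1]) == 0 || stats::sd(z[, s2]) == 0)
    stop("correlation undefined for a constant column", call. = FALSE)
  cm <- stats::cor(z)
  rs <- cm[upper.tri(cm)]
  r <- cm[s1, s2]
  list(r = r, percentile = 100 * mean(rs <= r), n_pairs = length(rs))
}

#' Recompute duplicate concordance after dropping discordant miRNAs
#'
#' Drops the `k` miRNAs with the smallest per-miRNA contribution to the
#' centered cross-product of the two profiles (the most discordant ones) and
#' recomputes the Pearson correlation.
#'
#' @inheritParams duplicate_concordance
#' @param k how many miRNAs to drop.
#' @return list with `r` (recomputed), `dropped` (miRNA ids).
#' @export
drop_least_concordant <- function(z, s1, s2, k = 20) {
  if (k >= nrow(z) - 2)
    stop("k must leave at least 3 miRNAs", call. = FALSE)
  x <- z[, s1]; y <- z[, s2]
  contrib <- (x - mean(x)) * (y - mean(y))
  if (k == 0) return(list(r = stats::cor(x, y), dropped = character(0)))
  drop <- order(contrib)[seq_len(k)]
  list(r = stats::cor(x[-drop], y[-drop]), dropped = rownames(z)[drop])
}

#' Null tail probability of the Pearson correlation
#'
#' One-sided P(R > r) for the correlation of two independent normal vectors
#' of length `dim`, from the exact null via the t-transform with dim - 2
#' degrees of freedom.
#'
#' @param r observed correlation, |r| < 1.
#' @param dim vector length (>= 3).
#' @return upper-tail probability.
#' @seealso [critical_correlation()], its inverse.
#' @export
null_correlation_tail <- function(r, dim) {
  if (abs(r) >= 1 || dim < 3) stop("need |r| < 1 and dim >= 3", call. = FALSE)
  t <- r * sqrt((dim - 2) / (1 - r^2))
  stats::pt(t, df = dim - 2, lower.tail = FALSE)
}

#' Per-subject mean-centering of PCR Cq values
#'
#' Subtracts from each subject's (column's) raw Cq values that subject's own
#' mean over assayed miRNAs, removing gross sample-to-sample bias; column
#' means become 0. Missing values are dropped from a subject's mean.
#'
#' @param cq miRNA x subject matrix of Cq values.
#' @return adjusted matrix (NAs preserved).
#' @export
pcr_mean_center <- function(cq) {
  allna <- apply(cq, 2, function(x) all(is.na(x)))
  if (any(allna))
    stop(sprintf("all-missing Cq column(s): %s",
                 paste(colnames(cq)[allna], collapse = ", ")), call. = FALSE)
  sweep(cq, 2, colMeans(cq, na.rm = TRUE))
}

#' Per-subject Spearman concordance of PCR vs sequencing
#'
#' One Spearman correlation per shared subject over shared miRNAs. Because
#' Cq decreases with abundance, the default orientation correlates -Cq with
#' read counts so that concordance is positive; `orientation = "raw"` uses
#' the Cq values as given.
#'
#' @param cq miRNA x subject Cq matrix.
#' @param counts miRNA x subject count (or quotient) matrix.
#' @param orientation `"neg_cq"` (default) or `"raw"`.
#' @return list with `rho` (named per-subject correlations), `mean`, `sd`,
#'   `min`.
#' @export
cross_platform_concordance <- function(cq, counts,
                                       orientation = c("neg_cq", "raw")) {
  orientation <- match.arg(orientation)
  subjects <- intersect(colnames(cq), colnames(counts))
  mirnas <- intersect(rownames(cq), rownames(counts))
  if (length(mirnas) < 3 || length(subjects) < 1)
    stop("need >= 3 shared miRNAs and >= 1 shared subject", call. = FALSE)
  sgn <- if (orientation == "neg_cq") -1 else 1
  rho <- vapply(subjects, function(s) {
    ok <- !is.na(cq[mirnas, s]) & !is.na(counts[mirnas, s])
    if (sum(ok) < 3)
      stop(sprintf("subject '%s' has < 3 shared assayed miRNAs", s),
           call. = FALSE)
    stats::cor(sgn * cq[mirnas, s][ok], counts[mirnas, s][ok],
               method = "spearman")
  }, numeric(1))
  list(rho = rho, mean = mean(rho), sd = stats::sd(rho), min = min(rho))
}
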