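#' Add-one Monte Carlo p-value
#'
#' `(k + 1) / (n + 1)` where `k` of `n` resampled statistics meet the
#' exceedance criterion against the observed one.
#'
#' @param k_exceed number of exceeding resamples (0..n_trials).
#' @param n_trials number of resamples.
#' @return p-value in \[1/(n+1), 1\].
#' @export
monte_carlo_pvalue <- function(k_exceed, n_trials) {
  if (n_trials < 1 || k_exceed < 0 || k_exceed > n_trials)
    stop("need 0 <= k_exceed <= n_trials, n_trials >= 1", call. = FALSE)
  (k_exceed + 1) / (n_trials + 1)
}

#' Smoothed permutation p-value from a beta fit
#'
#' Fits a beta distribution to the pseudo statistics by maximum likelihood
#' and returns the fitted upper tail beyond the observed statistic — a
#' smooth alternative to the add-one Monte Carlo estimate when the observed
#' value sits at the edge of (or beyond) the permutation sample.
#'
#' @param pseudo numeric vector in (0, 1), length >= 10 (values at exactly
#'   0/1 are nudged inside by machine epsilon).
#' @param true_value observed statistic.
#' @return 1 - CDF(true_value) under the fitted beta.
#' @export
beta_fit_pvalue <- function(pseudo, true_value) {
  if (length(pseudo) < 10)
    stop("need >= 10 pseudo statistics for a beta fit", call. = FALSE)
  eps <- .Machine$double.eps
  x <- pmin(pmax(pseudo, eps), 1 - eps)
  fit <- fitdistrplus::fitdist(x, "beta")
  stats::pbeta(true_value, fit$estimate[["shape1"]], fit$estimate[["shape2"]],
               lower.tail = FALSE)
}

#' Permutation test of the whole CALF training algorithm
#'
#' Class labels of the two compared classes are randomly permuted (class
#' sizes preserved; any reference group stays untouched upstream) and the
#' ENTIRE greedy training — marker selection included — is re-run on each
#' pseudo data set. The pseudo training AUCs form the null for the true
#' training AUC; the Monte Carlo p-value counts strict exceedances
#' (pseudo > true) with the add-one correction, and a smoothed beta-fit
#' p-value is attached.
#'
#' @param z z-score matrix (miRNAs x samples of the two classes).
#' @param labels two-class labels.
#' @param n_perm number of permutations.
#' @param max_markers greedy marker limit per fit.
#' @param seed integer seed.
#' @param pos_class forwarded to [calf()].
#' @return object of class `calf_permutation`: `true_auc`, `pseudo_aucs`,
#'   `p_montecarlo`, `p_beta`, `model` (the true fit), `seed`.
#' @export
permutation_test <- function(z, labels, n_perm = 1000, max_markers = 6,
                             seed = 1L, pos_class = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  model <- calf(z, labels, max_markers = max_markers, pos_class = pos_class)
  set.seed(seed)
  pseudo <- vapply(seq_len(n_perm), function(i) {
    calf(z, sample(labels), max_markers = max_markers,
         pos_class = model$pos_class)$auc
  }, numeric(1))
  k <- sum(pseudo > model$auc)
  structure(list(true_auc = model$auc, pseudo_aucs = pseudo,
                 p_montecarlo = monte_carlo_pvalue(k, n_perm),
                 p_beta = tryCatch(beta_fit_pvalue(pseudo, model$auc),
                                   error = function(e) NA_real_),
                 model = model, seed = seed),
            class = "calf_permutation")
}

#' @export
print.calf_permutation <- function(x, ...) {
  cat(sprintf(
    "CALF permutation test: true AUC %.3f vs %d pseudo AUCs (mean %.3f)\n",
    x$true_auc, length(x$pseudo_aucs), mean(x$pseudo_aucs)))
  cat(sprintf("  Monte Carlo p = %.4g; beta-fit p = %.4g\n",
              x$p_montecarlo, x$p_beta))
  invisible(x)
}

#' Stability selection by repeated subsampling
#'
#' Re-runs the greedy training on many random class-balanced subsets
#' (independent without-replacement draws of `floor(fraction * class size)`
#' samples per class) and tallies how often each miRNA is selected,
#' regardless of sign.
#'
#' @inheritParams permutation_test
#' @param subset_fraction fraction of each class drawn per trial.
#' @param n_trials number of subsampling trials.
#' @return object of class `calf_stability`: `counts` (named integer, one
#'   per miRNA), `n_trials`, `subset_fraction`.
#' @export
stability_selection <- function(z, labels, subset_fraction = 0.8,
                                n_trials = 1000, max_markers = 6, seed = 1L,
                                pos_class = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must have two classes", call. = FALSE)
  idx <- split(seq_along(labels), labels)
  take_n <- vapply(idx, function(i) floor(subset_fraction * length(i)),
                   numeric(1))
  if (any(take_n < 2))
    stop("subset_fraction leaves < 2 samples in a class", call. = FALSE)
  ids <- rownames(z)
  counts <- stats::setNames(integer(nrow(z)), ids)
  set.seed(seed)
  for (t in seq_len(n_trials)) {
    sel <- unlist(lapply(lv, function(g)
      sample(idx[[g]], take_n[[g]])), use.names = FALSE)
    fit <- calf(z[, sel, drop = FALSE], labels[sel],
                max_markers = max_markers, pos_class = pos_class)
    counts[fit$terms$mirna] <- counts[fit$terms$mirna] + 1L
  }
  structure(list(counts = counts, n_trials = n_trials,
                 subset_fraction = subset_fraction, seed = seed),
            class = "calf_stability")
}

#' @export
print.calf_stability <- function(x, ...) {
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  cat(sprintf("CALF stability selection over %d trials (%.0f%% subsets)\n",
              x$n_trials, 100 * x$subset_fraction))
  print(utils::head(top, 10))
  invisible(x)
}

#' Integrate a full-data model with stability selection
#'
#' The integrated classifier keeps the full-data model's markers that were
#' also stably selected (subsampling count >= `min_count`), with weights
#' taken from the full-data fit. The published five-miRNA classifier is this
#' construction with `min_count = 225` of 1000 trials.
#'
#' @param stability a `calf_stability`.
#' @param full_model the `calf` fit on the full data.
#' @param min_count stability threshold (inclusive).
#' @return a `calf` object holding the intersected terms (its trace/AUC are
#'   unset; re-score with [predict.calf()]).
#' @export
integrate_classifier <- function(stability, full_model, min_count = 225) {
  if (!nrow(full_model$terms)) stop("full model is empty", call. = FALSE)
  stable <- names(stability$counts)[stability$counts >= min_count]
  keep <- full_model$terms$mirna %in% stable
  if (!any(keep))
    stop(paste("no overlap between the stable set and the full model;",
               "review min_count"), call. = FALSE)
  out <- full_model
  out$terms <- full_model$terms[keep, , drop = FALSE]
  rownames(out$terms) <- NULL
  out$metric_trace <- numeric(0)
  out$auc <- NA_real_
  out$scores <- NULL
  out$integrated_from <- list(min_count = min_count,
                              n_trials = stability$n_trials)
  out
}

#' AUC distribution of a fixed model over random equal subsets
#'
#' The fitted model (no retraining) is scored on `n_trials` random subsets
#' of `n_per_group` samples per class, summarizing how stable its AUC is
#' under subject resampling.
#'
#' @param model a `calf` fit.
#' @param z z-score matrix.
#' @param labels two-class labels for the columns of `z`.
#' @param n_per_group subset size per class.
#' @param n_trials number of subsets.
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `aucs`.
#' @export
subset_auc_distribution <- function(model, z, labels, n_per_group = 25,
                                    n_trials = 1000, seed = 1L) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must have two classes", call. = FALSE)
  idx <- split(seq_along(labels), labels)
  if (any(vapply(idx, length, numeric(1)) < n_per_group))
    stop("a class is smaller than n_per_group", call. = FALSE)
  scores <- predict(model, z)
  pos <- labels == model$pos_class
  set.seed(seed)
  aucs <- vapply(seq_len(n_trials), function(t) {
    sel <- unlist(lapply(idx, sample, n_per_group), use.names = FALSE)
    auc(scores[sel], pos[sel])
  }, numeric(1))
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' AUC distribution under confound-extremal subsetting
#'
#' Per class, takes all flagged (`mode = "maximize"`) or all unflagged
#' (`mode = "minimize"`) samples first, then fills up to `n_per_group` with
#' a uniform draw from the remainder; the fixed model's AUC is recorded per
#' trial. Comparing the two modes against plain subsetting shows whether a
#' binary confound (e.g. medication) drives the classifier.
#'
#' @inheritParams subset_auc_distribution
#' @param flag logical (or 0/1) per sample.
#' @param mode `"maximize"` or `"minimize"` the number of flagged samples.
#' @return list with `mean`, `sd`, `range`, `aucs`.
#' @export
confound_extremal_subsets <- function(model, z, labels, flag,
                                      n_per_group = 25, n_trials = 1000,
                                      mode = c("maximize", "minimize"),
                                      seed = 1L) {
  mode <- match.arg(mode)
  labels <- as.character(labels)
  flag <- as.logical(flag)
  if (length(flag) != length(labels) || anyNA(flag))
    stop("flag must be defined for every sample", call. = FALSE)
  lv <- sort(unique(labels))
  if (length(lv) != 2) stop("labels must have two classes", call. = FALSE)
  idx <- split(seq_along(labels), labels)
  if (any(vapply(idx, length, numeric(1)) < n_per_group))
    stop("a class is smaller than n_per_group", call. = FALSE)
  scores <- predict(model, z)
  pos <- labels == model$pos_class
  set.seed(seed)
  resample <- function(x, n) x[sample.int(length(x), n)]
  draw_class <- function(i) {
    pref <- if (mode == "maximize") i[flag[i]] else i[!flag[i]]
    rest <- setdiff(i, pref)
    if (length(pref) >= n_per_group)
      resample(pref, n_per_group)
    else c(pref, resample(rest, n_per_group - length(pref)))
  }
  aucs <- vapply(seq_len(n_trials), function(t) {
    sel <- unlist(lapply(idx, draw_class), use.names = FALSE)
    auc(scores[sel], pos[sel])
  }, numeric(1))
  list(mean = mean(aucs), sd = stats::sd(aucs), range = range(aucs),
       aucs = aucs)
}
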