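#' Two-sample Student t-test p-value
#'
#' Two-sided pooled-variance Student t-test (Welch available via
#' `var_equal = FALSE`). A degenerate comparison (zero pooled variance)
#' returns p = 1 with attribute `degenerate = TRUE`, so a greedy search never
#' prefers it.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance Student test when `TRUE` (default).
#' @return two-sided p-value.
#' @export
two_sample_t_pvalue <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (stats::var(x) + stats::var(y) == 0)
    return(structure(1, degenerate = TRUE))
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

# Vectorized pooled t-test p-values for every row of M between two column
# index sets. Zero-variance rows get p = 1.
row_t_pvalues <- function(M, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(M[, idx1, drop = FALSE])
  m2 <- rowMeans(M[, idx2, drop = FALSE])
  ss1 <- rowSums((M[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((M[, idx2, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- rep(1, nrow(M))
  ok <- se > 0
  t <- abs(m1[ok] - m2[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(t, df = n1 + n2 - 2, lower.tail = FALSE)
  p
}

#' Fit a CALF coarse-weight classifier
#'
#' The Coarse Approximation Linear Function: a greedy forward selection of at
#' most `max_markers` miRNAs, each entering the classifier sum with weight +1
#' or -1, chosen to minimize the two-sample Student t-test p-value of the
#' weighted z-score sum between the two classes. Iteration 1 picks the single
#' miRNA with the smallest per-miRNA p-value, oriented so the positive class
#' has the higher mean (the classifier increases with risk); each later
#' iteration tries every unused miRNA with both signs added to the running
#' sum and accepts the best candidate only if it strictly lowers the p-value.
#' Ties are broken by miRNA id (ascending), then weight +1.
#'
#' @param z z-score matrix, miRNAs x samples.
#' @param labels per-sample class labels (two levels); see `pos_class`.
#' @param max_markers maximum number of selected miRNAs (default 6, the
#'   study's full-data limit).
#' @param pos_class which label is the positive (higher-risk) class; default
#'   the second sorted unique label.
#' @param var_equal pooled-variance t-test when `TRUE`.
#' @return an object of class `calf`: list with `terms` (data frame of
#'   `mirna`, `weight`), `metric_trace` (strictly decreasing p-values, one
#'   per accepted term), `auc` (training AUC of the final score), `scores`,
#'   `levels`, `pos_class`, `call`.
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(20 * 30), 20, 30,
#'             dimnames = list(sprintf("mir-%02d", 1:20), NULL))
#' y <- rep(c("a", "b"), each = 15)
#' z[1, y == "b"] <- z[1, y == "b"] + 2
#' fit <- calf(z, y, max_markers = 3)
#' coef(fit)
#' @export
calf <- function(z, labels, max_markers = 6, pos_class = NULL,
                 var_equal = TRUE) {
  stopifnot(is.matrix(z), ncol(z) == length(labels), max_markers >= 1)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("labels must have exactly two classes", call. = FALSE)
  if (is.null(pos_class)) pos_class <- lv[2]
  if (!pos_class %in% lv)
    stop(sprintf("pos_class '%s' not among labels", pos_class), call. = FALSE)
  neg_class <- setdiff(lv, pos_class)
  pos <- which(labels == pos_class); neg <- which(labels == neg_class)
  if (length(pos) < 2 || length(neg) < 2)
    stop("both classes need >= 2 samples", call. = FALSE)
  ids <- rownames(z)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(z)))

  # candidate order used for deterministic tie-breaks: id ascending
  ord <- order(ids)
  terms <- data.frame(mirna = character(0), weight = numeric(0))
  trace <- numeric(0)
  score <- numeric(ncol(z))
  used <- logical(nrow(z))
  best_p <- Inf

  for (iter in seq_len(max_markers)) {
    avail <- ord[!used[ord]]
    if (!length(avail)) break
    cand <- z[avail, , drop = FALSE]
    # candidate running sums with each sign
    Cp <- sweep(cand, 2, score, "+")
    Cm <- sweep(-cand, 2, score, "+")
    p_plus <- row_t_pvalues(Cp, pos, neg)
    p_minus <- row_t_pvalues(Cm, pos, neg)
    if (iter == 1) {
      # orientation convention: sign makes the positive class mean higher;
      # p is sign-invariant for a single marker
      mdiff <- rowMeans(cand[, pos, drop = FALSE]) -
        rowMeans(cand[, neg, drop = FALSE])
      w <- ifelse(mdiff >= 0, 1, -1)
      p <- p_plus  # equals p_minus for a single marker
    } else {
      take_plus <- p_plus <= p_minus  # +1 preferred on exact ties
      w <- ifelse(take_plus, 1, -1)
      p <- ifelse(take_plus, p_plus, p_minus)
    }
    j <- which.min(p)  # avail is id-sorted, so ties go to the lowest id
    if (p[j] >= best_p) break
    best_p <- p[j]
    row <- avail[j]
    used[row] <- TRUE
    score <- score + w[j] * z[row, ]
    terms <- rbind(terms, data.frame(mirna = ids[row], weight = w[j]))
    trace <- c(trace, best_p)
  }

  structure(list(terms = terms, metric_trace = trace,
                 auc = auc(score, labels == pos_class),
                 scores = stats::setNames(score, colnames(z)),
                 levels = c(negative = neg_class, positive = pos_class),
                 pos_class = pos_class, var_equal = var_equal,
                 call = match.call()),
            class = "calf")
}

#' @export
print.calf <- function(x, ...) {
  cat("CALF coarse-weight classifier\n")
  if (!nrow(x$terms)) {
    cat("  <no terms>\n"); return(invisible(x))
  }
  cat(sprintf("  score = %s\n",
              paste(sprintf("%s%s", ifelse(x$terms$weight > 0, "+", "-"),
                            x$terms$mirna), collapse = " ")))
  cat(sprintf("  positive class: %s;  final t-test p = %.3g;  training AUC = %.3f\n",
              x$pos_class, utils::tail(x$metric_trace, 1), x$auc))
  invisible(x)
}

#' @export
summary.calf <- function(object, ...) {
  out <- object$terms
  out$p_after <- object$metric_trace
  structure(list(terms = out, auc = object$auc,
                 levels = object$levels), class = "summary.calf")
}

#' @export
print.summary.calf <- function(x, ...) {
  cat(sprintf("CALF model (%s vs %s), training AUC = %.3f\n",
              x$levels["positive"], x$levels["negative"], x$auc))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' @export
coef.calf <- function(object, ...) {
  stats::setNames(object$terms$weight, object$terms$mirna)
}

#' Score samples with a fitted CALF model
#'
#' The classifier score is the signed sum of the model's z-scores: +1 terms
#' are added, -1 terms subtracted.
#'
#' @param object a `calf` fit.
#' @param z z-score matrix (miRNAs x samples) containing every model miRNA.
#' @param ... unused.
#' @return named numeric vector of per-sample scores.
#' @export
predict.calf <- function(object, z, ...) {
  if (missing(z)) return(object$scores)
  if (!nrow(object$terms))
    return(stats::setNames(numeric(ncol(z)), colnames(z)))
  missing_ids <- setdiff(object$terms$mirna, rownames(z))
  if (length(missing_ids))
    stop(sprintf("miRNA(s) missing from z: %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  w <- coef(object)
  stats::setNames(drop(crossprod(z[names(w), , drop = FALSE], w)),
                  colnames(z))
}

#' @export
plot.calf <- function(x, z = NULL, labels = NULL, ...) {
  scores <- if (is.null(z)) x$scores else predict(x, z)
  if (is.null(labels)) stop("labels required to draw a ROC", call. = FALSE)
  roc <- roc_curve(scores, labels == x$pos_class, bootstrap_n = 0)
  plot(roc$fpr, roc$tpr, type = "s", xlab = "1 - specificity",
       ylab = "sensitivity",
       main = sprintf("CALF ROC (AUC = %.3f)", roc$auc), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(roc)
}

#' Area under the ROC curve (Mann-Whitney, ties count one half)
#'
#' @param scores numeric per-sample scores.
#' @param labels logical (or two-level) per-sample labels; `TRUE` / the
#'   second sorted level is the positive class.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be nonempty", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2)
    stop("labels must have exactly two classes", call. = FALSE)
  as.character(labels) == lv[2]
}

#' Empirical ROC curve with bootstrap confidence band
#'
#' ROC points over all score thresholds; optionally a pointwise percentile
#' bootstrap band on sensitivity at a fixed 1-specificity grid.
#'
#' @param scores,labels as in [auc()].
#' @param bootstrap_n bootstrap resamples for the band (0 skips it).
#' @param alpha band level (default 0.05 for a 95% band).
#' @param seed integer seed for the bootstrap.
#' @return list of class `roc_curve`: `fpr`, `tpr` (from (0,0) to (1,1)),
#'   `thresholds`, `auc`, and (if requested) `band` (data frame `fpr`,
#'   `lower`, `upper`) and `auc_ci` (percentile bootstrap interval for the
#'   AUC).
#' @export
roc_curve <- function(scores, labels, bootstrap_n = 2000, alpha = 0.05,
                      seed = NULL) {
  labels <- as_binary_labels(labels)
  pts <- roc_points(scores, labels)
  out <- list(fpr = pts$fpr, tpr = pts$tpr, thresholds = pts$thr,
              auc = auc(scores, labels))
  if (bootstrap_n > 0) {
    if (!is.null(seed)) set.seed(seed)
    grid <- seq(0, 1, by = 0.02)
    sens <- matrix(NA_real_, bootstrap_n, length(grid))
    aucs <- numeric(bootstrap_n)
    idx1 <- which(labels); idx0 <- which(!labels)
    for (b in seq_len(bootstrap_n)) {
      take <- c(sample(idx1, replace = TRUE), sample(idx0, replace = TRUE))
      p <- roc_points(scores[take], labels[take])
      sens[b, ] <- stats::approx(p$fpr, p$tpr, xout = grid, ties = max,
                                 rule = 2)$y
      aucs[b] <- auc(scores[take], labels[take])
    }
    out$band <- data.frame(
      fpr = grid,
      lower = apply(sens, 2, stats::quantile, alpha / 2),
      upper = apply(sens, 2, stats::quantile, 1 - alpha / 2))
    out$auc_ci <- unname(stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  }
  structure(out, class = "roc_curve")
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  list(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1),
       thr = c(Inf, s[last]))
}

#' AUC of a fitted model between two metadata groups
#'
#' Restricts scores to the samples of two groups and computes the AUC with
#' `group_b` as the positive class (e.g. the published classifier applied to
#' unaffected vs progressed subjects).
#'
#' @param model a `calf` fit.
#' @param z z-score matrix.
#' @param metadata data frame with `sample_id`, `group`.
#' @param group_a negative-class group label.
#' @param group_b positive-class group label.
#' @return AUC.
#' @export
apply_to_groups <- function(model, z, metadata, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (!g %in% metadata$group)
      stop(sprintf("unknown group '%s'", g), call. = FALSE)
  sel <- metadata$group %in% c(group_a, group_b)
  ids <- metadata$sample_id[sel]
  if (sum(metadata$group == group_a) < 2 || sum(metadata$group == group_b) < 2)
    stop("both groups need >= 2 samples", call. = FALSE)
  scores <- predict(model, z[, ids, drop = FALSE])
  auc(scores, metadata$group[sel] == group_b)
}
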