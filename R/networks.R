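#' Critical Pearson correlation for a given null tail probability
#'
#' The one-sided upper `p_tail` quantile of the null distribution of the
#' Pearson correlation of two independent normal vectors of length `n`,
#' obtained by inverting the t-transform with n - 2 degrees of freedom. At
#' `p_tail = 0.001` and `n = 25` this is the 0.5878 edge threshold used for
#' the subsampled networks.
#'
#' @param p_tail upper tail probability, in (0, 0.5).
#' @param n vector length (>= 4).
#' @return correlation threshold r with P(R > r) = p_tail under the null.
#' @seealso [null_correlation_tail()], its inverse.
#' @export
critical_correlation <- function(p_tail, n) {
  if (p_tail <= 0 || p_tail >= 0.5) stop("p_tail must be in (0, 0.5)",
                                         call. = FALSE)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  t <- stats::qt(p_tail, df = n - 2, lower.tail = FALSE)
  t / sqrt(n - 2 + t^2)
}

#' Most abundant miRNAs by total read count
#'
#' @param counts miRNA x sample matrix.
#' @param k how many miRNAs to return.
#' @return ids of the `k` miRNAs with the largest row sums (ties broken by
#'   id ascending).
#' @export
top_abundant_nodes <- function(counts, k = 40) {
  if (k > nrow(counts)) stop("k exceeds the number of miRNAs", call. = FALSE)
  ids <- rownames(counts)
  tot <- rowSums(counts)
  ids[order(-tot, ids)][seq_len(k)]
}

#' Subsample exceedance counts for all miRNA pairs
#'
#' For one group: draws `n_trials` random without-replacement subsets of
#' `subset_size` samples, computes the Pearson correlation of every node
#' pair within each subset, and counts per pair how many trials exceeded
#' `r_threshold` (strictly; one-sided, positive correlations only).
#' Correlations undefined within a subset (constant values) never count as
#' exceedances; their number is recorded in attribute `n_undefined`.
#'
#' @param z z-score matrix.
#' @param metadata data frame with `sample_id`, `group`.
#' @param group group label whose samples are subsampled.
#' @param nodes miRNA ids (rows of `z`) forming the node set.
#' @param subset_size samples drawn per trial.
#' @param n_trials number of trials.
#' @param r_threshold exceedance threshold, e.g.
#'   `critical_correlation(0.001, subset_size)`.
#' @param seed integer seed.
#' @return data frame of class `pair_counts` with columns `mirna_i`,
#'   `mirna_j` (i < j in node order), `count`; parameters kept as
#'   attributes.
#' @export
subsample_exceedance_counts <- function(z, metadata, group, nodes,
                                        subset_size = 25, n_trials = 1000,
                                        r_threshold, seed = 1L) {
  samples <- intersect(colnames(z), metadata$sample_id[metadata$group == group])
  if (length(samples) < subset_size)
    stop(sprintf("group '%s' has %d samples, fewer than subset_size %d",
                 group, length(samples), subset_size), call. = FALSE)
  if (!all(nodes %in% rownames(z)))
    stop("some nodes are not rows of z", call. = FALSE)
  zs <- t(z[nodes, samples, drop = FALSE])  # samples x nodes
  ut <- upper.tri(matrix(0, length(nodes), length(nodes)))
  counts <- integer(sum(ut))
  n_undef <- 0L
  set.seed(seed)
  for (tr in seq_len(n_trials)) {
    sub <- zs[sample.int(length(samples), subset_size), , drop = FALSE]
    r <- suppressWarnings(stats::cor(sub))[ut]
    na <- is.na(r)
    n_undef <- n_undef + sum(na)
    r[na] <- -Inf
    counts <- counts + (r > r_threshold)
  }
  pairs <- which(ut, arr.ind = TRUE)
  out <- data.frame(mirna_i = nodes[pairs[, "row"]],
                    mirna_j = nodes[pairs[, "col"]],
                    count = counts, stringsAsFactors = FALSE)
  structure(out, class = c("pair_counts", "data.frame"),
            group = group, nodes = nodes, subset_size = subset_size,
            n_trials = n_trials, r_threshold = r_threshold,
            n_undefined = n_undef, seed = seed)
}

#' Build a correlation network from exceedance counts
#'
#' Pairs whose exceedance count is strictly greater than `edge_min` become
#' edges; the node set is kept whole, so miRNAs that drop out of a group's
#' network remain representable as isolated nodes.
#'
#' @param pair_counts a `pair_counts` table.
#' @param edge_min minimal exceedance count, strict (default 500 of 1000).
#' @return object of class `correlation_network`: `nodes`, `edges` (data
#'   frame `mirna_i`, `mirna_j`, `count`), `params`.
#' @export
build_network <- function(pair_counts, edge_min = 500) {
  stopifnot(all(c("mirna_i", "mirna_j", "count") %in% names(pair_counts)))
  edges <- pair_counts[pair_counts$count > edge_min, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- attr(pair_counts, "nodes")
  if (is.null(nodes))
    nodes <- sort(unique(c(pair_counts$mirna_i, pair_counts$mirna_j)))
  structure(list(nodes = nodes,
                 edges = as.data.frame(edges)[, c("mirna_i", "mirna_j",
                                                  "count")],
                 params = list(group = attr(pair_counts, "group"),
                               subset_size = attr(pair_counts, "subset_size"),
                               n_trials = attr(pair_counts, "n_trials"),
                               r_threshold = attr(pair_counts, "r_threshold"),
                               edge_min = edge_min)),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("Correlation network (%s): %d nodes, %d edges\n",
              if (is.null(x$params$group)) "?" else x$params$group,
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Compare several group networks over a shared node set
#'
#' @param nets list of `correlation_network` objects on the same node
#'   universe (names used as group labels when set).
#' @return list with `edge_counts`, `densities`, `shared_edges` (pairwise
#'   named list of shared-edge data frames), and `node_presence` (logical
#'   matrix, nodes x networks: does the node touch any edge).
#' @export
compare_networks <- function(nets) {
  stopifnot(length(nets) >= 2)
  labels <- names(nets)
  if (is.null(labels))
    labels <- vapply(nets, function(n)
      if (is.null(n$params$group)) "net" else n$params$group, character(1))
  labels <- make.unique(labels)
  universe <- nets[[1]]$nodes
  for (n in nets)
    if (!setequal(n$nodes, universe))
      stop("networks have inconsistent node universes", call. = FALSE)
  key <- function(n) paste(n$edges$mirna_i, n$edges$mirna_j, sep = "~")
  n_pairs <- choose(length(universe), 2)
  edge_counts <- vapply(nets, function(n) nrow(n$edges), numeric(1))
  shared <- list()
  for (i in seq_along(nets)) for (j in seq_along(nets)) if (i < j) {
    shared[[paste(labels[i], labels[j], sep = " & ")]] <-
      intersect(key(nets[[i]]), key(nets[[j]]))
  }
  presence <- vapply(nets, function(n)
    universe %in% c(n$edges$mirna_i, n$edges$mirna_j), logical(length(universe)))
  dimnames(presence) <- list(universe, labels)
  list(edge_counts = stats::setNames(edge_counts, labels),
       densities = stats::setNames(edge_counts / n_pairs, labels),
       shared_edges = shared,
       node_presence = presence)
}

#' Export a network as a Pajek .net file
#'
#' Writes the standard Pajek dialect: a `*Vertices n` block with 1-based
#' indices and quoted labels, then an `*Edges` block with index pairs and
#' the exceedance count as edge weight.
#'
#' @param net a `correlation_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(net, path) {
  if (!length(net$nodes)) stop("network has no nodes", call. = FALSE)
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  lines <- c(sprintf("*Vertices %d", length(net$nodes)),
             sprintf('%d "%s"', idx, net$nodes),
             "*Edges",
             if (nrow(net$edges))
               sprintf("%d %d %d", idx[net$edges$mirna_i],
                       idx[net$edges$mirna_j], net$edges$count))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file written by [export_pajek()]
#'
#' @param path file path.
#' @return a `correlation_network` (params empty).
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v_at <- grep("^\\*Vertices", lines, ignore.case = TRUE)[1]
  e_at <- grep("^\\*Edges", lines, ignore.case = TRUE)[1]
  if (is.na(v_at) || is.na(e_at))
    stop("not a Pajek .net file", call. = FALSE)
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[v_at],
                      ignore.case = TRUE))
  vlines <- lines[(v_at + 1):(e_at - 1)]
  labels <- sub('^\\s*\\d+\\s+"(.*)".*$', "\\1", vlines)
  ids <- as.integer(sub('^\\s*(\\d+)\\s.*$', "\\1", vlines))
  nodes <- character(n); nodes[ids] <- labels
  edges <- data.frame(mirna_i = character(0), mirna_j = character(0),
                      count = integer(0))
  if (e_at < length(lines)) {
    el <- do.call(rbind, lapply(strsplit(trimws(
      lines[(e_at + 1):length(lines)]), "\\s+"), as.integer))
    edges <- data.frame(mirna_i = nodes[el[, 1]], mirna_j = nodes[el[, 2]],
                        count = if (ncol(el) >= 3) el[, 3] else NA_integer_,
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, params = list()),
            class = "correlation_network")
}
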