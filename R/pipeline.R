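#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the stages end to end: robust-expression filtering and
#' superabundance removal, top-k quotient normalization, reference-group
#' z-scoring, CALF training on nonprogressed vs progressed, permutation and
#' stability validation, the integrated classifier, cross-group application,
#' per-group correlation networks (with Pajek export), and, when sequences
#' are supplied, the sequence-similarity Monte Carlo test on the integrated
#' markers. Per-stage seeds are derived deterministically from the master
#' seed, so any stage can be re-run in isolation and a second full run is
#' bit-identical.
#'
#' @param counts miRNA x sample count matrix (or path to a counts TSV).
#' @param metadata data frame with `sample_id`, `group` (or path to a CSV).
#' @param out_dir directory for artifacts (z-scores TSV, model JSON, Pajek
#'   nets, report JSON); `NULL` writes nothing.
#' @param mirna_fasta optional mature-miRNA FASTA enabling the
#'   sequence-similarity stage.
#' @param params list overriding any of the defaults: `min_total` (10000),
#'   `max_fraction` (0.5), `top_k` (30), `reference` ("unaffected"),
#'   `pos_class` ("progressed"), `neg_class` ("nonprogressed"),
#'   `max_markers` (6), `n_perm` (1000), `n_stability` (1000),
#'   `stability_min_count` (225 of 1000, scaled proportionally when
#'   `n_stability` differs), `subset_auc_n` (25), `network_top_k` (40),
#'   `network_subset_size` (25), `network_trials` (1000), `p_tail` (0.001),
#'   `edge_min` (500 of 1000, scaled with `network_trials`),
#'   `seqsim_trials` (1000).
#' @param seed master integer seed.
#' @return a report list (class `mirisk_report`) with the fitted models and
#'   every key number: training/integrated/cross-group AUCs, permutation
#'   p-values, stability counts, subset-AUC summaries, per-group edge
#'   counts, and the sequence-similarity p-value when run.
#' @export
run_pipeline <- function(counts, metadata, out_dir = NULL,
                         mirna_fasta = NULL, params = list(), seed = 1L) {
  if (is.character(counts)) {
    if (!file.exists(counts))
      stop(sprintf("counts file not found: %s", counts), call. = FALSE)
    counts <- read_counts(counts)
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata))
      stop(sprintf("metadata file not found: %s", metadata), call. = FALSE)
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  p <- utils::modifyList(list(
    min_total = 10000, max_fraction = 0.5, top_k = 30,
    reference = "unaffected", pos_class = "progressed",
    neg_class = "nonprogressed", max_markers = 6,
    n_perm = 1000, n_stability = 1000, stability_min_count = NULL,
    subset_auc_n = 25, network_top_k = 40, network_subset_size = 25,
    network_trials = 1000, p_tail = 0.001, edge_min = NULL,
    seqsim_trials = 1000), params)
  if (is.null(p$stability_min_count))
    p$stability_min_count <- ceiling(225 * p$n_stability / 1000)
  if (is.null(p$edge_min)) p$edge_min <- p$network_trials / 2
  seeds <- stage_seeds(seed)

  # preprocess
  keep <- filter_robust(counts, p$min_total)
  counts_f <- counts[keep, , drop = FALSE]
  sa <- drop_superabundant(counts_f, p$max_fraction)
  counts_f <- counts_f[sa$kept, , drop = FALSE]
  q <- quotient_normalize(counts_f, p$top_k)
  z <- zscore_reference(q, metadata, p$reference)

  # train on the two high-risk classes
  two <- metadata$group %in% c(p$pos_class, p$neg_class)
  ids2 <- metadata$sample_id[two]
  z2 <- z[, ids2, drop = FALSE]
  lab2 <- metadata$group[two]
  model <- calf(z2, lab2, max_markers = p$max_markers,
                pos_class = p$pos_class)

  perm <- permutation_test(z2, lab2, n_perm = p$n_perm,
                           max_markers = p$max_markers,
                           seed = seeds["perm"], pos_class = p$pos_class)
  stab <- stability_selection(z2, lab2, n_trials = p$n_stability,
                              max_markers = p$max_markers,
                              seed = seeds["stability"],
                              pos_class = p$pos_class)
  integrated <- integrate_classifier(stab, model,
                                     min_count = p$stability_min_count)
  int_scores <- predict(integrated, z2)
  int_auc <- auc(int_scores, lab2 == p$pos_class)
  cross_auc <- apply_to_groups(integrated, z, metadata,
                               p$reference, p$pos_class)
  sub <- subset_auc_distribution(integrated, z2, lab2,
                                 n_per_group = min(p$subset_auc_n,
                                                   min(table(lab2))),
                                 n_trials = p$network_trials,
                                 seed = seeds["subset"])

  # per-group correlation networks on the most abundant miRNAs
  nodes <- top_abundant_nodes(counts_f, min(p$network_top_k, nrow(counts_f)))
  r_thr <- critical_correlation(p$p_tail, p$network_subset_size)
  groups <- unique(metadata$group)
  nets <- list()
  for (g in groups) {
    n_g <- sum(metadata$group == g)
    if (n_g < p$network_subset_size) next
    pc <- subsample_exceedance_counts(z, metadata, g, nodes,
                                      subset_size = p$network_subset_size,
                                      n_trials = p$network_trials,
                                      r_threshold = r_thr,
                                      seed = seeds["network"])
    nets[[g]] <- build_network(pc, edge_min = p$edge_min)
  }
  net_cmp <- if (length(nets) >= 2) compare_networks(nets) else NULL

  seqsim <- NULL
  if (!is.null(mirna_fasta) && nrow(integrated$terms) >= 2) {
    mirnas <- load_mature_fasta(mirna_fasta)
    seqs <- stats::setNames(mirnas$sequence, mirnas$id)
    sel_ids <- intersect(integrated$terms$mirna, names(seqs))
    pool <- seqs[setdiff(names(seqs), sel_ids)]
    if (length(sel_ids) >= 2 && length(pool) >= length(sel_ids))
      seqsim <- similarity_null_test(seqs[sel_ids], pool,
                                     n_trials = p$seqsim_trials,
                                     seed = seeds["seqsim"])
  }

  report <- list(
    schema_version = "1.0",
    params = p, seed = seed, stage_seeds = as.list(seeds),
    n_mirnas_robust = length(keep),
    superabundant_dropped = names(sa$dropped),
    model = model, integrated = integrated,
    training_auc = model$auc, integrated_auc = int_auc,
    cross_group_auc = cross_auc,
    p_montecarlo = perm$p_montecarlo, p_beta = perm$p_beta,
    stability_counts = stab$counts,
    subset_auc = list(mean = sub$mean, sd = sub$sd),
    network_edges = vapply(nets, function(n) nrow(n$edges), numeric(1)),
    network_comparison = net_cmp,
    seqsim = seqsim)
  class(report) <- "mirisk_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(data.frame(mirna = rownames(z), z,
                                  check.names = FALSE),
                       file.path(out_dir, "zscores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(terms = model$terms, trace = model$metric_trace,
           auc = model$auc),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    for (g in names(nets))
      export_pajek(nets[[g]], file.path(out_dir, paste0(g, ".net")))
    jsonlite::write_json(report_numbers(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# flat, JSON-friendly summary of a pipeline report
report_numbers <- function(report) {
  list(schema_version = report$schema_version,
       seed = report$seed,
       n_mirnas_robust = report$n_mirnas_robust,
       training_auc = report$training_auc,
       integrated_auc = report$integrated_auc,
       cross_group_auc = report$cross_group_auc,
       p_montecarlo = report$p_montecarlo,
       p_beta = report$p_beta,
       integrated_markers = report$integrated$terms,
       subset_auc = report$subset_auc,
       network_edges = as.list(report$network_edges),
       seqsim_p = if (is.null(report$seqsim)) NULL else report$seqsim$p)
}

#' @export
print.mirisk_report <- function(x, ...) {
  cat("mirisk pipeline report\n")
  cat(sprintf("  robust miRNAs: %d;  training AUC %.3f (perm p = %.3g)\n",
              x$n_mirnas_robust, x$training_auc, x$p_montecarlo))
  cat(sprintf("  integrated classifier: %d markers, AUC %.3f; cross-group AUC %.3f\n",
              nrow(x$integrated$terms), x$integrated_auc, x$cross_group_auc))
  if (length(x$network_edges))
    cat(sprintf("  network edges: %s\n",
                paste(sprintf("%s=%d", names(x$network_edges),
                              as.integer(x$network_edges)), collapse = ", ")))
  if (!is.null(x$seqsim))
    cat(sprintf("  sequence-similarity p = %.3g\n", x$seqsim$p))
  invisible(x)
}

# deterministic per-stage seeds derived from one master seed
stage_seeds <- function(seed) {
  stages <- c("perm", "stability", "subset", "network", "seqsim")
  stats::setNames((as.integer(seed) * 97L + seq_along(stages) * 1009L) %%
                    .Machine$integer.max, stages)
}

#' Write a simulated cohort's files (counts TSV, metadata CSV, truth JSON)
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()] for producing a
#' demo data set on disk.
#'
#' @param dir output directory.
#' @param config a [cohort_config()] (defaults emulate the 27/37/30 x 136
#'   study design).
#' @return the written file paths, invisibly.
#' @export
simulate_cohort_files <- function(dir, config = cohort_config()) {
  write_cohort(generate_cohort(config), dir)
}
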