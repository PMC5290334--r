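#' Configure a synthetic psychosis-risk cohort
#'
#' Builds and validates the full parameter set for [generate_cohort()]. The
#' defaults emulate the design of the leukocyte miRNA study the package
#' targets: 27 unaffected comparison subjects, 37 clinical high-risk subjects
#' who did not progress to psychosis, 30 who did, and 136 robustly expressed
#' miRNAs. A handful of "planted" miRNAs carry a group mean shift in the
#' progressed group (three down, two up by default, mirroring the published
#' five-marker classifier's sign composition), and a per-group latent factor
#' induces within-group miRNA-miRNA correlation whose strength differs by
#' group (weak in progressed subjects, as the study's networks show).
#'
#' @param n_unaffected,n_nonprogressed,n_progressed group sizes (each >= 2).
#' @param n_mirnas number of miRNAs simulated.
#' @param planted data frame with columns `index` (1-based miRNA index),
#'   `sign` (+1 or -1; direction of the shift in the progressed group) and
#'   `effect` (shift magnitude in reference-group s.d. units on the
#'   normalized quotient scale; the log-mean shift is calibrated to deliver
#'   it). `NULL` plants nothing.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts. The default 0.02 is
#'   residual technical overdispersion beyond the biological log-normal
#'   layer; together with `biological_sd = 0.4` the total subject-level CV
#'   is about 43%, typical of robustly expressed leukocyte miRNAs.
#' @param library_size_range length-2 positive range; per-sample library-size
#'   factors are drawn log-uniformly from it and multiply all counts of a
#'   sample.
#' @param correlation_strength named numeric, one value in [0, 1) per group
#'   (`unaffected`, `nonprogressed`, `progressed`): the magnitude of the
#'   latent-factor loading. Pairwise correlations among non-planted miRNAs are
#'   approximately +/- strength^2 (see Details).
#' @param biological_sd per-miRNA biological s.d. on the natural-log scale;
#'   the unit in which planted effects are expressed.
#' @param medicated_prob probability a high-risk subject carries the binary
#'   medication flag (unaffected subjects are never flagged).
#' @param seed integer seed; the same config is bit-reproducible.
#'
#' @details Each miRNA carries a fixed latent-factor loading sign (+/-, drawn
#' once per cohort and reported in `truth`), so within a group pairs of
#' same-sign miRNAs correlate at about +strength^2 and opposite-sign pairs at
#' about -strength^2. A factor loading identically on every miRNA would be a
#' per-sample multiplicative scale, which the top-30 quotient normalization
#' removes exactly; the signed design is what lets planted correlation survive
#' normalization, as real co-regulation structure does. Planted miRNAs get
#' loading 0 so mean shifts and correlation structure stay orthogonal.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_unaffected = 27, n_nonprogressed = 37,
                          n_progressed = 30, n_mirnas = 136,
                          planted = default_planted(n_mirnas),
                          dispersion = 0.02,
                          library_size_range = c(0.5, 2),
                          correlation_strength = c(unaffected = 0.75,
                                                   nonprogressed = 0.75,
                                                   progressed = 0.3),
                          biological_sd = 0.4,
                          medicated_prob = 0.25,
                          seed = 1L) {
  cfg <- list(n_unaffected = n_unaffected, n_nonprogressed = n_nonprogressed,
              n_progressed = n_progressed, n_mirnas = n_mirnas,
              planted = planted, dispersion = dispersion,
              library_size_range = library_size_range,
              correlation_strength = correlation_strength,
              biological_sd = biological_sd,
              medicated_prob = medicated_prob, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default planted markers: five miRNAs, three down / two up in progressed
#' @param n_mirnas number of miRNAs available to plant into (needs >= 5).
#' @param effect common effect size in reference-s.d. units.
#' @return data frame with columns index, sign, effect.
#' @export
default_planted <- function(n_mirnas, effect = 1.2) {
  if (n_mirnas < 5) return(NULL)
  data.frame(index = 1:5, sign = c(-1, -1, -1, 1, 1), effect = effect)
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid cohort config: field '%s' %s", field, msg),
         call. = FALSE)
  for (f in c("n_unaffected", "n_nonprogressed", "n_progressed"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 2)
      stop_cfg(f, "must be a single count >= 2")
  if (!is.numeric(cfg$n_mirnas) || cfg$n_mirnas < 1)
    stop_cfg("n_mirnas", "must be a positive count")
  if (!is.null(cfg$planted)) {
    p <- cfg$planted
    if (!is.data.frame(p) || !all(c("index", "sign", "effect") %in% names(p)))
      stop_cfg("planted", "must be a data frame with index/sign/effect")
    if (anyDuplicated(p$index) || any(p$index < 1 | p$index > cfg$n_mirnas))
      stop_cfg("planted", "indices must be distinct and within 1..n_mirnas")
    if (!all(p$sign %in% c(-1, 1)))
      stop_cfg("planted", "signs must be +1 or -1")
    if (!all(is.finite(p$effect)))
      stop_cfg("planted", "effect sizes must be finite")
  }
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0)
    stop_cfg("dispersion", "must be >= 0")
  r <- cfg$library_size_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
    stop_cfg("library_size_range", "must be an increasing positive pair")
  cs <- cfg$correlation_strength
  if (!all(c("unaffected", "nonprogressed", "progressed") %in% names(cs)))
    stop_cfg("correlation_strength", "needs one value per group")
  if (any(cs < 0 | cs >= 1))
    stop_cfg("correlation_strength", "values must lie in [0, 1)")
  if (!is.numeric(cfg$biological_sd) || cfg$biological_sd <= 0)
    stop_cfg("biological_sd", "must be positive")
  invisible(cfg)
}

#' Generate a synthetic miRNA-seq cohort
#'
#' Draws a miRNA x sample matrix of negative-binomial read counts on a
#' log-normal latent mean: per-miRNA base abundances span roughly two orders
#' of magnitude, a per-group latent factor with signed loadings induces
#' within-group correlation, planted miRNAs have their log-mean shifted by
#' `sign * effect * biological_sd` in the progressed group, and a per-sample
#' library-size factor (drawn log-uniformly) multiplies every count of a
#' sample so that quotient normalization can remove it exactly.
#'
#' @param config a [cohort_config()].
#' @return an object of class `synthetic_cohort`: list with `counts` (integer
#'   matrix, miRNAs x samples, dimnames set), `metadata` (data frame with
#'   `sample_id`, `group`, `medicated`), and `truth` (planted triples, the
#'   correlation strengths used, per-miRNA loading signs, library factors).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  set.seed(config$seed)
  m <- config$n_mirnas
  sizes <- c(unaffected = config$n_unaffected,
             nonprogressed = config$n_nonprogressed,
             progressed = config$n_progressed)
  n <- sum(sizes)
  group <- rep(names(sizes), times = sizes)
  sample_id <- sprintf("S%03d", seq_len(n))
  mirna_id <- sprintf("mir-%03d", seq_len(m))

  log_base <- stats::runif(m, log(50), log(5000))
  load_sign <- sample(c(-1, 1), m, replace = TRUE)
  planted_idx <- if (is.null(config$planted)) integer(0) else config$planted$index
  load_sign[planted_idx] <- 0

  # Planted log-mean shifts are calibrated so the progressed-vs-unshifted
  # contrast equals sign * effect in pooled-s.d. units (Cohen's d) on the
  # normalized count scale. A log-mean shift delta multiplies the group mean
  # (and, the latent being log-normal, the group s.d.) by exp(delta), so the
  # calibration solves  exp(d) - 1 = effect * CV * sqrt(w1 + w2 exp(2 d))
  # with CV ~ sqrt(exp(sd^2) (1 + dispersion) - 1) and w1, w2 the pooled
  # degree-of-freedom weights of the two compared groups. Without this, a
  # fold-change up and an equal fold-change down would differ sharply in
  # detectability (the up-shifted group's variance inflates with its mean).
  shift <- numeric(m)
  if (length(planted_idx)) {
    cv <- sqrt(exp(config$biological_sd^2) * (1 + config$dispersion) - 1)
    n1 <- config$n_nonprogressed; n2 <- config$n_progressed
    w1 <- (n1 - 1) / (n1 + n2 - 2); w2 <- (n2 - 1) / (n1 + n2 - 2)
    shift[planted_idx] <- vapply(
      config$planted$sign * config$planted$effect,
      function(d_target) {
        f <- function(delta)
          expm1(delta) - d_target * cv * sqrt(w1 + w2 * exp(2 * delta))
        tryCatch(stats::uniroot(f, c(-20, 20), tol = 1e-10)$root,
                 error = function(e)
                   stop(paste("invalid cohort config: field 'planted' has an",
                              "effect too large to deliver at this",
                              "dispersion/biological_sd"), call. = FALSE))
      }, numeric(1))
  }

  lr <- log(config$library_size_range)
  lib <- exp(stats::runif(n, lr[1], lr[2]))
  f <- stats::rnorm(n)                       # per-sample latent factor
  a <- config$correlation_strength[group]    # loading magnitude by group

  counts <- matrix(0L, m, n, dimnames = list(mirna_id, sample_id))
  sig <- config$biological_sd
  for (s in seq_len(n)) {
    x <- load_sign * a[s] * f[s] +
      sqrt(1 - (abs(load_sign) * a[s])^2) * stats::rnorm(m)
    lmu <- log_base + sig * x + if (group[s] == "progressed") shift else 0
    mu <- lib[s] * exp(lmu)
    counts[, s] <- as.integer(if (config$dispersion > 0)
      stats::rnbinom(m, mu = mu, size = 1 / config$dispersion)
    else stats::rpois(m, mu))
  }

  medicated <- ifelse(group == "unaffected", 0L,
                      stats::rbinom(n, 1, config$medicated_prob))
  metadata <- data.frame(sample_id = sample_id, group = group,
                         medicated = medicated, stringsAsFactors = FALSE)
  truth <- list(planted = config$planted,
                correlation_strength = config$correlation_strength,
                loading_sign = stats::setNames(load_sign, mirna_id),
                library_factor = stats::setNames(lib, sample_id),
                biological_sd = config$biological_sd)
  structure(list(counts = counts, metadata = metadata, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic miRNA cohort: %d miRNAs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$metadata$group)),
                            as.integer(table(x$metadata$group))),
                    collapse = ", ")))
  np <- if (is.null(x$truth$planted)) 0 else nrow(x$truth$planted)
  cat(sprintf("  planted markers: %d; seed %d\n", np, x$config$seed))
  invisible(x)
}

#' Simulate a technical duplicate of one sample
#'
#' Returns a new count column whose log-counts equal the original sample's
#' plus iid normal noise of the stated s.d., rounded back to nonnegative
#' integers. With `noise_sd = 0` the column is returned unchanged. Used to
#' exercise the duplicate-concordance QC of the normalization stage.
#'
#' @param cohort a `synthetic_cohort`.
#' @param sample_id which sample to duplicate.
#' @param noise_sd s.d. of the log-scale technical noise (>= 0).
#' @param seed integer seed.
#' @return integer vector of counts, named by miRNA.
#' @export
generate_technical_duplicate <- function(cohort, sample_id, noise_sd = 0.2,
                                         seed = 1L) {
  if (!sample_id %in% colnames(cohort$counts))
    stop(sprintf("unknown sample id '%s'", sample_id), call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  x <- cohort$counts[, sample_id]
  if (noise_sd == 0) return(x)
  set.seed(seed)
  y <- round(exp(log(pmax(x, 0.5)) + stats::rnorm(length(x), 0, noise_sd)))
  y[x == 0] <- 0L
  stats::setNames(as.integer(pmax(y, 0)), rownames(cohort$counts))
}

#' Generate synthetic small-RNA reads embedding known miRNAs
#'
#' Each read contains exactly one sampled mature miRNA sequence at a random
#' offset, padded with random flanking bases; flanks are rejection-sampled so
#' the finished read contains no accidental exact match to any other miRNA in
#' the list (nor a second occurrence of the embedded one). Sampling of which
#' miRNA to embed is proportional to `abundances`.
#'
#' @param mirnas data frame with columns `id`, `sequence` (RNA alphabet), as
#'   returned by [load_mature_fasta()].
#' @param abundances nonnegative weights, one per miRNA, not all zero.
#' @param n_reads number of reads to generate.
#' @param read_length common read length; must be >= the longest miRNA.
#' @param seed integer seed.
#' @return character vector of reads (RNA alphabet), with the embedded miRNA
#'   id as names.
#' @export
generate_reads <- function(mirnas, abundances, n_reads, read_length,
                           seed = 1L) {
  stopifnot(is.data.frame(mirnas), nrow(mirnas) >= 1)
  if (length(abundances) != nrow(mirnas))
    stop("one abundance per miRNA required", call. = FALSE)
  if (any(abundances < 0) || all(abundances == 0))
    stop("abundances must be nonnegative and not all zero", call. = FALSE)
  maxlen <- max(nchar(mirnas$sequence))
  if (read_length < maxlen)
    stop(sprintf("read_length %d shorter than longest miRNA (%d nt)",
                 read_length, maxlen), call. = FALSE)
  if (n_reads == 0) return(character(0))
  set.seed(seed)
  alphabet <- c("A", "C", "G", "U")
  pick <- sample.int(nrow(mirnas), n_reads, replace = TRUE,
                     prob = abundances / sum(abundances))
  reads <- character(n_reads)
  for (r in seq_len(n_reads)) {
    s <- mirnas$sequence[pick[r]]
    pad <- read_length - nchar(s)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("could not place a read without stray matches; ",
             "miRNA sequences may be nested substrings", call. = FALSE)
      off <- if (pad > 0) sample.int(pad + 1, 1) - 1L else 0L
      left <- paste(sample(alphabet, off, replace = TRUE), collapse = "")
      right <- paste(sample(alphabet, pad - off, replace = TRUE), collapse = "")
      read <- paste0(left, s, right)
      # reject reads with any stray exact match (other miRNAs, or a second
      # occurrence of the embedded one)
      hits <- vapply(mirnas$sequence, function(q)
        length(gregexpr(q, read, fixed = TRUE)[[1]]) *
          (regexpr(q, read, fixed = TRUE) > 0), numeric(1))
      want <- as.numeric(seq_len(nrow(mirnas)) == pick[r])
      # embedded miRNA may match elsewhere only if identical substring occurs
      if (all(hits == want)) break
    }
    reads[r] <- read
  }
  stats::setNames(reads, mirnas$id[pick])
}

#' Write reads as FASTQ (dummy quality "I")
#' @param reads character vector from [generate_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids, "_", seq_along(reads)),
                           unname(reads), "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort to disk (counts TSV, metadata CSV, truth JSON)
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return named list of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "metadata.csv"),
                truth = file.path(dir, "truth.json"))
  write_counts(cohort$counts, paths$counts)
  utils::write.csv(cohort$metadata, paths$metadata, row.names = FALSE)
  truth <- cohort$truth
  truth$correlation_strength <- as.list(truth$correlation_strength)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
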