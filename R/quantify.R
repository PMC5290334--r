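#' Canonicalize an RNA sequence string
#'
#' Uppercases, strips any character outside the RNA alphabet (stray
#' underscores, whitespace and the like), and converts T to U.
#'
#' @param x character vector of sequences.
#' @return character vector over {A, C, G, U}.
#' @export
canonicalize_rna <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  gsub("[^ACGU]", "", x)
}

#' Load mature miRNA sequences from FASTA
#'
#' Reads a miRBase-mature-style FASTA; the id is the first
#' whitespace-delimited token of each header, sequences are canonicalized to
#' the RNA alphabet (T converted to U). Duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `sequence`; zero rows for an empty
#'   file.
#' @export
load_mature_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(id = character(0),
                                        sequence = character(0)))
  hdr <- grepl("^>", lines)
  if (!hdr[1])
    stop(sprintf("malformed FASTA: line 1 is not a header in %s", path),
         call. = FALSE)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1),
                 collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    bad <- which(!(as.character(seq_along(ids)) %in% names(seqs)) |
                   !nzchar(seqs[as.character(seq_along(ids))]))[1]
    stop(sprintf("malformed FASTA: record %d ('%s') has no sequence",
                 bad, ids[bad]), call. = FALSE)
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate miRNA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  seqs <- canonicalize_rna(unname(seqs[as.character(seq_along(ids))]))
  if (any(!nzchar(seqs)))
    stop("empty sequence after canonicalization", call. = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Count reads containing each mature miRNA as an exact substring
#'
#' A read counts once for every distinct miRNA whose sequence it contains as
#' a contiguous substring (per-read membership: a read holding the same
#' sequence twice still increments that miRNA once).
#'
#' @param reads character vector of reads (same alphabet as `mirnas`).
#' @param mirnas data frame with `id`, `sequence`.
#' @return named integer vector of counts, one per miRNA.
#' @export
count_exact_matches <- function(reads, mirnas) {
  counts <- vapply(mirnas$sequence, function(s)
    sum(grepl(s, reads, fixed = TRUE)), integer(1))
  stats::setNames(as.integer(counts), mirnas$id)
}

#' Trim canonical miRNA sequences to an isoform proxy
#'
#' Removes `five_prime` bases from the 5' end and `three_prime` bases from
#' the 3' end of every sequence (defaults 2 and 4), keeping ids. Shorter
#' trimmed sequences can only gain substring matches, so retabulated counts
#' are never smaller than canonical ones.
#'
#' @param mirnas data frame with `id`, `sequence`.
#' @param five_prime,three_prime number of bases trimmed from each end.
#' @return data frame with the same ids and trimmed sequences.
#' @export
trim_mirnas <- function(mirnas, five_prime = 2, three_prime = 4) {
  len <- nchar(mirnas$sequence)
  short <- len <= five_prime + three_prime
  if (any(short))
    stop(sprintf("sequence(s) too short to trim: %s",
                 paste(mirnas$id[short], collapse = ", ")), call. = FALSE)
  out <- mirnas
  out$sequence <- substr(mirnas$sequence, five_prime + 1, len - three_prime)
  out
}

#' Exclude low-abundance samples from a count matrix
#'
#' @param counts miRNA x sample integer matrix.
#' @param min_total_reads samples whose column sum is below this are dropped.
#' @return list with `counts` (kept columns, order preserved) and `excluded`
#'   (dropped sample ids).
#' @export
exclude_low_abundance_samples <- function(counts, min_total_reads) {
  stopifnot(min_total_reads >= 0)
  keep <- colSums(counts) >= min_total_reads
  if (!any(keep))
    stop("all samples fall below the read-count threshold", call. = FALSE)
  list(counts = counts[, keep, drop = FALSE],
       excluded = colnames(counts)[!keep])
}

#' Write / read a count matrix as TSV
#'
#' First column holds the miRNA id (header `mirna`), remaining columns are
#' samples.
#'
#' @param counts miRNA x sample matrix with dimnames.
#' @param path file path.
#' @return `path` invisibly (writer); integer matrix (reader).
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(mirna = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
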