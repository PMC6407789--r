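#' Tokenize a nucleotide sequence into overlapping k-mers
#'
#' All `N - k + 1` windows of length `k` (stride 1) are generated; any
#' window containing a character outside `A`, `C`, `G`, `T` (a degenerate
#' base) is omitted. The relative order of the surviving k-mers is
#' preserved.
#'
#' @param seq a nucleotide string (uppercased internally).
#' @param k k-mer length (`>= 1`).
#' @return Character vector of k-mers; empty when `k > nchar(seq)`.
#' @export
tokenize <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (k > n) return(character(0))
  toks <- substring(seq, 1:(n - k + 1L), k:n)
  # fast path: a fully ACGT sequence has no degenerate window
  if (grepl("[^ACGT]", seq)) toks <- toks[!grepl("[^ACGT]", toks)]
  toks
}

#' Tokenize many sequences
#'
#' @param seqs character vector of nucleotide strings.
#' @param k k-mer length.
#' @return A list of k-mer character vectors, one per input sequence.
#' @export
tokenize_set <- function(seqs, k) {
  lapply(seqs, tokenize, k = k)
}

#' Build a k-mer vocabulary from a tokenized corpus
#'
#' Counts every k-mer occurrence across the corpus and drops k-mers seen
#' strictly fewer than `min_count` times.
#'
#' @param corpus list of k-mer token vectors (one element per sequence).
#' @param min_count minimum corpus count for a k-mer to enter the
#'   vocabulary (the full-scale default used for 16S reference corpora
#'   is 100).
#' @return A list of class `kmer_vocabulary` with fields `kmer`
#'   (character), `id` (dense integer ids `1..|V|`), `count`, `k` and
#'   `min_count`. K-mers are ordered by decreasing count, ties
#'   lexicographic.
#' @export
build_vocabulary <- function(corpus, min_count = 100L) {
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) == 0L) stop("corpus contains no tokens")
  k <- unique(nchar(toks))
  if (length(k) != 1L) stop("corpus mixes k-mer lengths: ", paste(k, collapse = ", "))
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  if (length(tab) == 0L) {
    stop("empty vocabulary: no k-mer reaches min_count = ", min_count)
  }
  ord <- order(-as.integer(tab), names(tab))
  structure(list(kmer = names(tab)[ord],
                 id = seq_along(tab),
                 count = as.integer(tab)[ord],
                 k = as.integer(k),
                 min_count = as.integer(min_count)),
            class = "kmer_vocabulary")
}

#' @export
print.kmer_vocabulary <- function(x, ...) {
  cat(sprintf("k-mer vocabulary: %d %d-mers (min_count = %d, total count = %.0f)\n",
              length(x$kmer), x$k, x$min_count, sum(as.numeric(x$count))))
  invisible(x)
}

#' Baseline k-mer frequency table
#'
#' The classical alignment-free baseline: one row per group (sample or
#' sequence), one column per k-mer, cells holding occurrence counts or
#' within-group relative frequencies. For `k <= 8` all `4^k` columns are
#' materialized; for larger `k` only observed k-mers become columns.
#'
#' @param groups named list: group id to k-mer token vector.
#' @param k k-mer length (all tokens must have this length).
#' @param relative if `TRUE`, rows are normalized to sum to 1.
#' @return A numeric matrix (rows = groups, columns = k-mers).
#' @export
kmer_frequency_table <- function(groups, k, relative = FALSE) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  lens <- unique(nchar(unlist(groups, use.names = FALSE)))
  if (length(lens) > 0L && !identical(lens, as.integer(k))) {
    if (!all(lens == k)) stop("tokens do not all have length k = ", k)
  }
  cols <- if (k <= 8L) all_kmers(k) else sort(unique(unlist(groups, use.names = FALSE)))
  out <- matrix(0, nrow = length(groups), ncol = length(cols),
                dimnames = list(names(groups), cols))
  for (i in seq_along(groups)) {
    toks <- groups[[i]]
    if (length(toks) == 0L) {
      warning("group '", names(groups)[i], "' has zero tokens; row left at zero")
      next
    }
    tab <- table(toks)
    out[i, names(tab)] <- as.integer(tab)
    if (relative) out[i, ] <- out[i, ] / length(toks)
  }
  out
}

#' Enumerate all k-mers over the ACGT alphabet
#'
#' @param k k-mer length.
#' @return Character vector of all `4^k` k-mers, lexicographic order.
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1L, k <= 12L)
  base <- c("A", "C", "G", "T")
  out <- base
  for (i in seq_len(k - 1L)) out <- paste0(rep(out, each = 4L), base)
  out
}

#' Write a k-mer frequency table as delimited text
#'
#' @param tab matrix from [kmer_frequency_table()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(tab, path, sep = "\t") {
  utils::write.table(data.frame(group = rownames(tab), tab, check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
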