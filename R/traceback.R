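# Interpretability: activations are linear scores of embeddings against the
# sparse multinomial-lasso coefficients. For an items x d embedding matrix
# E and a d x J coefficient matrix beta, the activation matrix is E %*% beta
# (items x classes); intercepts are excluded so activations compare classes
# relative to one another.

#' Compute item-by-class activations
#'
#' @param embeddings items x d numeric matrix (k-mer or sequence
#'   embeddings).
#' @param beta d x J coefficient matrix (e.g. `fit$beta` from
#'   [fit_multinomial_lasso()]).
#' @return items x J activation matrix.
#' @export
compute_activations <- function(embeddings, beta) {
  embeddings <- as.matrix(embeddings)
  beta <- as.matrix(beta)
  if (ncol(embeddings) != nrow(beta)) {
    stop(sprintf("embedding dimension %d does not match coefficient rows %d",
                 ncol(embeddings), nrow(beta)))
  }
  embeddings %*% beta
}

#' Cumulative classification trajectory over taxon-sorted reads
#'
#' Sorts reads lexicographically by their taxon path, computes each read's
#' activation row from its raw (non-denoised) embedding, and accumulates
#' activations read by read. A class is favored when it has the largest
#' cumulative activation; the final predicted class is the argmax of the
#' last cumulative row. Raw embeddings are used because the read count
#' grows along the trajectory.
#'
#' @param read_embeddings_raw reads x d matrix of raw read embeddings.
#' @param read_taxa taxon path string per read.
#' @param beta d x J coefficient matrix.
#' @param read_ids optional read identifiers.
#' @return A list of class `trajectory`: `read_ids` and `taxa` in
#'   introduction order, `activations` (reads x J), `cumulative`
#'   (reads x J running sums), `final_class`.
#' @export
cumulative_trajectory <- function(read_embeddings_raw, read_taxa, beta,
                                  read_ids = NULL) {
  read_embeddings_raw <- as.matrix(read_embeddings_raw)
  n <- nrow(read_embeddings_raw)
  if (n == 0L) stop("empty read set")
  stopifnot(length(read_taxa) == n)
  if (is.null(read_ids)) read_ids <- as.character(seq_len(n))
  ord <- order(as.character(read_taxa), seq_len(n))
  act <- compute_activations(read_embeddings_raw[ord, , drop = FALSE], beta)
  cum <- apply(act, 2L, cumsum)
  if (n == 1L) cum <- matrix(cum, nrow = 1L, dimnames = dimnames(act))
  final <- colnames(beta)[which.max(cum[n, ])]
  if (is.null(final)) final <- which.max(cum[n, ])
  structure(list(read_ids = read_ids[ord], taxa = as.character(read_taxa)[ord],
                 activations = act, cumulative = cum, final_class = final),
            class = "trajectory")
}

#' Top-activation k-mers for one class
#'
#' Ranks the model's vocabulary by activation for the given class and
#' returns the top `n` (ties broken lexicographically by k-mer).
#'
#' @param model a `kmer_embedding_model`.
#' @param beta d x J coefficient matrix with column names containing
#'   `class_label`.
#' @param class_label the class whose activations are ranked.
#' @param n number of k-mers to return (1000 is the practical default at
#'   full scale); capped at the vocabulary size with a warning.
#' @return A data.frame with columns `kmer` and `activation`, descending.
#' @export
top_kmers <- function(model, beta, class_label, n = 1000L) {
  stopifnot(inherits(model, "kmer_embedding_model"), n >= 1L)
  beta <- as.matrix(beta)
  j <- match(class_label, colnames(beta))
  if (is.na(j)) stop("class '", class_label, "' not found in beta columns")
  act <- as.vector(compute_activations(model$matrix, beta[, j, drop = FALSE]))
  if (n > length(act)) {
    warning("n exceeds the vocabulary size; returning all ", length(act),
            " k-mers")
    n <- length(act)
  }
  ord <- order(-act, model$vocab$kmer)[seq_len(n)]
  data.frame(kmer = model$vocab$kmer[ord], activation = act[ord],
             stringsAsFactors = FALSE)
}

#' Locate k-mers in reads by exact substring matching
#'
#' Finds every (overlapping) occurrence of each k-mer in each read, in
#' 0-based half-open coordinates, and summarizes per-set read counts and
#' pairwise read-set intersections when `kmers` is a named list of k-mer
#' sets.
#'
#' @param kmers character vector of k-mers (one set), or a named list of
#'   such vectors (several sets, e.g. the top-activation k-mers of each
#'   class). All k-mers must share one length.
#' @param reads a sequence-record data.frame.
#' @return A list with `occurrences` (data.frame: `read_id`, `kmer`,
#'   `start`, `end`), `reads_per_set` (named count of reads containing at
#'   least one k-mer of each set) and `set_intersections` (data.frame of
#'   pairwise read-set intersection sizes; `NULL` for a single set).
#' @export
map_kmers_to_reads <- function(kmers, reads) {
  sets <- if (is.list(kmers)) kmers else list(set1 = kmers)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  all_k <- unlist(sets, use.names = FALSE)
  if (length(all_k) && length(unique(nchar(all_k))) > 1L) {
    stop("all k-mers must have the same length")
  }
  k <- if (length(all_k)) nchar(all_k[1L]) else 0L
  occ <- list()
  read_sets <- lapply(sets, function(s) character(0))
  uniq <- unique(all_k)
  for (km in uniq) {
    hits <- gregexpr(paste0("(?=", km, ")"), reads$seq, perl = TRUE)
    for (i in seq_along(hits)) {
      pos <- hits[[i]]
      if (pos[1L] == -1L) next
      occ[[length(occ) + 1L]] <- data.frame(
        read_id = reads$id[i], kmer = km,
        start = as.integer(pos) - 1L, end = as.integer(pos) - 1L + k,
        stringsAsFactors = FALSE)
      for (sn in names(sets)) {
        if (km %in% sets[[sn]]) {
          read_sets[[sn]] <- c(read_sets[[sn]], reads$id[i])
        }
      }
    }
  }
  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(read_id = character(0), kmer = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  read_sets <- lapply(read_sets, unique)
  reads_per_set <- vapply(read_sets, length, integer(1))
  set_intersections <- NULL
  if (length(sets) > 1L) {
    pairs <- utils::combn(names(sets), 2L)
    set_intersections <- data.frame(
      set_a = pairs[1L, ], set_b = pairs[2L, ],
      n_reads = apply(pairs, 2L, function(p) {
        length(intersect(read_sets[[p[1L]]], read_sets[[p[2L]]]))
      }), stringsAsFactors = FALSE)
  }
  list(occurrences = occurrences, reads_per_set = reads_per_set,
       set_intersections = set_intersections)
}
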