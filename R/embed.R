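# Pooling of k-mer embeddings into sequence/cluster/sample/body-site
# embeddings: a weighted mean of the k-mer vectors, where the weight of
# k-mer m is a / (a + f_m) with f_m its relative frequency in the query
# set (smooth inverse-frequency weighting), optionally followed by removal
# of the batch's first singular direction (common-component denoising).

#' Query-frequency down-weighting for pooled embeddings
#'
#' Computes, over an entire query corpus, the relative frequency `f_m` of
#' each model-vocabulary k-mer (counting only in-vocabulary tokens) and the
#' smooth inverse-frequency weight `a / (a + f_m)`. A k-mer absent from the
#' query corpus has `f = 0` and weight 1. This weighting is distinct from
#' the down-sampling applied during training, which reflects frequencies in
#' the training corpus.
#'
#' @param query_corpus list of k-mer token vectors (the full set of
#'   sequences about to be embedded).
#' @param model a `kmer_embedding_model`.
#' @param a smoothing parameter controlling how sharply frequent k-mers are
#'   down-weighted (default `1e-3`).
#' @return A list of class `query_weighting` with fields `a`, `freqs` and
#'   `weights` (numeric vectors aligned with, and named by, the model
#'   vocabulary).
#' @export
compute_query_weights <- function(query_corpus, model, a = 1e-3) {
  stopifnot(inherits(model, "kmer_embedding_model"), a > 0)
  toks <- unlist(query_corpus, use.names = FALSE)
  ids <- match(toks, model$vocab$kmer)
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0L) {
    stop("query corpus contains no in-vocabulary tokens")
  }
  counts <- tabulate(ids, nbins = length(model$vocab$kmer))
  freqs <- counts / length(ids)
  weights <- a / (a + freqs)
  names(freqs) <- names(weights) <- model$vocab$kmer
  structure(list(a = a, freqs = freqs, weights = weights),
            class = "query_weighting")
}

.resolve_weights <- function(model, weighting) {
  if (is.null(weighting)) {
    w <- rep(1, length(model$vocab$kmer))
    names(w) <- model$vocab$kmer
    return(w)
  }
  stopifnot(inherits(weighting, "query_weighting"))
  if (!identical(names(weighting$weights), model$vocab$kmer)) {
    stop("weighting was computed for a different model vocabulary")
  }
  weighting$weights
}

#' Pool many token sets into raw embeddings
#'
#' Vectorized form of [embed_set_raw()]: each element of `token_sets` is
#' pooled into one raw (non-denoised) embedding,
#' `(1/M) * sum_m weight_m * eps_m` over its in-vocabulary tokens
#' (multiplicity respected), with `M` the in-vocabulary token count.
#' Sets with zero in-vocabulary tokens receive no embedding and are
#' reported separately.
#'
#' @param token_sets list of k-mer token vectors.
#' @param model a `kmer_embedding_model`.
#' @param weighting a `query_weighting` from [compute_query_weights()], or
#'   `NULL` for uniform weights.
#' @param level embedding level label: one of `"sequence"`, `"cluster"`,
#'   `"sample"`, `"body_site"`, `"consensus"`.
#' @param ids optional character ids (default `names(token_sets)` or
#'   indices).
#' @return A list of class `pooled_embeddings`: `vectors` (n x d matrix,
#'   one row per embedded set), `n_tokens`, `n_oov`, `ids`, `level`, and
#'   `dropped` (ids of sets with no in-vocabulary tokens).
#' @export
embed_sets_raw <- function(token_sets, model, weighting = NULL,
                           level = "sequence", ids = NULL) {
  stopifnot(inherits(model, "kmer_embedding_model"))
  level <- match.arg(level, c("sequence", "cluster", "sample", "body_site",
                              "consensus"))
  if (is.null(ids)) {
    ids <- names(token_sets)
    if (is.null(ids)) ids <- as.character(seq_along(token_sets))
  }
  stopifnot(length(ids) == length(token_sets))
  w <- .resolve_weights(model, weighting)
  V <- length(model$vocab$kmer)
  lens <- lengths(token_sets)
  toks <- unlist(token_sets, use.names = FALSE)
  col <- match(toks, model$vocab$kmer)
  row <- rep.int(seq_along(token_sets), lens)
  oov <- is.na(col)
  n_oov <- as.integer(tabulate(row[oov], nbins = length(token_sets)))
  keep <- !oov
  counts <- Matrix::sparseMatrix(i = row[keep], j = col[keep], x = 1,
                                 dims = c(length(token_sets), V))
  m_tokens <- as.integer(Matrix::rowSums(counts))
  embedded <- m_tokens > 0L
  if (!any(embedded)) stop("no set has in-vocabulary tokens; nothing to embed")
  vectors <- as.matrix(counts[embedded, , drop = FALSE] %*%
                         (model$matrix * w)) / m_tokens[embedded]
  rownames(vectors) <- ids[embedded]
  structure(list(vectors = vectors,
                 n_tokens = m_tokens[embedded],
                 n_oov = n_oov[embedded],
                 ids = ids[embedded],
                 level = level,
                 dropped = ids[!embedded]),
            class = "pooled_embeddings")
}

#' Pool one token set into a raw embedding
#'
#' Sequence, cluster, sample and body-site embeddings all use this one
#' operation on the respective token multiset.
#'
#' @param tokens k-mer token vector (ordered multiset).
#' @inheritParams embed_sets_raw
#' @param id identifier recorded on the embedding.
#' @return A list of class `pooled_embedding` with fields `vector` (length
#'   `d`), `n_tokens` (in-vocabulary token count `M`), `n_oov`, `level`,
#'   `id`.
#' @export
embed_set_raw <- function(tokens, model, weighting = NULL,
                          level = "sequence", id = "set1") {
  res <- tryCatch(
    embed_sets_raw(list(tokens), model, weighting, level = level, ids = id),
    error = function(e) stop("no embedding: set has zero in-vocabulary tokens"))
  structure(list(vector = drop(res$vectors[1L, ]), n_tokens = res$n_tokens[1L],
                 n_oov = res$n_oov[1L], level = res$level, id = id),
            class = "pooled_embedding")
}

#' Frequency-weighted pooling of raw embeddings by group
#'
#' Because a raw embedding is a token-count-weighted mean of k-mer vectors,
#' the raw embedding of a union of token sets equals the `n_tokens`-weighted
#' mean of the sets' raw embeddings. This pools, e.g., read embeddings into
#' sample embeddings, or sample embeddings into body-site embeddings,
#' without re-tokenizing.
#'
#' @param vectors n x d matrix of raw embeddings.
#' @param n_tokens in-vocabulary token counts per row.
#' @param groups grouping vector of length n.
#' @return A list with `vectors` (one row per group), `n_tokens`, `ids`.
#' @export
pool_embeddings <- function(vectors, n_tokens, groups) {
  stopifnot(nrow(vectors) == length(n_tokens),
            nrow(vectors) == length(groups))
  gsum <- rowsum(vectors * n_tokens, groups)
  gM <- rowsum(as.numeric(n_tokens), groups)
  list(vectors = gsum / as.vector(gM),
       n_tokens = as.integer(gM),
       ids = rownames(gsum))
}

#' Remove the common component from a batch of raw embeddings
#'
#' Computes the first right singular vector `nu` of the (uncentered) batch
#' matrix and subtracts each row's projection onto it:
#' `out = raw - (raw . nu) nu`. The batch must be the full collection being
#' jointly analyzed; denoising a single embedding is undefined.
#'
#' @param x an n x d numeric matrix of raw embeddings (n >= 2), or a
#'   `pooled_embeddings` object.
#' @return For a matrix input: list with `vectors` (denoised matrix) and
#'   `nu` (unit vector). For a `pooled_embeddings` input: the same object
#'   with `vectors` replaced and `nu` attached.
#' @export
denoise_batch <- function(x) {
  pooled <- inherits(x, "pooled_embeddings")
  m <- if (pooled) x$vectors else as.matrix(x)
  if (nrow(m) < 2L) {
    stop("denoising needs a batch of >= 2 embeddings; denoise within the ",
         "full comparison batch")
  }
  if (all(m == 0)) stop("all-zero batch: no principal direction")
  if (any(!is.finite(m))) stop("non-finite embeddings in batch")
  nu <- svd(m, nu = 0L, nv = 1L)$v[, 1L]
  out <- m - (m %*% nu) %*% t(nu)
  dimnames(out) <- dimnames(m)
  if (pooled) {
    x$vectors <- out
    x$nu <- nu
    return(x)
  }
  list(vectors = out, nu = nu)
}

#' Cosine similarity between two embeddings
#'
#' @param a,b numeric vectors of equal length, both nonzero.
#' @return `sum(a*b) / (||a|| * ||b||)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity of a zero vector is undefined")
  sum(a * b) / (na * nb)
}

# row-normalized cosine of each row of m against each row of n
.cosine_matrix <- function(m, n) {
  mn <- m / sqrt(rowSums(m^2))
  nn <- n / sqrt(rowSums(n^2))
  tcrossprod(mn, nn)
}

#' Nearest neighbors of a k-mer in embedding space
#'
#' Returns all vocabulary k-mers (excluding the query) whose cosine
#' similarity with the query k-mer strictly exceeds `threshold`.
#'
#' @param model a `kmer_embedding_model`.
#' @param query_kmer an in-vocabulary k-mer.
#' @param threshold cosine threshold in `(-1, 1]` (0.25 is a practical
#'   default for 10-mer models).
#' @return A data.frame with columns `kmer` and `cosine`, sorted by
#'   decreasing cosine.
#' @export
nearest_kmers <- function(model, query_kmer, threshold = 0.25) {
  stopifnot(inherits(model, "kmer_embedding_model"),
            threshold > -1, threshold <= 1)
  i <- match(query_kmer, model$vocab$kmer)
  if (is.na(i)) stop("k-mer '", query_kmer, "' is not in the model vocabulary")
  q <- model$matrix[i, ]
  sims <- as.vector(.cosine_matrix(model$matrix, matrix(q, nrow = 1L)))
  sel <- which(sims > threshold)
  sel <- sel[sel != i]
  ord <- sel[order(-sims[sel], model$vocab$kmer[sel])]
  data.frame(kmer = model$vocab$kmer[ord], cosine = sims[ord],
             stringsAsFactors = FALSE)
}

#' Write pooled embeddings as delimited text
#'
#' @param emb a `pooled_embeddings` object.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, sep = "\t") {
  stopifnot(inherits(emb, "pooled_embeddings"))
  df <- data.frame(id = emb$ids, level = emb$level, n_tokens = emb$n_tokens,
                   n_oov = emb$n_oov, emb$vectors, check.names = FALSE)
  colnames(df)[-(1:4)] <- paste0("v", seq_len(ncol(emb$vectors)))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
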