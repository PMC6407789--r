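#' Skip-gram training hyperparameters
#'
#' Defaults mirror the model configuration selected for full-scale 16S
#' reference corpora: 10-mers embedded in 256 dimensions with a context
#' window of 20, 10 negative samples, down-sampling threshold `1e-4`,
#' minimum corpus count 100, 5 epochs. For desk-scale corpora the
#' vocabulary threshold and dimensionality are typically reduced.
#'
#' @param k k-mer length.
#' @param dim embedding dimensionality `d`.
#' @param window context window half-width (per position, the effective
#'   window is drawn uniformly from `1..window`, the standard word2vec
#'   scheme).
#' @param negative negative samples per positive pair, drawn from the
#'   unigram distribution raised to 0.75.
#' @param subsample_t down-sampling threshold `t`: a token with corpus
#'   frequency `f` is discarded with probability `max(0, 1 - sqrt(t/f))`.
#' @param min_count minimum corpus count for vocabulary membership.
#' @param epochs training epochs.
#' @param alpha initial learning rate (linearly decayed).
#' @param seed integer seed; training is single-threaded and bit-reproducible
#'   given the seed.
#' @return A list of class `train_params`.
#' @export
train_params <- function(k = 10L, dim = 256L, window = 20L, negative = 10L,
                         subsample_t = 1e-4, min_count = 100L, epochs = 5L,
                         alpha = 0.025, seed = 1L) {
  stopifnot(k >= 1, dim > 0, window >= 1, negative >= 0, subsample_t > 0,
            epochs >= 1, alpha > 0)
  structure(list(k = as.integer(k), dim = as.integer(dim),
                 window = as.integer(window), negative = as.integer(negative),
                 subsample_t = subsample_t, min_count = as.integer(min_count),
                 epochs = as.integer(epochs), alpha = alpha,
                 seed = as.integer(seed)),
            class = "train_params")
}

#' The hyperparameter grid used for model selection
#'
#' The grid explored when benchmarking embedding configurations on 16S
#' reference corpora: 6-mers and 10-mers crossed with three embedding
#' dimensionalities, two down-sampling thresholds, two negative-sample
#' counts and two context-window widths (48 parameterizations).
#'
#' @return A data.frame with one row per parameterization.
#' @export
default_parameter_grid <- function() {
  expand.grid(k = c(6L, 10L), dim = c(64L, 128L, 256L),
              subsample_t = c(1e-4, 1e-6), negative = c(10L, 20L),
              window = c(20L, 50L), KEEP.OUT.ATTRS = FALSE)
}

#' Train skip-gram k-mer embeddings with negative sampling
#'
#' One corpus element (a tokenized full-length sequence) is one "sentence":
#' context windows never span sequences. The trainer is an in-package,
#' single-threaded SGNS implementation; given the same corpus and seed it
#' returns bit-identical matrices.
#'
#' @param corpus list of k-mer token vectors, one per training sequence.
#' @param params a [train_params()] object.
#' @return An object of class `kmer_embedding_model`: fields `vocab`
#'   (a `kmer_vocabulary`), `matrix` (`|V| x d`, rownames = k-mers) and
#'   `params`.
#' @export
train_skipgram <- function(corpus, params = train_params()) {
  stopifnot(inherits(params, "train_params"))
  vocab <- build_vocabulary(corpus, min_count = params$min_count)
  if (vocab$k != params$k) {
    stop(sprintf("corpus is tokenized at k = %d but params$k = %d",
                 vocab$k, params$k))
  }
  idx <- lapply(corpus, function(toks) {
    i <- match(toks, vocab$kmer)
    i[is.na(i)] <- 0L
    i - 1L # 0-based; -1 marks out-of-vocabulary tokens
  })
  mat <- .sgns_train(idx, vocab$count, params$dim, params$window,
                     params$negative, params$subsample_t, params$epochs,
                     params$alpha, params$seed)
  if (any(!is.finite(mat))) stop("training produced non-finite embeddings")
  rownames(mat) <- vocab$kmer
  structure(list(vocab = vocab, matrix = mat, params = params),
            class = "kmer_embedding_model")
}

#' @export
print.kmer_embedding_model <- function(x, ...) {
  cat(sprintf("k-mer embedding model: %d %d-mers x %d dimensions\n",
              nrow(x$matrix), x$params$k, ncol(x$matrix)))
  cat(sprintf("  window %d, negative %d, subsample %g, epochs %d, seed %d\n",
              x$params$window, x$params$negative, x$params$subsample_t,
              x$params$epochs, x$params$seed))
  invisible(x)
}

#' Save a k-mer embedding model
#'
#' The matrix is written in the standard word2vec text format (header line
#' `"|V| d"`, then one `"kmer v1 ... vd"` line per k-mer, full precision),
#' with a JSON sidecar (`<path>.meta.json`) holding the training parameters
#' and vocabulary counts.
#'
#' @param model a `kmer_embedding_model`.
#' @param path output path for the vectors file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_embedding_model"))
  m <- model$matrix
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  rows <- apply(m, 1L, function(v) paste(format(v, digits = 17, trim = TRUE,
                                                scientific = TRUE),
                                         collapse = " "))
  writeLines(paste(rownames(m), rows), con)
  meta <- list(params = unclass(model$params),
               vocab = list(kmer = model$vocab$kmer,
                            count = model$vocab$count,
                            k = model$vocab$k,
                            min_count = model$vocab$min_count))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a k-mer embedding model saved by [save_model()]
#'
#' @param path path to the vectors file.
#' @return A `kmer_embedding_model`; round-trips through [save_model()]
#'   preserve vocabulary, parameters and matrix to stored precision.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("model file '", path, "' is empty or truncated")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad word2vec header in '", path, "'")
  nv <- hdr[1L]; d <- hdr[2L]
  body <- lines[-1L]
  if (length(body) != nv) {
    stop(sprintf("truncated model: header declares %d rows, found %d", nv,
                 length(body)))
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad)) {
    stop(sprintf("row %d has %d values, expected %d", bad[1L],
                 lengths(parts)[bad[1L]] - 1L, d))
  }
  kmers <- vapply(parts, `[[`, character(1), 1L)
  mat <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE)),
                nrow = nv, ncol = d, byrow = TRUE, dimnames = list(kmers, NULL))
  if (anyNA(mat)) stop("non-numeric values in model matrix")
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing model sidecar '", meta_path, "'")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  p <- meta$params
  params <- train_params(k = p$k, dim = p$dim, window = p$window,
                         negative = p$negative, subsample_t = p$subsample_t,
                         min_count = p$min_count, epochs = p$epochs,
                         alpha = p$alpha, seed = p$seed)
  if (params$dim != d) {
    stop(sprintf("dimension mismatch: sidecar says d = %d, matrix has %d",
                 params$dim, d))
  }
  if (unique(nchar(kmers))[1L] != params$k) {
    stop("k mismatch between stored vectors and sidecar parameters")
  }
  vocab <- structure(list(kmer = meta$vocab$kmer, id = seq_along(meta$vocab$kmer),
                          count = as.integer(meta$vocab$count),
                          k = as.integer(meta$vocab$k),
                          min_count = as.integer(meta$vocab$min_count)),
                     class = "kmer_vocabulary")
  if (!identical(vocab$kmer, kmers)) {
    stop("vocabulary in sidecar does not match the vectors file")
  }
  structure(list(vocab = vocab, matrix = mat, params = params),
            class = "kmer_embedding_model")
}
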