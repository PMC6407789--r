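# High-level glue: embed all reads and samples of a study with one
# weighting computed on the full query corpus, and run a seeded
# train/test classification. These are thin compositions of the module
# functions; every step is available individually.

#' Embed the reads and samples of a study
#'
#' Tokenizes every read at the model's k, computes the query-frequency
#' weighting over the whole read corpus, pools raw read embeddings, and
#' pools them further (token-count weighted) into per-sample embeddings.
#' Sample embeddings are also returned denoised within the batch of all
#' samples.
#'
#' @param study a `synthetic_study` (or any list with a `reads` data.frame
#'   holding `id`, `seq`, `sample_id` and optionally `taxon`, plus a
#'   `samples` data.frame with `sample_id`, `class_label`).
#' @param model a `kmer_embedding_model`.
#' @param a query down-weighting smoothing parameter.
#' @return A list with components `reads` (raw embeddings: `vectors`,
#'   `n_tokens`, `ids`, `sample_id`, `taxon`), `samples` (`raw`,
#'   `denoised` matrices with sample ids as rownames, `class_label`
#'   aligned to rows) and `weighting`.
#' @export
embed_study <- function(study, model, a = 1e-3) {
  k <- model$params$k
  toks <- tokenize_set(study$reads$seq, k)
  names(toks) <- study$reads$id
  weighting <- compute_query_weights(toks, model, a = a)
  emb <- embed_sets_raw(toks, model, weighting, level = "sequence")
  idx <- match(emb$ids, study$reads$id)
  read_info <- list(vectors = emb$vectors, n_tokens = emb$n_tokens,
                    ids = emb$ids, sample_id = study$reads$sample_id[idx],
                    taxon = study$reads$taxon[idx], n_dropped = length(emb$dropped))
  pooled <- pool_embeddings(emb$vectors, emb$n_tokens, read_info$sample_id)
  den <- denoise_batch(pooled$vectors)
  cl <- study$samples$class_label[match(pooled$ids, study$samples$sample_id)]
  list(reads = read_info,
       samples = list(raw = pooled$vectors, denoised = den$vectors,
                      nu = den$nu, ids = pooled$ids, class_label = cl),
       weighting = weighting)
}

#' Seeded stratified train/test split
#'
#' @param y class labels.
#' @param test_fraction fraction of each class held out (default 0.1,
#'   i.e. a 90/10 split).
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(y, test_fraction = 0.1, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- factor(y)
  set.seed(seed)
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Train and evaluate a sparse multinomial classifier on one feature set
#'
#' Stratified 90/10 split, 10-fold cross-validated lasso on the training
#' portion, evaluation on the held-out portion with balanced accuracy and
#' macro precision/recall/F1.
#'
#' @param features samples x features matrix.
#' @param labels class label per sample.
#' @param test_fraction held-out fraction.
#' @param n_folds CV folds for lambda selection.
#' @param seed integer seed (split and fold assignment).
#' @return A list with `fit` (the `sparse_linear_model`), `split`,
#'   `balanced_accuracy`, `report`, `y_true`, `y_pred`.
#' @export
classify_samples <- function(features, labels, test_fraction = 0.1,
                             n_folds = 10L, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  split <- train_test_split(labels, test_fraction, seed)
  fit <- fit_multinomial_lasso(features[split$train, , drop = FALSE],
                               labels[split$train], n_folds = n_folds,
                               seed = seed)
  y_pred <- predict(fit, features[split$test, , drop = FALSE])
  y_true <- factor(labels[split$test], levels = fit$class_names)
  list(fit = fit, split = split,
       balanced_accuracy = balanced_accuracy(y_true, y_pred),
       report = classification_report(y_true, y_pred),
       y_true = y_true, y_pred = y_pred)
}
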