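# In-code fixtures: a hand-set toy embedding model, a two-dialect corpus
# with family-exclusive co-occurrence, and small writers for temp files.

toy_model <- function(kmers, mat, counts = rep(100L, length(kmers))) {
  k <- unique(nchar(kmers))
  stopifnot(length(k) == 1L, nrow(mat) == length(kmers))
  rownames(mat) <- kmers
  vocab <- structure(list(kmer = kmers, id = seq_along(kmers),
                          count = as.integer(counts), k = as.integer(k),
                          min_count = 1L),
                     class = "kmer_vocabulary")
  structure(list(vocab = vocab, matrix = mat,
                 params = train_params(k = k, dim = ncol(mat), min_count = 1L)),
            class = "kmer_embedding_model")
}

# deterministic toy model: 8 distinct 3-mers with fixed random vectors
small_toy_model <- function(dim = 5L, seed = 99L) {
  set.seed(seed)
  kmers <- c("AAA", "ACG", "CCT", "GAT", "GGC", "TAC", "TTG", "CGA")
  toy_model(kmers, matrix(rnorm(length(kmers) * dim), ncol = dim))
}

# two token families with family-exclusive co-occurrence: sentences mix
# tokens of one family only
dialect_corpus <- function(n_sent = 50L, sent_len = 30L, seed = 7L) {
  set.seed(seed)
  fam_a <- all_kmers(4)[c(1, 18, 35, 52, 69, 86)]
  fam_b <- all_kmers(4)[c(150, 167, 184, 201, 218, 235)]
  corpus <- c(lapply(seq_len(n_sent), function(i) sample(fam_a, sent_len, TRUE)),
              lapply(seq_len(n_sent), function(i) sample(fam_b, sent_len, TRUE)))
  list(corpus = corpus, fam_a = fam_a, fam_b = fam_b)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_tmp_lines <- function(lines, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# mean within-family minus mean across-family cosine of model vectors
family_cosine_gap <- function(model, fam_a, fam_b) {
  m <- model$matrix / sqrt(rowSums(model$matrix^2))
  cm <- tcrossprod(m)
  ia <- match(intersect(fam_a, rownames(m)), rownames(m))
  ib <- match(intersect(fam_b, rownames(m)), rownames(m))
  within <- c(cm[ia, ia][upper.tri(diag(length(ia)))],
              cm[ib, ib][upper.tri(diag(length(ib)))])
  across <- as.vector(cm[ia, ib])
  mean(within) - mean(across)
}
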