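test_that("query weights follow a / (a + f) on in-vocabulary frequencies", {
  m <- small_toy_model()
  # corpus of 1000 in-vocabulary tokens, 9 of them "ACG"
  corpus <- list(c(rep("ACG", 9), rep("AAA", 991)))
  w <- compute_query_weights(corpus, m, a = 1e-3)
  expect_equal(sum(w$freqs), 1)
  expect_equal(unname(w$weights["ACG"]), 1e-3 / (1e-3 + 9e-3))
  # absent from the query: f = 0, weight 1
  expect_equal(unname(w$weights["TTG"]), 1)
  # f equal to a gives weight 1/2
  w2 <- compute_query_weights(list(c("AAA", rep("CCT", 999))), m, a = 1e-3)
  expect_equal(unname(w2$weights["AAA"]), 0.5)
  expect_error(compute_query_weights(list(c("NNN")), m), "in-vocabulary")
})

test_that("pooling is the weighted token-count-normalized mean", {
  m <- small_toy_model()
  w <- compute_query_weights(list(m$vocab$kmer), m, a = 1e-3)
  wt <- w$weights
  e1 <- embed_set_raw("ACG", m, w)
  expect_equal(e1$vector, unname(wt["ACG"] * m$matrix["ACG", ]))
  expect_equal(e1$n_tokens, 1L)
  e2 <- embed_set_raw(c("ACG", "CCT"), m, w)
  expect_equal(e2$vector,
               unname((wt["ACG"] * m$matrix["ACG", ] +
                         wt["CCT"] * m$matrix["CCT", ]) / 2))
  # out-of-vocabulary tokens are skipped but tallied
  e3 <- embed_set_raw(c("ACG", "NNN"), m, w)
  expect_equal(e3$n_tokens, 1L)
  expect_equal(e3$n_oov, 1L)
  expect_error(embed_set_raw(c("NNN"), m, w), "no embedding")
})

test_that("pooling is linear over token-set unions", {
  m <- small_toy_model()
  set.seed(21)
  for (i in 1:10) {
    a <- sample(m$vocab$kmer, sample(3:10, 1), replace = TRUE)
    b <- sample(m$vocab$kmer, sample(3:10, 1), replace = TRUE)
    w <- compute_query_weights(list(c(a, b)), m)
    ea <- embed_set_raw(a, m, w)
    eb <- embed_set_raw(b, m, w)
    eab <- embed_set_raw(c(a, b), m, w)
    lhs <- (ea$n_tokens + eb$n_tokens) * eab$vector
    rhs <- ea$n_tokens * ea$vector + eb$n_tokens * eb$vector
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("grouped pooling of raw embeddings matches pooled tokenization", {
  m <- small_toy_model()
  set.seed(22)
  sets <- lapply(1:6, function(i) sample(m$vocab$kmer, 8, replace = TRUE))
  w <- compute_query_weights(sets, m)
  emb <- embed_sets_raw(sets, m, w)
  groups <- c("g1", "g1", "g1", "g2", "g2", "g2")
  pooled <- pool_embeddings(emb$vectors, emb$n_tokens, groups)
  direct <- embed_set_raw(unlist(sets[1:3]), m, w)
  expect_lt(max(abs(pooled$vectors["g1", ] - direct$vector)), 1e-12)
})

test_that("denoising removes exactly the first singular direction", {
  # rank-1 batch maps to zero
  u <- c(1, 2, -1, 0.5)
  batch <- outer(c(1, -2, 3), u)
  out <- denoise_batch(batch)
  expect_lt(max(abs(out$vectors)), 1e-12)
  expect_equal(sum(out$nu^2), 1)

  # the dominant of two orthogonal vectors is annihilated
  b2 <- rbind(c(10, 0), c(0, 1))
  o2 <- denoise_batch(b2)
  expect_lt(max(abs(o2$vectors[1, ])), 1e-10)
  expect_equal(o2$vectors[2, ], c(0, 1), tolerance = 1e-10)

  # random batch agrees with an explicit full-SVD oracle
  set.seed(31)
  r <- matrix(rnorm(80), nrow = 10)
  o3 <- denoise_batch(r)
  sv <- svd(r)
  nu <- sv$v[, 1]
  oracle <- r - (r %*% nu) %*% t(nu)  # invariant to the sign of nu
  expect_lt(max(abs(o3$vectors - oracle)), 1e-10)
  # residual projections vanish relative to the batch norm
  expect_lt(sum((o3$vectors %*% o3$nu)^2), 1e-12 * sum(r^2))

  expect_error(denoise_batch(matrix(1, 1, 4)), "batch")
  expect_error(denoise_batch(matrix(0, 3, 4)), "zero")
})

test_that("cosine similarity matches its closed form and invariances", {
  u <- c(1, 2, 3)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), u[1:2]), "zero")
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(6); al <- runif(1, 0.1, 10)
    expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
    expect_equal(cosine_similarity(al * a, b), cosine_similarity(a, b))
  }
})

test_that("k-mer neighbor queries apply a strict threshold and exclude self", {
  m <- small_toy_model()
  expect_equal(nrow(nearest_kmers(m, "ACG", threshold = 1)), 0L)
  # duplicated vector is returned with cosine 1
  m2 <- toy_model(c("AAA", "AAC", "GGG"),
                  rbind(c(1, 0), c(1, 0), c(0, 1)))
  nb <- nearest_kmers(m2, "AAA", threshold = 0.9)
  expect_equal(nb$kmer, "AAC")
  expect_equal(nb$cosine, 1)
  expect_error(nearest_kmers(m, "NNN", 0.2), "vocabulary")

  # brute force over a 5-word toy model
  set.seed(51)
  m3 <- toy_model(c("AA", "AC", "CA", "GG", "TT"),
                  matrix(rnorm(15), ncol = 3))
  got <- nearest_kmers(m3, "AC", threshold = -0.5)
  brute <- vapply(setdiff(m3$vocab$kmer, "AC"), function(k) {
    cosine_similarity(m3$matrix["AC", ], m3$matrix[k, ])
  }, numeric(1))
  brute <- sort(brute[brute > -0.5], decreasing = TRUE)
  expect_equal(got$kmer, names(brute))
  expect_equal(got$cosine, unname(brute))
})

test_that("embedding tables round-trip core fields through delimited text", {
  m <- small_toy_model()
  sets <- list(s1 = c("ACG", "AAA"), s2 = c("CCT", "GGC", "TAC"))
  emb <- embed_sets_raw(sets, m, level = "sample")
  p <- tempfile(fileext = ".tsv")
  write_embeddings(emb, p)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(back$id, c("s1", "s2"))
  expect_equal(back$n_tokens, c(2L, 3L))
  expect_equal(as.matrix(back[, -(1:4)]), emb$vectors,
               ignore_attr = TRUE, tolerance = 1e-12)
})
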