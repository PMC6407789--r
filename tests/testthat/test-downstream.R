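test_that("clr transform matches its closed form and zero-sum property", {
  expect_equal(clr_transform(rbind(c(1, 1, 1)))[1, ], c(0, 0, 0))
  expect_equal(clr_transform(rbind(c(0, 0, 0)))[1, ], c(0, 0, 0))
  # row (3, 0): pseudocounted (4, 1), g = 2, clr = (log 2, -log 2)
  expect_equal(clr_transform(rbind(c(3, 0)))[1, ], c(log(2), -log(2)))
  set.seed(61)
  x <- matrix(rpois(60, 5), nrow = 6)
  out <- clr_transform(x)
  expect_lt(max(abs(rowSums(out))), 1e-8)
  # invariance to scaling the pseudocounted row: (3,0)+1 = (4,1); x2 with
  # (x2+1) = (8,2) has the same composition
  expect_equal(clr_transform(rbind(c(7, 1)))[1, ],
               clr_transform(rbind(c(3, 0)))[1, ])
  expect_error(clr_transform(rbind(c(-1, 2))), "negative")
})

test_that("seeded K-means recovers separated blobs deterministically", {
  set.seed(62)
  blob1 <- matrix(rnorm(60, mean = 0, sd = 0.1), ncol = 2)
  blob2 <- matrix(rnorm(60, mean = 10, sd = 0.1), ncol = 2)
  X <- rbind(blob1, blob2)
  truth <- rep(1:2, each = 30)
  km <- kmeans_cluster(X, 2, seed = 4)
  expect_equal(clustering_metrics(truth, km$labels)$ari, 1)
  km2 <- kmeans_cluster(X, 2, seed = 4)
  expect_identical(km$centroids, km2$centroids)
  # K = n: every point its own cluster
  kmn <- kmeans_cluster(X[1:5, ], 5, seed = 1)
  expect_equal(kmn$inertia, 0)
  expect_setequal(kmn$labels, 1:5)
  expect_error(kmeans_cluster(X[1:3, ], 4), "exceeds")
})

test_that("pseudo-OTU centroids summarize embedding blobs", {
  set.seed(63)
  means <- matrix(c(0, 0, 5, 5, -5, 5), ncol = 2, byrow = TRUE)
  E <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(200, sd = 0.2), ncol = 2), 2, means[i, ], "+")
  }))
  po <- fit_pseudo_otus(E, K = 3, seed = 2)
  ord <- order(po$centroids[, 1])
  got <- po$centroids[ord, ]
  want <- means[order(means[, 1]), ]
  expect_lt(max(abs(got - want)), 0.15)
  # K = 1: centroid is the subsample mean
  po1 <- fit_pseudo_otus(E, K = 1, seed = 2)
  expect_equal(drop(po1$centroids), colMeans(E), tolerance = 1e-10)
  expect_error(fit_pseudo_otus(E, K = 10, subsample_n = 5), "exceeds")
})

test_that("pseudo-OTU assignment conserves counts and breaks ties low", {
  po <- structure(list(centroids = rbind(c(0, 1), c(0, -1)), K = 2L,
                       seed = 1L, n_training_embeddings = 2L),
                  class = "pseudo_otu_model")
  tab <- assign_pseudo_otus(po, rbind(c(0, 0.5)), "s1")
  expect_equal(unname(tab["s1", ]), c(1L, 0L))
  # equidistant point goes to the lowest centroid index
  tie <- assign_pseudo_otus(po, rbind(c(3, 0)), "s1")
  expect_equal(unname(tie["s1", ]), c(1L, 0L))
  set.seed(64)
  E <- matrix(rnorm(40), ncol = 2)
  ids <- rep(c("a", "b"), each = 10)
  tab2 <- assign_pseudo_otus(po, E, ids)
  expect_equal(unname(rowSums(tab2)), c(10L, 10L))
  expect_error(assign_pseudo_otus(po, matrix(0, 2, 3), c("a", "b")), "dimension")
})

test_that("the multinomial lasso separates separable classes and respects nulls", {
  set.seed(65)
  # separable 1-D problem
  x <- matrix(c(rnorm(40, -3, 0.3), rnorm(40, 3, 0.3)), ncol = 1)
  x <- cbind(x, matrix(rnorm(160), ncol = 2))
  y <- rep(c("a", "b"), each = 40)
  res <- classify_samples(x, y, test_fraction = 0.2, n_folds = 5, seed = 9)
  expect_equal(res$balanced_accuracy, 1)
  # permuted labels: held-out accuracy near the majority-class rate
  set.seed(66)
  xn <- matrix(rnorm(200 * 10), ncol = 10)
  yn <- sample(rep(c("a", "b"), c(120, 80)))
  # the null fit typically predicts one class for everything, so the report
  # legitimately warns about an unpredicted class
  resn <- suppressWarnings(
    classify_samples(xn, yn, test_fraction = 0.25, n_folds = 5, seed = 10))
  plain_acc <- mean(resn$y_pred == resn$y_true)
  expect_lt(abs(plain_acc - 0.6), 0.15)
  expect_error(fit_multinomial_lasso(xn, rep("a", 200)), "two classes")
})

test_that("the lasso recovers a single informative feature among noise", {
  set.seed(67)
  n <- 200
  X <- matrix(rnorm(n * 50), ncol = 50)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 7] <- X[y == "b", 7] + 3
  fit <- fit_multinomial_lasso(X, y, n_folds = 10, seed = 3)
  expect_true(any(fit$beta[7, ] != 0))
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(balanced_accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  # recalls 1.0, 0.5, 0.0 average to 0.5
  y_true <- c("a", "a", "b", "b", "c", "c")
  y_pred <- c("a", "a", "b", "a", "a", "b")
  expect_equal(balanced_accuracy(y_true, y_pred), 0.5)
  # all-majority predictions in a 3-class problem
  y3 <- c(rep("a", 6), rep("b", 2), rep("c", 2))
  expect_equal(balanced_accuracy(y3, rep("a", 10)), 1 / 3)
  empty <- factor(c("a", "b"), levels = c("a", "b", "c"))
  expect_error(balanced_accuracy(empty, c("a", "b")), "zero members")
})

test_that("classification reports macro-average precision, recall and F1", {
  y <- c("x", "x", "y", "y")
  r <- classification_report(y, y)
  expect_equal(unlist(r[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # binary confusion TP=2 FP=1 FN=1 TN=6 for class "pos"
  y_true <- c(rep("pos", 3), rep("neg", 7))
  y_pred <- c("pos", "pos", "neg", "pos", rep("neg", 6))
  r2 <- classification_report(y_true, y_pred)
  expect_equal(r2$confusion["pos", "pos"], 2)
  # class-level pos P = R = F1 = 2/3; macro averages with neg (6/7, 6/7)
  expect_equal(r2$precision, (2 / 3 + 6 / 7) / 2)
  expect_equal(r2$recall, (2 / 3 + 6 / 7) / 2)
  expect_warning(r3 <- classification_report(y_true, rep("neg", 10)),
                 "no predictions")
  expect_equal(r3$precision, (0 + 0.7) / 2)
})

test_that("clustering metrics match their definitions and an external ARI", {
  same <- clustering_metrics(c(1, 1, 2, 2), c(5, 5, 9, 9))
  expect_equal(unlist(same), c(homogeneity = 1, completeness = 1, ari = 1,
                               ami = 1, nmi = 1))
  # a single predicted cluster: complete but not homogeneous
  one <- clustering_metrics(c(1, 1, 2, 2), rep(1, 4))
  expect_equal(one$completeness, 1)
  expect_equal(one$homogeneity, 0)
  # random labelings: ARI concentrates near 0
  set.seed(68)
  a <- sample(1:5, 1000, replace = TRUE)
  b <- sample(a)
  expect_lt(abs(clustering_metrics(a, b)$ari), 0.05)
  expect_lt(abs(clustering_metrics(a, b)$ami), 0.05)
  # agreement with an independent ARI implementation
  for (i in 1:5) {
    x <- sample(1:4, 60, replace = TRUE)
    y <- sample(1:3, 60, replace = TRUE)
    expect_equal(clustering_metrics(x, y)$ari,
                 mclust::adjustedRandIndex(x, y))
  }
  expect_error(clustering_metrics(1:3, 1:4), "lengths")
})

test_that("expected mutual information matches a permutation estimate", {
  # AMI's null term: average MI over label permutations with fixed margins
  set.seed(69)
  x <- c(1, 1, 1, 2, 2, 3, 3, 3)
  y <- c(1, 2, 1, 2, 1, 2, 1, 2)
  mi_of <- function(a, b) {
    ct <- table(a, b) / length(a)
    pa <- rowSums(ct); pb <- colSums(ct)
    s <- 0
    for (i in seq_along(pa)) for (j in seq_along(pb)) {
      if (ct[i, j] > 0) s <- s + ct[i, j] * log(ct[i, j] / (pa[i] * pb[j]))
    }
    s
  }
  emi_hat <- mean(replicate(4000, mi_of(x, sample(y))))
  m <- clustering_metrics(x, y)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mean_h <- (h(table(x) / 8) + h(table(y) / 8)) / 2
  # reconstruct the exact EMI from the reported AMI and compare
  emi_exact <- unname((mi_of(x, y) - m$ami * mean_h) / (1 - m$ami))
  expect_equal(emi_exact, emi_hat, tolerance = 0.02)
})
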