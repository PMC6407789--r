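#' Centered log-ratio transform of a count table
#'
#' Per sample (row), `x* = log((x + 1) / g)` where `g` is the geometric
#' mean of the pseudocounted row `(x + 1)`. The pseudocount is applied
#' inside the geometric mean as well, so every transformed row sums to
#' zero and all-zero rows map to zero.
#'
#' @param counts samples x features matrix of nonnegative counts.
#' @return The transformed matrix (rows sum to 0), with attribute
#'   `pseudocount = 1`.
#' @export
clr_transform <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("need at least one feature")
  if (any(counts < 0)) stop("negative counts are not compositional data")
  lx <- log(counts + 1)
  out <- lx - rowMeans(lx)
  attr(out, "pseudocount") <- 1
  out
}

# squared Euclidean distances between rows of x and rows of centers
.sqdist <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
}

# nearest centroid per row; ties broken by lowest centroid index
.nearest_centroid <- function(x, centers) {
  max.col(-.sqdist(x, centers), ties.method = "first")
}

#' Seeded K-means clustering (k-means++ initialization, Lloyd iterations)
#'
#' @param vectors n x d numeric matrix.
#' @param K number of clusters (`K <= n`).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param iter_max maximum Lloyd iterations.
#' @return A list with `labels` (nearest-centroid assignment, ties to the
#'   lowest centroid index), `centroids` (K x d) and `inertia` (total
#'   within-cluster sum of squares).
#' @export
kmeans_cluster <- function(vectors, K, seed = 1L, iter_max = 100L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (K > n) stop("K = ", K, " exceeds the number of points n = ", n)
  set.seed(seed)
  # k-means++ seeding
  centers <- matrix(0, nrow = K, ncol = ncol(vectors))
  centers[1L, ] <- vectors[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- .sqdist(vectors, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2L:K) {
      d2 <- pmax(d2, 0)
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      centers[j, ] <- vectors[pick, ]
      d2 <- pmin(d2, .sqdist(vectors, centers[j, , drop = FALSE])[, 1L])
    }
  }
  if (K == n) {
    labels <- .nearest_centroid(vectors, vectors)
    return(list(labels = labels, centroids = vectors, inertia = 0))
  }
  km <- suppressWarnings(stats::kmeans(vectors, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd"))
  labels <- .nearest_centroid(vectors, km$centers)
  d2 <- .sqdist(vectors, km$centers)
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = unname(km$centers), inertia = inertia)
}

#' Fit pseudo-OTU centroids by clustering sequence embeddings
#'
#' Pseudo-OTUs are the embedding-space analog of OTUs: K-means centroids
#' fitted on a seeded subsample of sequence embeddings (at full scale,
#' roughly 1,000,000 embeddings clustered into K = 1000).
#'
#' @param seq_embeddings n x d matrix of (typically denoised) sequence
#'   embeddings.
#' @param K number of pseudo-OTUs.
#' @param subsample_n number of embeddings to subsample for fitting
#'   (default: all rows).
#' @param seed integer seed.
#' @return A list of class `pseudo_otu_model`: `centroids` (K x d), `K`,
#'   `seed`, `n_training_embeddings`.
#' @export
fit_pseudo_otus <- function(seq_embeddings, K, subsample_n = nrow(seq_embeddings),
                            seed = 1L) {
  seq_embeddings <- as.matrix(seq_embeddings)
  if (subsample_n > nrow(seq_embeddings)) {
    stop("subsample_n exceeds the number of available embeddings")
  }
  if (K > subsample_n) stop("K = ", K, " exceeds subsample_n = ", subsample_n)
  set.seed(seed)
  idx <- sample.int(nrow(seq_embeddings), subsample_n)
  km <- kmeans_cluster(seq_embeddings[idx, , drop = FALSE], K, seed = seed)
  structure(list(centroids = km$centroids, K = as.integer(K),
                 seed = as.integer(seed),
                 n_training_embeddings = as.integer(subsample_n)),
            class = "pseudo_otu_model")
}

#' Assign sequence embeddings to pseudo-OTUs and count per sample
#'
#' Each sequence embedding is assigned to its nearest centroid (Euclidean;
#' ties to the lowest centroid index); counts are tallied per sample. Row
#' sums equal the number of embedded sequences per sample.
#'
#' @param model a `pseudo_otu_model`.
#' @param seq_embeddings n x d matrix of sequence embeddings.
#' @param sample_ids sample id per embedding (length n).
#' @return samples x K integer count matrix (columns `pOTU1..pOTUK`).
#' @export
assign_pseudo_otus <- function(model, seq_embeddings, sample_ids) {
  stopifnot(inherits(model, "pseudo_otu_model"))
  seq_embeddings <- as.matrix(seq_embeddings)
  if (ncol(seq_embeddings) != ncol(model$centroids)) {
    stop(sprintf("embedding dimension %d does not match centroid dimension %d",
                 ncol(seq_embeddings), ncol(model$centroids)))
  }
  stopifnot(nrow(seq_embeddings) == length(sample_ids))
  lab <- .nearest_centroid(seq_embeddings, model$centroids)
  samples <- sort(unique(as.character(sample_ids)))
  out <- matrix(0L, nrow = length(samples), ncol = model$K,
                dimnames = list(samples, paste0("pOTU", seq_len(model$K))))
  tab <- table(factor(as.character(sample_ids), levels = samples),
               factor(lab, levels = seq_len(model$K)))
  out[] <- as.integer(tab)
  out
}

.stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' L1-penalized multinomial logistic regression with seeded CV
#'
#' Fits the softmax (true multinomial) lasso over a descending lambda path
#' and selects the lambda minimizing the mean cross-validated deviance over
#' seeded, stratified folds. Backed by glmnet.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels (>= 2 classes, each with at least `n_folds`
#'   members).
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return A list of class `sparse_linear_model`: `beta` (features x J
#'   coefficient matrix at the selected lambda), `intercepts` (length J),
#'   `lambda`, `class_names`, `nonzero` (per-class nonzero coefficient
#'   counts) and the underlying `cv_fit`.
#' @export
fit_multinomial_lasso <- function(X, y, n_folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("no features")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (any(table(y) < n_folds)) {
    stop("every class needs at least n_folds = ", n_folds, " members")
  }
  foldid <- .stratified_folds(y, n_folds, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "multinomial", alpha = 1,
                          foldid = foldid, type.measure = "deviance",
                          standardize = TRUE)
  co <- glmnet::coef.glmnet(cv$glmnet.fit, s = cv$lambda.min)
  beta <- do.call(cbind, lapply(co, function(m) as.numeric(m[-1L, 1L])))
  rownames(beta) <- rownames(co[[1L]])[-1L]
  colnames(beta) <- levels(y)
  intercepts <- vapply(co, function(m) m[1L, 1L], numeric(1))
  names(intercepts) <- levels(y)
  structure(list(beta = beta, intercepts = intercepts,
                 lambda = cv$lambda.min, class_names = levels(y),
                 nonzero = colSums(beta != 0), cv_fit = cv),
            class = "sparse_linear_model")
}

#' Predict class labels from a fitted sparse multinomial model
#'
#' @param object a `sparse_linear_model`.
#' @param newx samples x features matrix.
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.sparse_linear_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  scores <- newx %*% object$beta +
    matrix(object$intercepts, nrow(newx), length(object$intercepts),
           byrow = TRUE)
  factor(object$class_names[max.col(scores, ties.method = "first")],
         levels = object$class_names)
}

.as_true_factor <- function(y_true, y_pred) {
  # keep declared (possibly empty) classes when y_true is already a factor
  if (!is.factor(y_true)) y_true <- factor(y_true)
  if (any(table(y_true) == 0L)) {
    stop("a declared class has zero members in y_true")
  }
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  if (anyNA(y_pred)) stop("y_pred contains labels outside the declared classes")
  list(t = y_true, p = y_pred)
}

#' Balanced accuracy
#'
#' The mean over classes of the within-class accuracy (recall), which
#' adjusts for class imbalance: `(1/J) * sum_j P(pred = true | true = j)`.
#'
#' @param y_true true class labels (classes taken from its factor levels).
#' @param y_pred predicted labels, drawn from the same class set.
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  z <- .as_true_factor(y_true, y_pred)
  mean(vapply(levels(z$t), function(cl) {
    idx <- z$t == cl
    mean(z$p[idx] == cl)
  }, numeric(1)))
}

#' Classification report: balanced accuracy plus macro P/R/F1
#'
#' Precision, recall and F1 are macro-averaged over classes. A class that
#' receives no predictions has undefined precision and contributes 0 with
#' a warning.
#'
#' @inheritParams balanced_accuracy
#' @return A list with `accuracy` (balanced), `precision`, `recall`, `f1`
#'   (macro) and the `confusion` matrix (true x predicted).
#' @export
classification_report <- function(y_true, y_pred) {
  z <- .as_true_factor(y_true, y_pred)
  cm <- table(true = z$t, pred = z$p)
  J <- nlevels(z$t)
  prec <- rec <- f1 <- numeric(J)
  for (j in seq_len(J)) {
    tp <- cm[j, j]
    pred_j <- sum(cm[, j])
    true_j <- sum(cm[j, ])
    if (pred_j == 0L) {
      warning("class '", levels(z$t)[j],
              "' received no predictions; precision counted as 0")
      prec[j] <- 0
    } else prec[j] <- tp / pred_j
    rec[j] <- tp / true_j
    f1[j] <- if (prec[j] + rec[j] == 0) 0 else
      2 * prec[j] * rec[j] / (prec[j] + rec[j])
  }
  list(accuracy = balanced_accuracy(y_true, y_pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       confusion = cm)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Clustering-fidelity metrics
#'
#' Homogeneity, completeness, adjusted Rand index (ARI), adjusted mutual
#' information (AMI) and normalized mutual information (NMI) between a true
#' labeling and a predicted clustering. AMI and NMI use the arithmetic-mean
#' normalization; AMI's expected mutual information is the exact
#' hypergeometric value.
#'
#' @param labels_true,labels_pred vectors of equal length.
#' @return A list with `homogeneity`, `completeness`, `ari`, `ami`, `nmi`.
#' @export
clustering_metrics <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("labelings have different lengths")
  }
  n <- length(labels_true)
  if (n == 0L) stop("empty labelings")
  ct <- table(labels_true, labels_pred)
  a <- rowSums(ct); b <- colSums(ct)
  hc <- .entropy(a / n); hk <- .entropy(b / n)
  p <- ct / n
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (a[i] * b[j] / n^2))
  }
  homogeneity <- if (hc == 0) 1 else mi / hc
  completeness <- if (hk == 0) 1 else mi / hk
  # ARI
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(as.numeric(ct)))
  sum_a <- sum(comb2(as.numeric(a))); sum_b <- sum(comb2(as.numeric(b)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) 1 else (sum_ij - expected) / (max_index - expected)
  # exact expected MI under the hypergeometric model
  emi <- 0
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      nij_min <- max(1, ai + bj - n)
      nij_max <- min(ai, bj)
      if (nij_min > nij_max) next
      nij <- nij_min:nij_max
      lp <- lgamma(ai + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) +
        lgamma(n - ai + 1) - lgamma(bj - nij + 1) -
        lgamma(n - ai - bj + nij + 1) - (lgamma(n + 1) - lgamma(bj + 1) -
                                           lgamma(n - bj + 1))
      emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  mean_h <- (hc + hk) / 2
  nmi <- if (mean_h == 0) 1 else mi / mean_h
  ami <- if (mean_h - emi == 0) 1 else (mi - emi) / (mean_h - emi)
  list(homogeneity = as.numeric(homogeneity),
       completeness = as.numeric(completeness),
       ari = as.numeric(ari), ami = as.numeric(ami), nmi = as.numeric(nmi))
}
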