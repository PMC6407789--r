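test_that("global identity matches hand-checkable alignments", {
  s <- random_dna(40, seed = 81)
  expect_equal(global_identity(s, s)$identity, 1)
  expect_equal(global_identity("A", "C")$identity, 0)
  # best global alignment of ACGT vs ACGA: 3 matches over 4 columns
  expect_equal(global_identity("ACGT", "ACGA")$identity, 0.75)
  expect_error(global_identity("", "ACGT"), "empty")
})

test_that("identity is symmetric and degrades under added mismatches", {
  set.seed(82)
  drops <- integer(0)
  for (i in 1:8) {
    s <- random_dna(120)
    mutate_at <- function(x, pos) {
      ch <- strsplit(x, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        character(1))
      paste(ch, collapse = "")
    }
    p1 <- sample(120, 6)
    m1 <- mutate_at(s, p1)
    m2 <- mutate_at(m1, sample(setdiff(1:120, p1), 6))
    i1 <- global_identity(s, m1)$identity
    i2 <- global_identity(s, m2)$identity
    expect_equal(global_identity(m1, s)$identity, i1)
    drops <- c(drops, i1 - i2)
  }
  expect_true(all(drops >= 0))
  expect_gt(mean(drops), 0.02)
})

test_that("identity matrices agree with scalar calls and honor grouping", {
  set.seed(83)
  seqs <- vapply(1:4, function(i) random_dna(60), character(1))
  m <- identity_matrix(seqs)
  expect_equal(m, t(m))
  expect_equal(m[2, 3], global_identity(seqs[2], seqs[3])$identity)
  grouped <- identity_matrix(seqs, within = c("a", "a", "b", "b"))
  expect_true(is.na(grouped[1, 3]))
  expect_equal(grouped[1, 2], m[1, 2])
})

test_that("greedy clustering recovers sequence families at 0.8 identity", {
  set.seed(84)
  same <- rep(random_dna(50), 4)
  expect_equal(max(greedy_cluster(same)$membership), 1L)

  roots <- vapply(1:3, function(i) random_dna(150), character(1))
  mutate_rate <- function(x, r) {
    ch <- strsplit(x, "")[[1]]
    hit <- which(runif(length(ch)) < r)
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  fams <- unlist(lapply(1:3, function(i) {
    vapply(1:4, function(j) mutate_rate(roots[i], 0.03), character(1))
  }))
  cl <- greedy_cluster(fams, identity_threshold = 0.8)
  expect_equal(clustering_metrics(rep(1:3, each = 4), cl$membership)$ari, 1)

  distinct <- vapply(1:4, function(i) random_dna(30), character(1))
  expect_equal(max(greedy_cluster(distinct, identity_threshold = 1)$membership),
               4L)
})

test_that("consensus takes the column majority with deterministic ties", {
  expect_equal(consensus_sequence("ACGT"), "ACGT")
  expect_equal(consensus_sequence(c("A", "A", "C")), "A")
  expect_equal(consensus_sequence(c("A", "C")), "A")
  # a gap-majority column is omitted; a gap tie goes to the base
  expect_equal(consensus_sequence(c("A-G", "A-G", "ACG")), "AG")
  expect_equal(consensus_sequence(c("A-", "AC")), "AC")
  expect_error(consensus_sequence(c("AC", "ACG")), "equal length")
})

test_that("consensus embeddings align with their own cluster embeddings", {
  m <- small_toy_model()
  set.seed(85)
  mk <- function() paste(sample(m$vocab$kmer, 5, replace = TRUE), collapse = "")
  # singleton clusters: consensus equals the member, diagonal is exactly 1
  singles <- list(c1 = mk(), c2 = mk(), c3 = mk())
  cam <- consensus_agreement_matrix(singles, m)
  expect_equal(unname(diag(cam$cosine)), rep(1, 3), tolerance = 1e-9)
  expect_equal(cam$diagonal_argmax_rate, 1)
  # two clusters with identical content: tied argmax counts as failure
  s <- mk()
  cam2 <- consensus_agreement_matrix(list(a = c(s, s), b = c(s, s)), m)
  expect_equal(cam2$diagonal_argmax_rate, 0)
})

test_that("the taxon-level trend matches a hand OLS and flat inputs", {
  # constant scores: zero slope after centering
  sc <- matrix(0.5, 4, 4); diag(sc) <- 1
  taxa <- data.frame(l1 = c("a", "a", "a", "a"), l2 = c("x", "x", "y", "y"))
  tr <- taxon_level_similarity_trend(sc, taxa)
  expect_equal(tr$slope, 0)

  # two-level toy with hand-computed pooled z-scores and OLS slope
  sc2 <- matrix(NA_real_, 4, 4)
  sc2[lower.tri(sc2)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  sc2 <- pmax(sc2, t(sc2), na.rm = TRUE); diag(sc2) <- 1
  # level 1 shares everything (6 pairs); level 2 pairs (1,2) and (3,4)
  taxa2 <- data.frame(l1 = rep("a", 4), l2 = c("x", "x", "y", "y"))
  tr2 <- taxon_level_similarity_trend(sc2, taxa2)
  lvl1 <- sc2[lower.tri(sc2)]
  lvl2 <- c(sc2[2, 1], sc2[4, 3])
  pooled <- c(lvl1, lvl2)
  z <- (pooled - mean(pooled)) / sd(pooled)
  d <- rep(c(1, 2), c(6, 2))
  slope_hand <- sum((d - mean(d)) * (z - mean(z))) / sum((d - mean(d))^2)
  expect_equal(tr2$slope, slope_hand, tolerance = 1e-12)

  # scores increasing with depth recover slope ~ 1/sd(pooled)
  set.seed(86)
  n <- 30
  taxa3 <- data.frame(l1 = rep("a", n),
                      l2 = rep(c("x", "y"), each = n / 2))
  sc3 <- matrix(0, n, n)
  for (i in 2:n) for (j in 1:(i - 1)) {
    lev <- if (taxa3$l2[i] == taxa3$l2[j]) 2 else 1
    sc3[i, j] <- sc3[j, i] <- lev + rnorm(1, sd = 0.01)
  }
  tr3 <- taxon_level_similarity_trend(sc3, taxa3)
  expect_gt(tr3$slope, 0)
  # transparent recomputation: collect, pool-z, ordinary least squares
  low <- lower.tri(sc3)
  raw1 <- sc3[outer(taxa3$l1, taxa3$l1, "==") & low]
  raw2 <- sc3[outer(taxa3$l2, taxa3$l2, "==") & low]
  pooled3 <- c(raw1, raw2)
  z3 <- (pooled3 - mean(pooled3)) / sd(pooled3)
  d3 <- rep(c(1, 2), c(length(raw1), length(raw2)))
  hand <- stats::lm(z3 ~ d3)
  expect_equal(tr3$slope, unname(coef(hand)[2]), tolerance = 1e-12)
  expect_equal(tr3$r_squared, summary(hand)$r.squared, tolerance = 1e-12)
})
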