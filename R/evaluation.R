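# Alignment-based comparison analyses: global-alignment identity, greedy
# centroid clustering, column-majority consensus sequences, and the
# embedding-vs-alignment agreement analyses (consensus/cluster cosine
# matrices and the taxon-level similarity trend).

#' Global-alignment identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (via
#' Biostrings); identity is the number of matched columns divided by the
#' total number of alignment columns, gaps counted in the denominator.
#' Defaults resemble common usearch-family scoring.
#'
#' @param a,b nonempty nucleotide strings (ACGT).
#' @param match match score.
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening penalty (negative).
#' @param gap_extend gap extension penalty (negative).
#' @return A list of class `pairwise_identity`: `identity` in `[0, 1]`,
#'   `matches`, `columns`, `score`.
#' @export
global_identity <- function(a, b, match = 2, mismatch = -4,
                            gap_open = -10, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = abs(gap_open),
                                       gapExtension = abs(gap_extend))
  pat <- as.character(Biostrings::alignedPattern(aln))
  cols <- nchar(pat)
  matches <- Biostrings::nmatch(aln)
  structure(list(identity = matches / cols, matches = matches,
                 columns = cols, score = Biostrings::score(aln)),
            class = "pairwise_identity")
}

#' Pairwise identity matrix for a set of sequences
#'
#' Alignments against each subject are batched (one vectorized
#' Needleman-Wunsch call per subject), so `n` sequences need `n - 1`
#' alignment calls rather than `n(n-1)/2`.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param match,mismatch,gap_open,gap_extend scoring, as in
#'   [global_identity()].
#' @param within optional grouping vector of length `n`; identities are
#'   computed only for pairs in the same group (others left `NA`). Useful
#'   when downstream analyses only consume within-clade pairs.
#' @return Symmetric n x n matrix of identities (unit diagonal); `NA` for
#'   pairs excluded by `within`.
#' @export
identity_matrix <- function(seqs, match = 2, mismatch = -4,
                            gap_open = -10, gap_extend = -1, within = NULL) {
  n <- length(seqs)
  out <- matrix(NA_real_, n, n)
  diag(out) <- 1
  if (!is.null(within)) stopifnot(length(within) == n)
  if (n > 1L) {
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
    pats <- Biostrings::DNAStringSet(seqs)
    for (j in seq_len(n - 1L)) {
      idx <- (j + 1L):n
      if (!is.null(within)) idx <- idx[within[idx] == within[j]]
      if (length(idx) == 0L) next
      aln <- Biostrings::pairwiseAlignment(pats[idx], seqs[j], type = "global",
                                           substitutionMatrix = sub,
                                           gapOpening = abs(gap_open),
                                           gapExtension = abs(gap_extend))
      ids <- Biostrings::nmatch(aln) /
        nchar(as.character(Biostrings::alignedPattern(aln)))
      out[idx, j] <- out[j, idx] <- ids
    }
  }
  dimnames(out) <- list(names(seqs), names(seqs))
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Input-order greedy clustering: the first unassigned sequence becomes a
#' centroid; each subsequent sequence joins the first existing centroid
#' with which its global-alignment identity is `>= identity_threshold`,
#' otherwise it founds a new cluster. Deterministic given the input order.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param identity_threshold identity threshold in `(0, 1]` (0.8 is a
#'   practical default for 16S cluster/consensus analyses).
#' @param ... passed to [global_identity()].
#' @return A list with `membership` (cluster index per sequence) and
#'   `centroids` (index of each cluster's founding sequence).
#' @export
greedy_cluster <- function(seqs, identity_threshold = 0.8, ...) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  n <- length(seqs)
  membership <- integer(n)
  centroids <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (ci in seq_along(centroids)) {
      idn <- global_identity(seqs[i], seqs[centroids[ci]], ...)$identity
      if (idn >= identity_threshold) {
        membership[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroids <- c(centroids, i)
      membership[i] <- length(centroids)
    }
  }
  list(membership = membership, centroids = centroids)
}

#' Column-majority consensus of equal-length (pre-aligned) sequences
#'
#' Per column, the most frequent symbol wins; ties among nucleotides are
#' broken alphabetically (`A < C < G < T`), and a gap (`-`) wins a column
#' only when strictly more frequent than every nucleotide, in which case
#' the column is omitted from the consensus.
#'
#' @param seqs character vector of equal-length sequences (gaps as `-`).
#' @return The consensus nucleotide string.
#' @export
consensus_sequence <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) {
    stop("sequences must be pre-aligned to equal length; found lengths ",
         paste(lens, collapse = ", "))
  }
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                     use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  cols <- apply(m, 2L, function(col) {
    tab <- table(col)
    bases <- tab[names(tab) != "-"]
    gap_n <- if ("-" %in% names(tab)) tab[["-"]] else 0L
    if (length(bases) == 0L || gap_n > max(bases)) return("")
    winners <- names(bases)[bases == max(bases)]
    sort(winners)[1L]
  })
  paste(cols, collapse = "")
}

#' Consensus-vs-cluster embedding agreement
#'
#' For each cluster, embeds (1) the consensus sequence of its members and
#' (2) the pooled tokens of all members (the cluster embedding), denoises
#' consensus and cluster embeddings jointly, and reports the matrix of
#' cosine similarities plus the fraction of clusters whose consensus
#' embedding is most similar to its own cluster embedding (diagonal
#' argmax; ties count as failures).
#'
#' @param clusters named list of character vectors of member sequences
#'   (equal length within each cluster so a consensus is defined).
#' @param model a `kmer_embedding_model`.
#' @param weighting optional `query_weighting`; by default computed from
#'   all member sequences.
#' @return A list with `cosine` (consensus x cluster matrix),
#'   `diagonal_argmax_rate`, and `excluded` (clusters whose consensus had
#'   no in-vocabulary tokens).
#' @export
consensus_agreement_matrix <- function(clusters, model, weighting = NULL) {
  stopifnot(length(clusters) >= 2L, inherits(model, "kmer_embedding_model"))
  if (is.null(names(clusters))) names(clusters) <- paste0("cluster", seq_along(clusters))
  k <- model$params$k
  member_tokens <- lapply(clusters, function(s) {
    unlist(lapply(s, tokenize, k = k), use.names = FALSE)
  })
  if (is.null(weighting)) {
    weighting <- compute_query_weights(member_tokens, model)
  }
  cons_tokens <- lapply(clusters, function(s) tokenize(consensus_sequence(s), k))
  cons_ok <- vapply(cons_tokens, function(t) any(t %in% model$vocab$kmer),
                    logical(1))
  if (any(!cons_ok)) {
    warning("excluding cluster(s) with no embeddable consensus: ",
            paste(names(clusters)[!cons_ok], collapse = ", "))
  }
  keep <- which(cons_ok)
  if (length(keep) < 2L) stop("fewer than 2 embeddable clusters")
  K <- length(keep)
  batch <- embed_sets_raw(c(cons_tokens[keep], member_tokens[keep]), model,
                          weighting, level = "cluster",
                          ids = c(paste0("consensus.", names(clusters)[keep]),
                                  paste0("cluster.", names(clusters)[keep])))
  den <- denoise_batch(batch$vectors)$vectors
  cons_e <- den[seq_len(K), , drop = FALSE]
  clus_e <- den[K + seq_len(K), , drop = FALSE]
  cosm <- .cosine_matrix(cons_e, clus_e)
  dimnames(cosm) <- list(names(clusters)[keep], names(clusters)[keep])
  hit <- vapply(seq_len(K), function(i) {
    mx <- max(cosm[i, ])
    sum(cosm[i, ] == mx) == 1L && which.max(cosm[i, ]) == i
  }, logical(1))
  list(cosine = cosm, diagonal_argmax_rate = mean(hit),
       excluded = names(clusters)[!cons_ok])
}

#' Taxon-level similarity trend
#'
#' For each taxonomic level, collects pairwise scores among items that
#' share a taxon at that level, z-scores all collected scores with the
#' pooled mean and standard deviation, and fits an ordinary least-squares
#' line of z-score against level depth (coded `1..L`, ascending toward the
#' species-like level). A positive slope means items become more similar
#' as the shared taxon gets more specific.
#'
#' @param scores symmetric n x n matrix of pairwise scores (cosine
#'   similarities or alignment identities).
#' @param taxa data.frame with n rows and one column per taxonomic level,
#'   ordered from root-most to leaf-most; taxon labels must be unique
#'   across lineages (e.g. full path prefixes).
#' @return A list of class `trend_result`: `levels`, `slope` (z-score
#'   change per level step), `r_squared`, `per_level_sd`, `per_level_mean`,
#'   `n_pairs`, and `z` (list of per-level z-scored score vectors).
#' @export
taxon_level_similarity_trend <- function(scores, taxa) {
  scores <- as.matrix(scores)
  taxa <- as.data.frame(taxa)
  n <- nrow(scores)
  stopifnot(n == nrow(taxa), ncol(taxa) >= 2L)
  L <- ncol(taxa)
  lower <- lower.tri(scores)
  per_level <- vector("list", L)
  names(per_level) <- colnames(taxa)
  for (l in seq_len(L)) {
    same <- outer(taxa[[l]], taxa[[l]], "==") & lower
    s <- scores[same]
    per_level[[l]] <- s[!is.na(s)]
  }
  has_pairs <- lengths(per_level) >= 1L
  if (any(!has_pairs)) {
    warning("level(s) without a within-taxon pair skipped: ",
            paste(names(per_level)[!has_pairs], collapse = ", "))
  }
  used <- which(has_pairs)
  pooled <- unlist(per_level[used], use.names = FALSE)
  mu <- mean(pooled); sdv <- stats::sd(pooled)
  if (!is.finite(sdv) || sdv == 0) {
    z <- lapply(per_level[used], function(s) s - mu)
  } else {
    z <- lapply(per_level[used], function(s) (s - mu) / sdv)
  }
  depth <- rep(used, lengths(z))
  fit <- stats::lm(unlist(z, use.names = FALSE) ~ depth)
  structure(list(levels = names(per_level)[used],
                 slope = unname(stats::coef(fit)[2L]),
                 r_squared = summary(fit)$r.squared,
                 per_level_sd = vapply(z, stats::sd, numeric(1)),
                 per_level_mean = vapply(z, mean, numeric(1)),
                 n_pairs = lengths(z), z = z),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("taxon-level similarity trend: slope %.3f z/level (R^2 = %.3f)\n",
              x$slope, x$r_squared))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %-10s n_pairs %6d  mean z %7.3f  sd %6.3f\n", x$levels[i],
                x$n_pairs[i], x$per_level_mean[i], x$per_level_sd[i]))
  }
  invisible(x)
}
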