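# Taxonomy-structured synthetic 16S-like data. A random root sequence is
# propagated down a fixed-branching hierarchy; each edge at level l applies
# i.i.d. substitutions at that level's rate (substituted bases resample
# uniformly among the 3 alternatives, Jukes-Cantor style, so two leaves
# diverge in proportion to the rate accumulated along their paths).
# Reads are uniform-start substrings with i.i.d. substitution errors and a
# constant Phred score consistent with the error rate. Samples draw a taxon
# composition from a Dirichlet around a class-specific base composition, so
# a class label ("body site") shapes which taxa a sample contains.

#' Specification of a synthetic taxonomy
#'
#' @param levels named integer vector: children per node at each level,
#'   ordered root-most to leaf-most. The default `c(phylum = 2, class = 3,
#'   genus = 3, species = 3)` yields 54 leaf species.
#' @param subst_rate_per_level per-level substitution probability applied
#'   along each edge (same order as `levels`); each must lie in
#'   `[0, 0.75]`.
#' @param root_length root sequence length in nucleotides (1.5 kb mimics a
#'   full-length 16S gene).
#' @param seed integer seed.
#' @return A list of class `taxonomy_spec`.
#' @export
taxonomy_spec <- function(levels = c(phylum = 2L, class = 3L, genus = 3L,
                                     species = 3L),
                          subst_rate_per_level = c(0.08, 0.04, 0.02, 0.01),
                          root_length = 1500L, seed = 1L) {
  stopifnot(length(levels) == length(subst_rate_per_level),
            all(levels >= 1L), root_length >= 1L)
  if (any(subst_rate_per_level < 0 | subst_rate_per_level > 0.75)) {
    stop("substitution rates must lie in [0, 0.75]")
  }
  if (is.null(names(levels))) {
    names(levels) <- paste0("level", seq_along(levels))
  }
  structure(list(levels = levels,
                 subst_rate_per_level = subst_rate_per_level,
                 root_length = as.integer(root_length),
                 seed = as.integer(seed)),
            class = "taxonomy_spec")
}

.BASES <- c("A", "C", "G", "T")

.mutate_seq <- function(chars, rate) {
  if (rate == 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    # resample uniformly among the 3 alternative bases
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(.BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  chars
}

#' Simulate full-length sequences down a taxonomy
#'
#' @param spec a [taxonomy_spec()].
#' @return A data.frame with one row per leaf: `id`, one column per
#'   taxonomic level holding the full path label (so labels are unique
#'   across lineages), and `seq`; the ancestral root sequence is attached
#'   as attribute `root_seq`. Deterministic given `spec$seed`.
#' @export
simulate_taxonomy_sequences <- function(spec) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  set.seed(spec$seed)
  root <- sample(.BASES, spec$root_length, replace = TRUE)
  nodes <- list(list(chars = root, comps = character(0)))
  for (l in seq_along(spec$levels)) {
    rate <- spec$subst_rate_per_level[l]
    nxt <- list()
    for (node in nodes) {
      for (child in seq_len(spec$levels[l])) {
        comp <- paste0(substr(names(spec$levels)[l], 1, 1), child)
        nxt[[length(nxt) + 1L]] <- list(chars = .mutate_seq(node$chars, rate),
                                        comps = c(node$comps, comp))
      }
    }
    nodes <- nxt
  }
  # level labels are full path prefixes, unique across lineages
  tax <- t(vapply(nodes, function(n) {
    vapply(seq_along(n$comps), function(l) {
      paste(n$comps[seq_len(l)], collapse = ".")
    }, character(1))
  }, character(length(spec$levels))))
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  colnames(tax) <- names(spec$levels)
  out <- data.frame(id = paste0("leaf", seq_along(nodes)), tax,
                    seq = vapply(nodes, function(n) paste(n$chars, collapse = ""),
                                 character(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "root_seq") <- paste(root, collapse = "")
  out
}

# internal: simulate one read per entry of source_idx from seqs[source_idx]
.sim_reads_from_sources <- function(seqs, source_idx, read_length, error_rate) {
  lens <- nchar(seqs)[source_idx]
  if (any(read_length > lens)) stop("read_length exceeds a source sequence length")
  starts <- floor(stats::runif(length(source_idx)) * (lens - read_length + 1))
  raw <- substr(seqs[source_idx], starts + 1L, starts + read_length)
  if (error_rate > 0) {
    chars <- matrix(unlist(strsplit(raw, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(raw), byrow = TRUE)
    hit <- which(stats::runif(length(chars)) < error_rate)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(.BASES, b), 1L),
                           character(1), USE.NAMES = FALSE)
    }
    raw <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  }
  q <- if (error_rate > 0) {
    min(40L, as.integer(round(-10 * log10(error_rate))))
  } else 40L
  list(seq = raw, start = as.integer(starts),
       qual = strrep(intToUtf8(q + 33L), read_length))
}

#' Simulate error-bearing reads from full-length sequences
#'
#' Uniform random start positions, i.i.d. substitution errors at
#' `error_rate`, and a constant Phred score consistent with the error rate.
#' Each read records its source sequence and 0-based start.
#'
#' @param full_length a data.frame with columns `id` and `seq` (e.g. from
#'   [simulate_taxonomy_sequences()]).
#' @param read_length read length in nucleotides (125 mimics trimmed
#'   short-read amplicon data).
#' @param error_rate per-base substitution error probability.
#' @param reads_per_seq reads drawn from each source sequence.
#' @param seed integer seed.
#' @return A sequence-record data.frame with extra columns `source_id` and
#'   `start`.
#' @export
simulate_reads <- function(full_length, read_length = 125L, error_rate = 0.005,
                           reads_per_seq = 10L, seed = 1L) {
  stopifnot(reads_per_seq >= 1L, error_rate >= 0, error_rate < 1)
  set.seed(seed)
  src <- rep(seq_len(nrow(full_length)), each = reads_per_seq)
  r <- .sim_reads_from_sources(full_length$seq, src, read_length, error_rate)
  out <- seq_records(paste0("read", seq_along(src)), r$seq, r$qual)
  out$source_id <- full_length$id[src]
  out$start <- r$start
  out
}

#' Simulate a labeled multi-sample study
#'
#' Each class (e.g. body site) receives a base composition over the leaf
#' taxa in which a class-specific subset of taxa is up-weighted by
#' `1 + class_signature_strength`; with strength 0 all classes share one
#' base composition. Each sample draws its own composition from a
#' Dirichlet centered on its class base
#' (`Dirichlet(dirichlet_concentration * base)`), draws read counts per
#' taxon multinomially, and reads are simulated as in [simulate_reads()].
#'
#' @param full_length leaf sequences from [simulate_taxonomy_sequences()]
#'   (taxonomy columns are carried onto the reads).
#' @param classes character vector of class labels (>= 2).
#' @param dirichlet_concentration Dirichlet precision around the class
#'   base; larger values give more homogeneous samples within a class.
#' @param class_signature_strength extra weight on each class's signature
#'   taxa; 0 removes all class signal.
#' @param reads_per_sample reads drawn per sample.
#' @param n_samples_per_class samples per class.
#' @param read_length read length.
#' @param error_rate per-base read error rate.
#' @param signature_level taxonomy column whose clades are assigned (round
#'   robin, seeded) to classes as signature taxa. Real body-site
#'   compositions differ predominantly in deep clades (e.g. the phyla
#'   dominating gut versus skin), so the default up-weights whole
#'   second-level subtrees; set to `NA` to scatter signature taxa over
#'   individual leaves instead.
#' @param seed integer seed; the whole study is bit-reproducible given the
#'   seed.
#' @return A list of class `synthetic_study`: `sequences` (the leaves),
#'   `reads` (records with `sample_id`, `source_id`, `taxon`, `start`),
#'   `samples` (data.frame `sample_id`, `class_label`), `params`.
#' @export
simulate_samples <- function(full_length, classes = c("fecal", "skin", "tongue"),
                             dirichlet_concentration = 50,
                             class_signature_strength = 5,
                             reads_per_sample = 500L,
                             n_samples_per_class = 40L,
                             read_length = 125L, error_rate = 0.005,
                             signature_level = NULL, seed = 1L) {
  stopifnot(length(classes) >= 2L, reads_per_sample >= 1L,
            n_samples_per_class >= 1L, class_signature_strength >= 0,
            dirichlet_concentration > 0)
  set.seed(seed)
  n_leaf <- nrow(full_length)
  J <- length(classes)
  # disjoint signature taxon subsets, one per class: whole clades at
  # signature_level (deep compositional differences, as between body
  # sites), or individual leaves when no taxonomy is available
  taxcols0 <- setdiff(colnames(full_length), c("id", "seq"))
  if (is.null(signature_level)) {
    signature_level <- if (length(taxcols0) >= 2L) taxcols0[2L] else NA
  }
  if (!is.na(signature_level)) {
    if (!signature_level %in% taxcols0) {
      stop("signature_level '", signature_level, "' is not a taxonomy column")
    }
    clades <- unique(full_length[[signature_level]])
    if (length(clades) < J) {
      stop("fewer clades at '", signature_level, "' than classes")
    }
    clade_class <- sample(rep_len(seq_len(J), length(clades)))
    assignment <- clade_class[match(full_length[[signature_level]], clades)]
  } else {
    assignment <- sample(rep_len(seq_len(J), n_leaf))
  }
  base <- vapply(seq_len(J), function(j) {
    w <- 1 + class_signature_strength * (assignment == j)
    w / sum(w)
  }, numeric(n_leaf))
  base <- matrix(base, nrow = n_leaf) # vapply drops dims when n_leaf == 1
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g <- rep(1, length(alpha))
    g / sum(g)
  }
  samples <- data.frame(
    sample_id = paste0("s", seq_len(J * n_samples_per_class)),
    class_label = rep(classes, each = n_samples_per_class),
    stringsAsFactors = FALSE)
  taxcols <- setdiff(colnames(full_length), c("id", "seq"))
  leaf_taxon <- if (length(taxcols)) full_length[[taxcols[length(taxcols)]]] else
    full_length$id
  read_list <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    j <- match(samples$class_label[i], classes)
    comp <- rdirichlet1(dirichlet_concentration * base[, j])
    counts <- as.integer(stats::rmultinom(1L, reads_per_sample, comp))
    src <- rep(seq_len(n_leaf), counts)
    r <- .sim_reads_from_sources(full_length$seq, src, read_length, error_rate)
    df <- seq_records(paste0(samples$sample_id[i], ".r", seq_along(src)),
                      r$seq, r$qual)
    df$sample_id <- samples$sample_id[i]
    df$source_id <- full_length$id[src]
    df$taxon <- leaf_taxon[src]
    df$start <- r$start
    read_list[[i]] <- df
  }
  structure(list(sequences = full_length,
                 reads = do.call(rbind, read_list),
                 samples = samples,
                 params = list(classes = classes,
                               dirichlet_concentration = dirichlet_concentration,
                               class_signature_strength = class_signature_strength,
                               reads_per_sample = as.integer(reads_per_sample),
                               n_samples_per_class = as.integer(n_samples_per_class),
                               read_length = as.integer(read_length),
                               error_rate = error_rate,
                               signature_level = signature_level,
                               signature_assignment = assignment,
                               seed = as.integer(seed))),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d samples (%s), %d reads, %d leaf taxa\n",
              nrow(x$samples),
              paste(unique(x$samples$class_label), collapse = "/"),
              nrow(x$reads), nrow(x$sequences)))
  invisible(x)
}

#' Convert a synthetic study to a sample table
#'
#' @param study a `synthetic_study`.
#' @return A `sample_table` usable with [filter_samples()].
#' @export
as_sample_table <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  reads <- split(study$reads, study$reads$sample_id)
  reads <- reads[study$samples$sample_id]
  sample_table(study$samples$sample_id, study$samples$class_label, reads)
}

#' Write a synthetic study to FASTA/FASTQ plus manifest and taxon table
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly. Writes `full_length.fasta`, one FASTQ per
#'   sample, `manifest.tsv` (sample_id, class_label, file_path) and
#'   `taxonomy.tsv`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(study$sequences[, c("id", "seq")], file.path(dir, "full_length.fasta"))
  files <- character(nrow(study$samples))
  for (i in seq_len(nrow(study$samples))) {
    sid <- study$samples$sample_id[i]
    files[i] <- paste0(sid, ".fastq")
    write_fastq(study$reads[study$reads$sample_id == sid, , drop = FALSE],
                file.path(dir, files[i]))
  }
  utils::write.table(data.frame(sample_id = study$samples$sample_id,
                                class_label = study$samples$class_label,
                                file_path = files),
                     file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$sequences[, setdiff(colnames(study$sequences), "seq")],
                     file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
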