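# Sequence records are plain data.frames with columns:
#   id   - record identifier (first whitespace-separated token of the header)
#   seq  - uppercased nucleotide string
#   qual - Phred+33-encoded quality string (FASTQ encoding), or NA_character_
# The encoded representation is compact for 1e5-scale read sets; qualities
# are decoded to integer Phred scores on demand.

#' Construct a set of sequence records
#'
#' @param id record identifiers.
#' @param seq nucleotide strings (uppercased).
#' @param qual Phred+33-encoded quality strings (FASTQ encoding), or `NA`
#'   for sequences without qualities.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
seq_records <- function(id, seq, qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  data.frame(id = as.character(id), seq = toupper(as.character(seq)),
             qual = rep_len(as.character(qual), length(id)),
             stringsAsFactors = FALSE)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of FASTQ-encoded quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
decode_qual <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    if (nchar(q) == 0L) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

.check_parseable <- function(path, marker) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) {
      stop(sprintf("parse error in '%s': empty file (line %d)", path, lineno + 1L))
    }
    lineno <- lineno + 1L
    if (nzchar(trimws(ln))) {
      if (!startsWith(ln, marker)) {
        stop(sprintf("parse error in '%s' at line %d: expected '%s' header, found '%s'",
                     path, lineno, marker, substr(ln, 1L, 30L)))
      }
      return(invisible(TRUE))
    }
  }
}

#' Read a FASTA file
#'
#' Sequences are uppercased; records are returned in file order. Gzipped
#' input is handled transparently.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return A data.frame of sequence records (columns `id`, `seq`, `qual`;
#'   `qual` is `NA` for FASTA input).
#' @export
read_fasta <- function(path) {
  .check_parseable(path, ">")
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0L) stop(sprintf("parse error in '%s': no records (line 1)", path))
  ids <- sub("\\s.*$", "", names(x))
  seq_records(ids, as.character(x))
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path path to a FASTQ file (optionally gzip-compressed).
#' @return A data.frame of sequence records with per-base qualities kept as
#'   Phred+33 strings in the `qual` column.
#' @export
read_fastq <- function(path) {
  .check_parseable(path, "@")
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(x) == 0L) stop(sprintf("parse error in '%s': no records (line 1)", path))
  ids <- sub("\\s.*$", "", names(x))
  seq_records(ids, as.character(x), as.character(S4Vectors::mcols(x)$qualities))
}

#' Write sequence records to FASTA
#'
#' @param records a sequence-record data.frame.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  chunks <- vapply(records$seq, function(s) {
    n <- nchar(s)
    if (n <= width) return(s)
    paste(substring(s, seq(1L, n, width), pmin(seq(1L, n, width) + width - 1L, n)),
          collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  writeLines(paste0(">", records$id, "\n", chunks), path)
  invisible(path)
}

#' Write sequence records to FASTQ
#'
#' All records must carry quality strings.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (anyNA(records$qual)) stop("all records need quality strings to write FASTQ")
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", records$qual), path)
  invisible(path)
}

#' Quality-control parameters for amplicon reads
#'
#' Mirrors the read preprocessing applied to 125-nt amplicon data: fixed
#' positional trimming, quality truncation at the first low-quality base,
#' and an expected-error filter.
#'
#' @param trim_start 0-based inclusive start of the retained window.
#' @param trim_end 0-based exclusive end of the retained window.
#' @param trunc_q Phred threshold: the read is cut before the first base with
#'   quality `<= trunc_q`.
#' @param max_ee maximum sum of per-base error probabilities
#'   `10^(-q/10)` tolerated after trimming/truncation.
#' @param min_sample_reads minimum post-QC reads for a sample to be retained.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(trim_start = 10L, trim_end = 135L, trunc_q = 2L,
                      max_ee = 2, min_sample_reads = 10000L) {
  stopifnot(trim_start < trim_end, trunc_q >= 0, max_ee > 0,
            min_sample_reads >= 0)
  structure(list(trim_start = as.integer(trim_start),
                 trim_end = as.integer(trim_end),
                 trunc_q = as.integer(trunc_q), max_ee = max_ee,
                 min_sample_reads = as.integer(min_sample_reads)),
            class = "qc_params")
}

#' Quality-filter reads
#'
#' Each read is (1) sliced to the window `[trim_start, trim_end)`,
#' (2) truncated before the first base with Phred score `<= trunc_q`, and
#' (3) retained only if its expected errors `sum(10^(-q/10))` do not exceed
#' `max_ee`. Reads whose trim window extends past the read end are dropped
#' and counted. Input order is preserved.
#'
#' @param records sequence records with quality strings (e.g. from
#'   [read_fastq()]).
#' @param params a [qc_params()] object.
#' @param exclude optional character vector of exact sequences to drop after
#'   trimming (hook for protocol-specific contaminant lists, e.g. bloom
#'   sequences).
#' @return The surviving records, with attributes `n_dropped_window`,
#'   `n_dropped_trunc` (empty after truncation), `n_dropped_ee` and
#'   `n_dropped_excluded` recording the drop tallies.
#' @export
qc_filter_reads <- function(records, params = qc_params(), exclude = NULL) {
  if (nrow(records) > 0L && anyNA(records$qual)) {
    stop("qc_filter_reads requires quality scores on every record")
  }
  ts <- params$trim_start
  te <- params$trim_end
  n <- nrow(records)
  keep <- logical(n)
  out_seq <- character(n)
  out_qual <- character(n)
  n_win <- 0L; n_trunc <- 0L; n_ee <- 0L; n_ex <- 0L
  thr <- params$trunc_q + 33L
  for (i in seq_len(n)) {
    s <- records$seq[i]
    if (nchar(s) < te) { n_win <- n_win + 1L; next }
    q <- utf8ToInt(substr(records$qual[i], ts + 1L, te))
    bad <- which(q <= thr)
    len <- if (length(bad)) bad[1L] - 1L else length(q)
    if (len == 0L) { n_trunc <- n_trunc + 1L; next }
    q <- q[seq_len(len)]
    ee <- sum(10^(-(q - 33L) / 10))
    if (ee > params$max_ee) { n_ee <- n_ee + 1L; next }
    sq <- substr(s, ts + 1L, ts + len)
    if (!is.null(exclude) && sq %in% exclude) { n_ex <- n_ex + 1L; next }
    keep[i] <- TRUE
    out_seq[i] <- sq
    out_qual[i] <- intToUtf8(q)
  }
  out <- records[keep, , drop = FALSE]
  out$seq <- out_seq[keep]
  out$qual <- out_qual[keep]
  rownames(out) <- NULL
  structure(out, n_dropped_window = n_win, n_dropped_trunc = n_trunc,
            n_dropped_ee = n_ee, n_dropped_excluded = n_ex)
}

#' Build a sample table from per-sample reads
#'
#' @param sample_ids character vector of sample identifiers.
#' @param class_labels class label per sample (e.g. body site), drawn from a
#'   finite set.
#' @param reads list of sequence-record data.frames, one per sample.
#' @return A list of class `sample_table` keyed by sample id; each element
#'   has fields `sample_id`, `class_label` and `reads`.
#' @export
sample_table <- function(sample_ids, class_labels, reads) {
  stopifnot(length(sample_ids) == length(class_labels),
            length(sample_ids) == length(reads),
            !anyDuplicated(sample_ids))
  out <- Map(function(s, cl, r) list(sample_id = s, class_label = cl, reads = r),
             as.character(sample_ids), as.character(class_labels), reads)
  names(out) <- sample_ids
  structure(out, class = "sample_table")
}

#' Read a sample manifest and load its read files
#'
#' The manifest is delimited text with columns `sample_id`, `class_label`,
#' `file_path` (FASTA or FASTQ, optionally gzipped; paths resolved relative
#' to the manifest).
#'
#' @param path manifest path.
#' @param sep field separator (default tab).
#' @return A `sample_table`.
#' @export
read_sample_manifest <- function(path, sep = "\t") {
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "class_label", "file_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns sample_id, class_label, file_path")
  }
  base <- dirname(normalizePath(path))
  reads <- lapply(m$file_path, function(fp) {
    if (!file.exists(fp)) fp <- file.path(base, fp)
    if (grepl("\\.(fq|fastq)(\\.gz)?$", fp)) read_fastq(fp) else read_fasta(fp)
  })
  sample_table(m$sample_id, m$class_label, reads)
}

#' Drop samples with too few reads
#'
#' Samples with strictly fewer than `min_sample_reads` reads are removed;
#' the remaining samples are untouched.
#'
#' @param table a `sample_table`.
#' @param min_sample_reads minimum read count (strict "fewer than" rule:
#'   a sample with exactly this many reads is retained).
#' @return The filtered `sample_table` (possibly empty).
#' @export
filter_samples <- function(table, min_sample_reads) {
  stopifnot(inherits(table, "sample_table"))
  keep <- vapply(table, function(s) nrow(s$reads) >= min_sample_reads, logical(1))
  structure(unclass(table)[keep], class = "sample_table")
}
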