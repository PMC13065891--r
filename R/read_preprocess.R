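# Read preprocessing: FASTQ ingest, per-read quality gates, 3' A/U tail
# trimming, collapsing of identical reads, the final 16-25 nt retention
# window, and the per-dataset QC verdict.
#
# The pipeline expects adapter-trimmed input (cutadapt-style upstream
# trimming is delegated, not re-implemented); all gates below act on the
# trimmed reads.

#' Read a small-RNA FASTQ file
#'
#' Sanger Phred+33 encoding; gzip-compressed files are accepted. Sequences
#' are normalized to the internal RNA alphabet (T becomes U).
#'
#' @param path FASTQ(.gz) path
#' @return data.frame with `read_id`, `seq` (RNA), `qual` (Phred+33 string)
#' @export
read_fastq <- function(path) {
  # Biostrings warns unconditionally about dropped mcols on FASTQ input
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(
    read_id = sub("\\s.*$", "", names(x)),
    seq = dna_to_rna(as.character(x)),
    qual = as.character(methods::as(Biostrings::quality(x), "PhredQuality")),
    stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (DNA alphabet on disk)
#' @param reads data.frame as returned by [read_fastq()]
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", rna_to_dna(reads$seq),
                    "\n+\n", reads$qual), con)
  invisible(path)
}

#' Per-read quality gates
#'
#' Drops a read when it has more than `max_n` ambiguous bases (N), when its
#' length falls outside `[min_len, max_len]`, or when its mean Phred quality
#' is at or below `min_mean_q` (the boundary is an inclusive drop: mean
#' quality exactly 20 is removed). The drop reason is recorded as
#' `ambiguous`, `length` or `quality`, checked in that order.
#'
#' @param reads data.frame from [read_fastq()]
#' @param max_n maximum tolerated N count (default 5)
#' @param min_len,max_len QC length window (defaults 15, 25)
#' @param min_mean_q mean-quality drop threshold (default 20, inclusive drop)
#' @return list with `kept` (reads data.frame) and `dropped`
#'   (data.frame `read_id`, `reason`)
#' @export
filter_reads <- function(reads, max_n = 5L, min_len = 15L, max_len = 25L,
                         min_mean_q = 20) {
  len <- nchar(reads$seq)
  n_amb <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  # mean Phred per read, via one decode of the concatenated quality string
  qlen <- nchar(reads$qual)
  if (nrow(reads)) {
    cs <- c(0, cumsum(as.numeric(utf8ToInt(paste(reads$qual, collapse = "")))))
    ends <- cumsum(qlen)
    meanq <- ifelse(qlen > 0, (cs[ends + 1L] - cs[ends - qlen + 1L]) / qlen - 33, 0)
  } else meanq <- numeric(0)
  reason <- rep(NA_character_, nrow(reads))
  reason[meanq <= min_mean_q] <- "quality"
  reason[len < min_len | len > max_len] <- "length"
  reason[n_amb > max_n] <- "ambiguous"
  keep <- is.na(reason)
  list(kept = reads[keep, , drop = FALSE],
       dropped = data.frame(read_id = reads$read_id[!keep],
                            reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Trim non-templated 3' A/U tails
#'
#' Animal miRNA 3' ends are frequently extended by untemplated A or U
#' addition; the last two bases of each read are therefore inspected
#' iteratively (3'-most first) and removed while they are A or U, at most
#' two removals. A terminal non-A/U base blocks further trimming.
#'
#' @param seqs character vector of RNA sequences
#' @return trimmed sequences
#' @export
trim_three_prime_au <- function(seqs) {
  for (i in 1:2) {
    last <- substr(seqs, nchar(seqs), nchar(seqs))
    cut <- nchar(seqs) > 0L & (last == "A" | last == "U")
    seqs[cut] <- substr(seqs[cut], 1L, nchar(seqs[cut]) - 1L)
  }
  seqs
}

#' Collapse identical reads
#'
#' Groups reads by (post-trim) sequence; the collapsed record keeps the
#' multiplicity and the arithmetic per-position mean Phred quality across
#' duplicates. Multiplicity is conserved: counts sum to the input size.
#'
#' @param reads data.frame with `seq` and `qual`
#' @return data.frame with `seq`, `count`, and `qual` (list column of
#'   per-position mean Phred scores)
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      qual = I(list()), stringsAsFactors = FALSE))
  groups <- split(reads$qual, reads$seq)
  seqs <- names(groups)
  counts <- lengths(groups)
  mq <- lapply(groups, function(g) {
    if (length(g) == 1L) as.numeric(utf8ToInt(g) - 33L)
    else rowMeans(matrix(utf8ToInt(paste(g, collapse = "")) - 33L,
                         nrow = nchar(g[1])))
  })
  out <- data.frame(seq = seqs, count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$qual <- unname(mq)
  out
}

#' Final length retention window
#'
#' Applied after trimming and collapsing: only reads between `min_len` and
#' `max_len` nucleotides (default 16-25, both inclusive) are retained.
#'
#' @param collapsed data.frame from [collapse_reads()]
#' @param min_len,max_len retention window (defaults 16, 25)
#' @return filtered collapsed data.frame
#' @export
length_gate_final <- function(collapsed, min_len = 16L, max_len = 25L) {
  len <- nchar(collapsed$seq)
  collapsed[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Full preprocessing of one sample
#'
#' filter -> 3' A/U trim -> collapse -> final length gate, returning the
#' collapsed read set plus gate-by-gate accounting.
#'
#' @param reads data.frame from [read_fastq()]
#' @inheritParams filter_reads
#' @param final_min,final_max final retention window (defaults 16, 25)
#' @return list with `collapsed`, `qc` (named counts), `dropped`
#' @export
preprocess_reads <- function(reads, max_n = 5L, min_len = 15L, max_len = 25L,
                             min_mean_q = 20, final_min = 16L, final_max = 25L) {
  raw_bases <- sum(nchar(reads$seq))
  f <- filter_reads(reads, max_n = max_n, min_len = min_len,
                    max_len = max_len, min_mean_q = min_mean_q)
  kept <- f$kept
  kept$seq <- trim_three_prime_au(kept$seq)
  kept$qual <- substr(kept$qual, 1L, nchar(kept$seq))
  collapsed <- collapse_reads(kept)
  final <- length_gate_final(collapsed, final_min, final_max)
  qc <- c(total_raw_reads = nrow(reads),
          clean_reads = nrow(kept),
          dropped_ambiguous = sum(f$dropped$reason == "ambiguous"),
          dropped_length = sum(f$dropped$reason == "length"),
          dropped_quality = sum(f$dropped$reason == "quality"),
          bases_raw = raw_bases,
          bases_retained = sum(nchar(kept$seq)),
          unique_after_collapse = nrow(collapsed),
          unique_after_final_gate = nrow(final))
  list(collapsed = final, qc = qc, dropped = f$dropped)
}

#' Per-dataset QC verdict
#'
#' A dataset passes when it retains at least `min_clean_reads` clean reads,
#' at least `min_frac_bases` of its raw bases after trimming, and at least
#' `min_mapped_reads` 16-25 nt reads mapped to the miRNA references. Each
#' gate can be relaxed individually for desk-scale testing.
#'
#' @param qc named counts from [preprocess_reads()]
#' @param mapped_16_25_reads mapped-read count from the alignment stage
#' @param min_clean_reads default 1e6
#' @param min_frac_bases default 0.60
#' @param min_mapped_reads default 1e5
#' @return list with the gate values, individual verdicts and overall `pass`
#' @export
dataset_qc <- function(qc, mapped_16_25_reads,
                       min_clean_reads = 1e6, min_frac_bases = 0.60,
                       min_mapped_reads = 1e5) {
  frac <- unname(qc[["bases_retained"]] / qc[["bases_raw"]])
  gates <- c(clean_reads = unname(qc[["clean_reads"]]) >= min_clean_reads,
             fraction_bases_retained = frac >= min_frac_bases,
             mapped_16_25 = mapped_16_25_reads >= min_mapped_reads)
  list(total_raw_reads = unname(qc[["total_raw_reads"]]),
       clean_reads = unname(qc[["clean_reads"]]),
       fraction_bases_retained = frac,
       mapped_16_25_reads = mapped_16_25_reads,
       gates = gates, pass = all(gates))
}
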