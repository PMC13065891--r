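# Internal sequence and quality helpers shared across modules.
# All sequences are handled as plain uppercase character vectors:
# RNA alphabet {A,C,G,U,N} internally, DNA {A,C,G,T,N} only at the
# genome-exclusion boundary and in FASTQ files on disk.

#' @importFrom methods as is
NULL

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Upper-cases and converts T to U. Any character outside {A,C,G,U,N}
#' raises an error naming the offending record.
#'
#' @param x character vector of sequences
#' @param ids optional identifiers used in error messages
#' @return character vector over {A,C,G,U,N}
#' @keywords internal
normalize_rna <- function(x, ids = NULL) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    stop("non-nucleotide characters in sequence: ", lab, call. = FALSE)
  }
  out
}

#' @keywords internal
rna_to_dna <- function(x) chartr("U", "T", toupper(x))

#' @keywords internal
dna_to_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement
#'
#' @param x sequences; `alphabet` selects RNA (A-U) or DNA (A-T) pairing.
#' @keywords internal
revcomp <- function(x, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  comp <- if (alphabet == "rna") chartr("ACGUN", "UGCAN", x) else chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Decode a Phred+33 quality string to integer scores
#' @keywords internal
phred_decode <- function(q) {
  lapply(q, function(s) utf8ToInt(s) - 33L)
}

#' Encode integer Phred scores to a Phred+33 string
#' @keywords internal
phred_encode <- function(q) {
  vapply(q, function(v) intToUtf8(pmin(v, 60L) + 33L), character(1))
}

#' Exact substring matching of a single query against a set of subjects
#'
#' Returns every full-length occurrence of `query` in each subject,
#' as a data.frame with subject id and 1-based start. This is the
#' no-mismatch matching primitive behind the two-pass read assignment.
#'
#' @param query single sequence
#' @param subjects named character vector of reference sequences
#' @return data.frame(ref_id, start) with zero rows when absent
#' @keywords internal
match_exact <- function(query, subjects) {
  hits_id <- character(0)
  hits_start <- integer(0)
  for (i in seq_along(subjects)) {
    m <- gregexpr(query, subjects[[i]], fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      hits_id <- c(hits_id, rep(names(subjects)[i], length(m)))
      hits_start <- c(hits_start, as.integer(m))
    }
  }
  data.frame(ref_id = hits_id, start = hits_start, stringsAsFactors = FALSE)
}

#' Mean silhouette width for a labelled score matrix
#'
#' Standard Rousseeuw silhouette on Euclidean distances; used to
#' quantify condition separation in PCA score space.
#'
#' @param x numeric matrix (samples x dimensions) or vector
#' @param labels group labels, length nrow(x)
#' @return mean silhouette width in [-1, 1]
#' @export
silhouette_width <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) <= 1L) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
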