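# Reference database: pre-miRNA hairpins, mature-arm annotation, catalogued
# A-to-I editing sites, and the per-site edited reference sequences used by
# the second alignment pass.

#' Load pre-miRNA hairpins and mature-arm annotation
#'
#' Reads a hairpin FASTA (miRBase dialect: RNA or DNA alphabet, case
#' insensitive) together with a mature-arm annotation table and returns a
#' validated reference set. All coordinates are 1-based inclusive positions
#' within the hairpin.
#'
#' The mature table must be TSV with a header row and columns
#' `pre_id`, `mature_id`, `start`, `end`, `arm` (arm is `5p` or `3p`).
#'
#' @param premirna_fasta path to the hairpin FASTA
#' @param mature_tsv path to the mature-arm annotation TSV
#' @return a `premirna_set`: list with `seq` (named character, RNA alphabet)
#'   and `arms` (data.frame with `pre_id`, `mature_id`, `start`, `end`,
#'   `arm`, `mature_seq`)
#' @export
load_references <- function(premirna_fasta, mature_tsv) {
  fa <- Biostrings::readBStringSet(premirna_fasta)
  ids <- sub("\\s.*$", "", names(fa))
  seqs <- stats::setNames(as.character(fa), ids)
  arms <- utils::read.delim(mature_tsv, stringsAsFactors = FALSE)
  needed <- c("pre_id", "mature_id", "start", "end", "arm")
  if (!all(needed %in% names(arms)))
    stop("mature annotation must have columns: ", paste(needed, collapse = ", "))
  premirna_set(seqs, arms)
}

#' Construct a validated pre-miRNA reference set from in-memory objects
#'
#' @param seqs named character vector of hairpin sequences
#' @param arms data.frame with pre_id, mature_id, start, end, arm
#' @return a `premirna_set`
#' @export
premirna_set <- function(seqs, arms) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate pre-miRNA id: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)
  seqs <- stats::setNames(normalize_rna(seqs, names(seqs)), names(seqs))
  len <- nchar(seqs)
  if (any(len < 40 | len > 200))
    warning("hairpin length outside the expected 40-200 nt range: ",
            paste(names(seqs)[len < 40 | len > 200], collapse = ", "))
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  arms$start <- as.integer(arms$start); arms$end <- as.integer(arms$end)
  missing_pre <- setdiff(arms$pre_id, names(seqs))
  if (length(missing_pre))
    stop("mature record references unknown pre-miRNA: ",
         paste(missing_pre, collapse = ", "), call. = FALSE)
  if (!all(arms$arm %in% c("5p", "3p")))
    stop("arm must be '5p' or '3p'", call. = FALSE)
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    L <- nchar(seqs[[a$pre_id]])
    if (a$start < 1L || a$end > L || a$start > a$end)
      stop("mature interval out of bounds for ", a$mature_id,
           " on ", a$pre_id, " (", a$start, "-", a$end, ", hairpin ", L, " nt)",
           call. = FALSE)
    w <- a$end - a$start + 1L
    if (w < 15L || w > 30L)
      warning("mature arm length outside the expected 15-30 nt range: ",
              a$mature_id)
  }
  dup <- duplicated(arms[, c("pre_id", "arm")])
  if (any(dup))
    stop("more than one ", arms$arm[dup][1], " arm on ", arms$pre_id[dup][1],
         call. = FALSE)
  arms$mature_seq <- substr(seqs[arms$pre_id], arms$start, arms$end)
  structure(list(seq = seqs, arms = arms), class = "premirna_set")
}

#' @export
print.premirna_set <- function(x, ...) {
  cat("premirna_set:", length(x$seq), "hairpins,", nrow(x$arms), "mature arms\n")
  invisible(x)
}

#' Load and validate a catalogue of known A-to-I editing sites
#'
#' The site table stands in for externally curated editing-site lists; it is
#' TSV with a header and columns `site_id`, `pre_id`, `mature_id`,
#' `mature_pos` (1-based within the mature arm). The hairpin position is
#' derived (`pre_pos = arm start + mature_pos - 1`) and the reference base at
#' every site must be A; anything else is a hard error listing the offender.
#'
#' @param refs a `premirna_set`
#' @param sites_tsv path to the site TSV, or a data.frame with the same columns
#' @return data.frame with `site_id`, `pre_id`, `mature_id`, `mature_pos`,
#'   `pre_pos`, `ref_base`
#' @export
load_edit_sites <- function(refs, sites_tsv) {
  sites <- if (is.character(sites_tsv))
    utils::read.delim(sites_tsv, stringsAsFactors = FALSE) else
    as.data.frame(sites_tsv, stringsAsFactors = FALSE)
  needed <- c("site_id", "pre_id", "mature_id", "mature_pos")
  if (!all(needed %in% names(sites)))
    stop("site table must have columns: ", paste(needed, collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ", sites$site_id[duplicated(sites$site_id)][1])
  sites$mature_pos <- as.integer(sites$mature_pos)
  key <- paste(refs$arms$pre_id, refs$arms$mature_id)
  idx <- match(paste(sites$pre_id, sites$mature_id), key)
  if (anyNA(idx))
    stop("site references unknown mature arm: ",
         paste(sites$site_id[is.na(idx)], collapse = ", "), call. = FALSE)
  arm <- refs$arms[idx, ]
  arm_len <- arm$end - arm$start + 1L
  bad_pos <- sites$mature_pos < 1L | sites$mature_pos > arm_len
  if (any(bad_pos))
    stop("mature_pos outside arm for site: ",
         paste(sites$site_id[bad_pos], collapse = ", "), call. = FALSE)
  sites$pre_pos <- arm$start + sites$mature_pos - 1L
  sites$ref_base <- substr(refs$seq[sites$pre_id], sites$pre_pos, sites$pre_pos)
  not_a <- sites$ref_base != "A"
  if (any(not_a))
    stop("editing site reference base is not A: ",
         paste(sites$site_id[not_a], collapse = ", "), call. = FALSE)
  sites[, c("site_id", "pre_id", "mature_id", "mature_pos", "pre_pos", "ref_base")]
}

#' Build single-site edited reference sequences
#'
#' For every validated editing site, produces one hairpin variant carrying G
#' instead of A at the site position. Multi-site co-edited haplotypes are
#' deliberately not enumerated: each edited reference differs from the
#' unedited hairpin at exactly one position.
#'
#' @param refs a `premirna_set`
#' @param sites validated site table from [load_edit_sites()]
#' @return data.frame with `site_id`, `pre_id`, `pre_pos`, `sequence`
#' @export
build_edited_references <- function(refs, sites) {
  base <- substr(refs$seq[sites$pre_id], sites$pre_pos, sites$pre_pos)
  if (any(base != "A"))
    stop("editing site reference base is not A: ",
         paste(sites$site_id[base != "A"], collapse = ", "), call. = FALSE)
  seqs <- refs$seq[sites$pre_id]
  substr(seqs, sites$pre_pos, sites$pre_pos) <- "G"
  data.frame(site_id = sites$site_id, pre_id = sites$pre_id,
             pre_pos = sites$pre_pos, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}
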