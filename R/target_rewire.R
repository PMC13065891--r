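# Seed-mediated target prediction for unedited versus edited mature
# miRNAs, and functional-domain annotation of editing positions.
#
# Inosine pairs like guanosine during hybridization, so the edited miRNA is
# modelled as its A-to-G substituted sequence. Targeting uses the three
# canonical site types defined on the miRNA seed (nucleotides 2-8): an
# exact Watson-Crick match in the 3'UTR to nts 2-8 (7mer-m8), to nts 2-7
# followed by an A opposite nt 1 (7mer-A1), or both combined (8mer).

#' Edited form of a mature miRNA
#'
#' Single A-to-G substitution at `mature_pos`; the reference base there
#' must be A.
#'
#' @param mature_seq RNA sequence of the mature miRNA
#' @param mature_pos 1-based edited position
#' @return edited sequence
#' @export
edited_mature <- function(mature_seq, mature_pos) {
  mature_seq <- normalize_rna(mature_seq)
  if (mature_pos < 1L || mature_pos > nchar(mature_seq))
    stop("mature_pos outside the mature sequence", call. = FALSE)
  if (substr(mature_seq, mature_pos, mature_pos) != "A")
    stop("base at mature_pos is not A", call. = FALSE)
  substr(mature_seq, mature_pos, mature_pos) <- "G"
  mature_seq
}

#' Canonical seed-site patterns of a mature miRNA
#'
#' Patterns are returned in target 5'->3' orientation:
#' 7mer-m8 is the reverse complement of miRNA nts 2-8, 7mer-A1 the reverse
#' complement of nts 2-7 followed by A, and 8mer the 7mer-m8 followed by A.
#'
#' @param mature_seq RNA sequence, length >= 8
#' @return named character vector with `8mer`, `7mer-m8`, `7mer-A1`
#' @export
seed_site_patterns <- function(mature_seq) {
  mature_seq <- normalize_rna(mature_seq)
  if (nchar(mature_seq) < 8L)
    stop("mature sequence must be at least 8 nt", call. = FALSE)
  m8 <- revcomp(substr(mature_seq, 2L, 8L))
  a1 <- paste0(revcomp(substr(mature_seq, 2L, 7L)), "A")
  c("8mer" = paste0(m8, "A"), "7mer-m8" = m8, "7mer-A1" = a1)
}

#' Scan 3'UTRs for canonical seed sites
#'
#' Finds every exact occurrence of the three patterns in each UTR. A
#' position matching the 8mer is reported once, as 8mer (priority
#' 8mer > 7mer-m8 > 7mer-A1); the contained 7mer matches at the same
#' register are suppressed.
#'
#' @param patterns named patterns from [seed_site_patterns()]
#' @param utrs named character vector of 3'UTR sequences (RNA or DNA)
#' @return data.frame `utr_id`, `site_type`, `utr_pos` (1-based start)
#' @export
scan_utrs <- function(patterns, utrs) {
  utrs <- stats::setNames(normalize_rna(dna_to_rna(utrs), names(utrs)),
                          names(utrs))
  res <- list()
  for (uid in names(utrs)) {
    u <- utrs[[uid]]
    pos <- lapply(patterns, function(p) {
      m <- gregexpr(p, u, fixed = TRUE)[[1]]
      if (m[1] == -1L) integer(0) else as.integer(m)
    })
    p8 <- pos[["8mer"]]
    pm8 <- setdiff(pos[["7mer-m8"]], p8)
    pa1 <- setdiff(pos[["7mer-A1"]], p8 + 1L)
    if (length(p8) + length(pm8) + length(pa1) == 0L) next
    df <- data.frame(
      utr_id = rep(uid, length(p8) + length(pm8) + length(pa1)),
      site_type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                      c(length(p8), length(pm8), length(pa1))),
      utr_pos = c(p8, pm8, pa1), stringsAsFactors = FALSE)
    if (nrow(df)) res[[uid]] <- df[order(df$utr_pos), , drop = FALSE]
  }
  if (!length(res))
    return(data.frame(utr_id = character(0), site_type = character(0),
                      utr_pos = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Target set of a mature miRNA over a UTR collection
#'
#' @param mature_seq mature miRNA sequence
#' @param utrs named UTR sequences
#' @return character vector of distinct target UTR ids
#' @export
target_set <- function(mature_seq, utrs) {
  sort(unique(scan_utrs(seed_site_patterns(mature_seq), utrs)$utr_id))
}

#' Overlap between two target-gene sets
#'
#' Default metric is Jaccard, |A intersect B| / |A union B|, with the
#' convention that two empty sets overlap 0. `method = "retained"` instead
#' reports the fraction of unedited targets still targeted after editing.
#'
#' @param set_unedited,set_edited character vectors of target ids
#' @param method `"jaccard"` or `"retained"`
#' @return overlap fraction in [0, 1]
#' @export
target_overlap <- function(set_unedited, set_edited,
                           method = c("jaccard", "retained")) {
  method <- match.arg(method)
  a <- unique(set_unedited); b <- unique(set_edited)
  if (method == "jaccard") {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
  } else {
    if (length(a) == 0L) return(0)
    length(intersect(a, b)) / length(a)
  }
}

#' Functional domain of a mature-miRNA position
#'
#' Partition used for interpreting where an editing site falls:
#' nt 1 is the 5' anchor, nts 2-8 the seed, nts 9-12 the central region,
#' nts 13-16 the 3' supplementary region, and nts 17 onward the 3' tail.
#'
#' @param mature_pos 1-based position(s) in the mature miRNA
#' @return character vector of domain labels
#' @export
annotate_domain <- function(mature_pos) {
  if (any(mature_pos < 1L)) stop("mature_pos must be >= 1", call. = FALSE)
  cut_points <- c(1, 2, 9, 13, 17, Inf)
  labels <- c("5p_anchor", "seed", "central", "supplementary_3p", "tail_3p")
  labels[findInterval(mature_pos, cut_points)]
}

#' Target rewiring induced by one editing site
#'
#' Runs the full unedited-versus-edited comparison: seed patterns, UTR
#' scans, target sets, overlap, and the functional domain of the edit.
#'
#' @param mature_seq unedited mature sequence
#' @param mature_pos edited position (must be A)
#' @param utrs named UTR sequences
#' @param method overlap metric, see [target_overlap()]
#' @return list with `domain`, `targets_unedited`, `targets_edited`,
#'   `overlap`, and the two site tables
#' @export
rewire_targets <- function(mature_seq, mature_pos, utrs,
                           method = c("jaccard", "retained")) {
  ed <- edited_mature(mature_seq, mature_pos)
  sites_un <- scan_utrs(seed_site_patterns(mature_seq), utrs)
  sites_ed <- scan_utrs(seed_site_patterns(ed), utrs)
  set_un <- sort(unique(sites_un$utr_id))
  set_ed <- sort(unique(sites_ed$utr_id))
  list(domain = annotate_domain(mature_pos),
       targets_unedited = set_un, targets_edited = set_ed,
       overlap = target_overlap(set_un, set_ed, method = method),
       sites_unedited = sites_un, sites_edited = sites_ed)
}
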