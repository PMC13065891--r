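# Two-pass no-mismatch assignment of collapsed reads to pre-miRNA
# references. Pass 1 matches each read as an exact full-length substring of
# the unedited hairpins; only reads unmatched there proceed to pass 2
# against the single-site edited references. An edited-reference hit counts
# as editing evidence only when the read actually covers the substituted
# base -- otherwise the read is indistinguishable from unedited sequence and
# is re-routed. Exact full-length containment replaces a no-mismatch BLAST
# search: for queries this short the two contracts coincide, and substring
# matching is deterministic and dependency-free.

#' Build an exact-substring index over reference sequences
#'
#' @param seqs named character vector of reference sequences
#' @return a `substring_index` object supporting [query_index()]
#' @export
build_index <- function(seqs) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  # references concatenated with a separator no query can contain, so a
  # single fixed-pattern scan answers a lookup over the whole set
  lens <- nchar(seqs)
  begins <- cumsum(c(1L, head(lens + 1L, -1L)))
  structure(list(seqs = seqs,
                 concat = paste(seqs, collapse = "#"),
                 begins = begins, lens = lens),
            class = "substring_index")
}

#' Look up all exact full-length occurrences of a query
#'
#' @param idx a `substring_index`
#' @param query one sequence
#' @return data.frame(ref_id, start) of 1-based hit starts
#' @export
query_index <- function(idx, query) {
  h <- index_hits(idx, query)
  data.frame(ref_id = h$ref_id, start = h$start, stringsAsFactors = FALSE)
}

# allocation-light lookup used on the per-read hot path
index_hits <- function(idx, query) {
  m <- gregexpr(query, idx$concat, fixed = TRUE)[[1]]
  if (m[1] == -1L)
    return(list(ref_id = character(0), start = integer(0), n = 0L))
  pos <- as.integer(m)
  ref <- findInterval(pos, idx$begins)
  list(ref_id = names(idx$seqs)[ref], start = pos - idx$begins[ref] + 1L,
       n = length(pos))
}

#' Assign collapsed reads to unedited and edited references
#'
#' Implements the two-pass contract. Multi-mapping reads receive fractional
#' weight 1/k over their k hits (k distinct covering sites in pass 2).
#'
#' @param collapsed collapsed reads from [preprocess_reads()]
#' @param refs a `premirna_set`
#' @param edited edited references from [build_edited_references()]
#' @return data.frame with one row per (read, hit): `seq`, `count`,
#'   `status` (unedited/edited/unassigned), `ref_id` (hairpin id), `start`,
#'   `end`, `site_id`, `weight`, `reason` (for unassigned rows)
#' @export
assign_reads <- function(collapsed, refs, edited) {
  un_idx <- build_index(refs$seq)
  ed_seqs <- stats::setNames(edited$sequence, edited$site_id)
  ed_idx <- if (length(ed_seqs)) build_index(ed_seqs) else NULL
  ed_pos <- stats::setNames(edited$pre_pos, edited$site_id)
  ed_pre <- stats::setNames(edited$pre_id, edited$site_id)
  n <- nrow(collapsed)
  acc <- list(seq = vector("list", n), count = vector("list", n),
              status = vector("list", n), ref_id = vector("list", n),
              start = vector("list", n), site_id = vector("list", n),
              weight = vector("list", n), reason = vector("list", n))
  put <- function(i, s, cnt, status, ref_id, start, site_id, weight, reason) {
    k <- length(ref_id)
    acc$seq[[i]] <<- rep(s, k); acc$count[[i]] <<- rep(cnt, k)
    acc$status[[i]] <<- rep(status, k); acc$ref_id[[i]] <<- ref_id
    acc$start[[i]] <<- start; acc$site_id[[i]] <<- site_id
    acc$weight[[i]] <<- rep(weight, k); acc$reason[[i]] <<- rep(reason, k)
  }
  for (i in seq_len(n)) {
    s <- collapsed$seq[i]; cnt <- collapsed$count[i]; L <- nchar(s)
    h1 <- index_hits(un_idx, s)
    if (h1$n) {
      put(i, s, cnt, "unedited", h1$ref_id, h1$start,
          rep(NA_character_, h1$n), 1 / h1$n, NA_character_)
      next
    }
    h2 <- if (!is.null(ed_idx)) index_hits(ed_idx, s) else list(n = 0L)
    if (h2$n) {
      covers <- h2$start <= ed_pos[h2$ref_id] &
        ed_pos[h2$ref_id] <= h2$start + L - 1L
      if (any(covers)) {
        k <- sum(covers)
        put(i, s, cnt, "edited", unname(ed_pre[h2$ref_id[covers]]),
            h2$start[covers], h2$ref_id[covers], 1 / k, NA_character_)
        next
      }
      # hit does not span the substituted base: the matched window is
      # identical to unedited hairpin sequence, so route it there
      h1b <- index_hits(un_idx, s)
      if (h1b$n) {
        put(i, s, cnt, "unedited", h1b$ref_id, h1b$start,
            rep(NA_character_, h1b$n), 1 / h1b$n, NA_character_)
        next
      }
    }
    put(i, s, cnt, "unassigned", NA_character_, NA_integer_,
        NA_character_, 0, "unmapped")
  }
  start <- unlist(acc$start)
  out <- data.frame(seq = unlist(acc$seq), count = unlist(acc$count),
                    status = unlist(acc$status), ref_id = unlist(acc$ref_id),
                    start = start,
                    end = start + nchar(unlist(acc$seq)) - 1L,
                    site_id = unlist(acc$site_id),
                    weight = unlist(acc$weight), reason = unlist(acc$reason),
                    stringsAsFactors = FALSE)
  out$end[out$status == "unassigned"] <- NA_integer_
  out
}

#' Demote edited reads that perfectly match the genome
#'
#' Reads supporting an edited reference but occurring verbatim (either
#' strand, DNA alphabet) anywhere in the supplied genome are more
#' parsimoniously explained as genomic sequence and are demoted to
#' unassigned with reason `genomic`. With `genome = NULL` the stage is
#' skipped with a warning and nothing is demoted.
#'
#' @param assignments assignment table from [assign_reads()]
#' @param genome named character vector of genome sequences (DNA), or NULL
#' @return the assignment table with genomic edited reads demoted
#' @export
exclude_genome_matchers <- function(assignments, genome = NULL) {
  if (is.null(genome)) {
    warning("no genome supplied: perfect-match exclusion skipped")
    return(assignments)
  }
  ed <- assignments$status == "edited"
  if (!any(ed)) return(assignments)
  seqs <- unique(assignments$seq[ed])
  fw <- rna_to_dna(seqs)
  rc <- revcomp(fw, alphabet = "dna")
  hit <- vapply(seq_along(seqs), function(i) {
    any(vapply(genome, function(g)
      grepl(fw[i], g, fixed = TRUE) || grepl(rc[i], g, fixed = TRUE),
      logical(1)))
  }, logical(1))
  bad <- assignments$seq %in% seqs[hit] & ed
  if (any(bad)) {
    demoted <- unique(assignments$seq[bad])
    keep <- !(assignments$seq %in% demoted & ed)
    extra <- data.frame(seq = demoted,
                        count = assignments$count[match(demoted, assignments$seq)],
                        status = "unassigned", ref_id = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        site_id = NA_character_, weight = 0,
                        reason = "genomic", stringsAsFactors = FALSE)
    assignments <- rbind(assignments[keep, , drop = FALSE], extra)
  }
  assignments
}

#' Attribute assigned reads to mature arms
#'
#' A read is attributed to a mature arm when its match interval lies within
#' the arm interval extended by two nucleotides on each side (isomiR slack).
#' A read attributable to k distinct mature arms across references
#' contributes weight 1/k to each.
#'
#' @param assignments assignment table from [assign_reads()]
#' @param refs a `premirna_set`
#' @param slack nucleotides of tolerance around the arm interval (default 2)
#' @return data.frame `seq`, `count`, `pre_id`, `mature_id`, `weight`
#' @export
attribute_mature <- function(assignments, refs, slack = 2L) {
  hits <- assignments[assignments$status != "unassigned", , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      pre_id = character(0), mature_id = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  arms <- refs$arms
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    a <- arms[arms$pre_id == h$ref_id &
                h$start >= arms$start - slack &
                h$end <= arms$end + slack, , drop = FALSE]
    if (nrow(a))
      out[[i]] <- data.frame(seq = h$seq, count = h$count, pre_id = a$pre_id,
                             mature_id = a$mature_id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(seq = character(0), count = integer(0),
                      pre_id = character(0), mature_id = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  out <- unique(out)             # one row per (read, distinct arm)
  k <- table(out$seq)
  out$weight <- 1 / as.numeric(k[out$seq])
  out
}

#' Mapped-read count in the final length window
#'
#' Multiplicity-expanded number of reads assigned to any reference,
#' feeding the dataset-level mapped-read QC gate.
#'
#' @param assignments assignment table
#' @return numeric count
#' @export
count_mapped_reads <- function(assignments) {
  m <- assignments[assignments$status != "unassigned",
                   c("seq", "count"), drop = FALSE]
  sum(unique(m)$count)
}
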