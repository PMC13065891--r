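# Per-sample editing quantification and significance testing.
#
# At each catalogued site the editing level is the fraction of reads
# carrying G among reads covering the position (after quality masking of
# the G-supporting reads), and significance is assessed against a
# sequencing-error null: a one-sided upper-tail binomial test of the edited
# count versus the per-base A-to-G miscall rate, BH-corrected across all
# candidate sites of the sample.

#' Sequencing-error model
#'
#' `epsilon_ag` is the probability that a true A is read as G at a single
#' base. It must lie in (0, 0.25): larger values are indistinguishable from
#' signal for the upper-tail test.
#'
#' @param epsilon_ag per-base A-to-G miscall probability
#' @return an `error_model` object
#' @export
error_model <- function(epsilon_ag = 0.001 / 3) {
  if (!is.numeric(epsilon_ag) || epsilon_ag <= 0 || epsilon_ag >= 0.25)
    stop("epsilon_ag must lie in (0, 0.25)", call. = FALSE)
  structure(list(epsilon_ag = epsilon_ag), class = "error_model")
}

#' Estimate the A-to-G miscall rate from aligned reads
#'
#' Mean per-base miscall probability computed from the (collapsed,
#' per-position mean) Phred scores of all assigned reads, divided by 3 for
#' the uniform-direction assumption. Falls back to `default` with a warning
#' when fewer than `min_bases` aligned bases are available.
#'
#' @param collapsed collapsed reads (with the `qual` list column)
#' @param assignments assignment table from [assign_reads()]
#' @param default fallback epsilon_ag (default 0.001)
#' @param min_bases minimum aligned bases for estimation (default 10000)
#' @return an `error_model`
#' @export
estimate_error_rate <- function(collapsed, assignments, default = 0.001,
                                min_bases = 10000) {
  aligned <- unique(assignments$seq[assignments$status != "unassigned"])
  sel <- collapsed$seq %in% aligned
  n_bases <- sum(collapsed$count[sel] * nchar(collapsed$seq[sel]))
  if (n_bases < min_bases) {
    warning("fewer than ", min_bases,
            " aligned bases; using default epsilon_ag = ", default)
    return(error_model(default))
  }
  p_sum <- 0
  for (i in which(sel))
    p_sum <- p_sum + collapsed$count[i] * sum(10^(-collapsed$qual[[i]] / 10))
  error_model(p_sum / n_bases / 3)
}

#' Pile up read support at one editing site
#'
#' Coverage counts every assigned read whose match interval spans the site
#' position; the edited count is the weighted sum of reads matching the
#' site's edited reference whose mean base quality at the substituted
#' position is at least `min_base_q`. Edited reads failing the quality mask
#' are removed from numerator and denominator alike (masking only the
#' numerator would bias levels downward).
#'
#' @param assignments assignment table from [assign_reads()]
#' @param collapsed collapsed reads (for per-position qualities)
#' @param sites validated site table
#' @param min_base_q quality mask for G-supporting bases (default 30)
#' @return data.frame `site_id`, `coverage`, `edited_count`
#' @export
pileup_sites <- function(assignments, collapsed, sites, min_base_q = 30) {
  qual_of <- stats::setNames(collapsed$qual, collapsed$seq)
  out <- data.frame(site_id = sites$site_id, coverage = 0, edited_count = 0,
                    stringsAsFactors = FALSE)
  asn <- assignments[assignments$status != "unassigned", , drop = FALSE]
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    over <- asn$ref_id == s$pre_id & asn$start <= s$pre_pos & asn$end >= s$pre_pos
    rows <- asn[over, , drop = FALSE]
    if (nrow(rows) == 0L) next
    is_site_edit <- !is.na(rows$site_id) & rows$site_id == s$site_id
    cov <- sum(rows$count[!is_site_edit] * rows$weight[!is_site_edit])
    edited <- 0
    er <- rows[is_site_edit, , drop = FALSE]
    if (nrow(er)) {
      pos_in_read <- s$pre_pos - er$start + 1L
      q <- vapply(seq_len(nrow(er)),
                  function(j) qual_of[[er$seq[j]]][pos_in_read[j]], numeric(1))
      ok <- q >= min_base_q
      edited <- sum(er$count[ok] * er$weight[ok])
      cov <- cov + edited          # masked edited reads leave both counts
    }
    out$coverage[i] <- cov
    out$edited_count[i] <- edited
  }
  out
}

#' Editing level of a pileup
#'
#' Exact ratio of the edited count to the coverage depth. Undefined (NA)
#' at zero coverage; no call is emitted for such sites.
#'
#' @param edited_count,coverage weighted counts
#' @return fraction in [0, 1]
#' @export
editing_level <- function(edited_count, coverage) {
  ifelse(coverage > 0, edited_count / coverage, NA_real_)
}

#' One-sided binomial test against the sequencing-error null
#'
#' P(X >= edited | X ~ Binomial(coverage, epsilon_ag)). Fractional weighted
#' counts are rounded half-up to integers for the test only; reported
#' levels keep exact fractions.
#'
#' @param edited_count,coverage weighted counts (coverage >= 1)
#' @param e an `error_model`
#' @return p-value(s)
#' @export
site_test <- function(edited_count, coverage, e) {
  if (!inherits(e, "error_model")) stop("e must be an error_model")
  k <- floor(edited_count + 0.5)
  n <- floor(coverage + 0.5)
  stats::pbinom(k - 1, n, e$epsilon_ag, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own step-up implementation (q_(i) = min_{j >= i} p_(j) * m / j, capped
#' at 1), kept separate from stats::p.adjust so the two can be compared as
#' independent routes.
#'
#' @param p p-values in [0, 1]
#' @return q-values, in input order
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Call editing at all candidate sites of one sample
#'
#' Emits one call per site with coverage >= 1 (levels are reported even for
#' failing sites so they can enter the cohort editing matrix). A call
#' passes when it has at least `min_edited` edited reads, a level of at
#' least `min_level`, and BH q below `max_q`. The BH universe is all
#' candidate sites with coverage >= 1 within the sample.
#'
#' @param pileups data.frame from [pileup_sites()]
#' @param e an `error_model`
#' @param sample_id identifier recorded on each call
#' @param min_edited minimum edited reads (default 2)
#' @param min_level minimum editing level (default 0.05)
#' @param max_q BH significance threshold (default 0.05)
#' @return data.frame `sample_id`, `site_id`, `coverage`, `edited_count`,
#'   `level`, `p_value`, `q_value`, `passes`
#' @export
call_sites <- function(pileups, e, sample_id = "sample",
                       min_edited = 2, min_level = 0.05, max_q = 0.05) {
  keep <- pileups$coverage >= 1
  p <- pileups[keep, , drop = FALSE]
  if (nrow(p) == 0L)
    return(data.frame(sample_id = character(0), site_id = character(0),
                      coverage = numeric(0), edited_count = numeric(0),
                      level = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), passes = logical(0),
                      stringsAsFactors = FALSE))
  lev <- editing_level(p$edited_count, p$coverage)
  pv <- site_test(p$edited_count, p$coverage, e)
  qv <- bh_adjust(pv)
  data.frame(sample_id = sample_id, site_id = p$site_id,
             coverage = p$coverage, edited_count = p$edited_count,
             level = lev, p_value = pv, q_value = qv,
             passes = p$edited_count >= min_edited & lev >= min_level &
               qv < max_q,
             stringsAsFactors = FALSE)
}

#' High-confidence sites across samples
#'
#' A site is high-confidence when it passes the per-sample filters with at
#' least `min_edited` edited reads in at least `min_samples` samples.
#'
#' @param calls row-bound per-sample call tables
#' @param min_samples default 10
#' @param min_edited default 2
#' @return data.frame `site_id`, `n_samples_detected`, `mean_level`
#' @export
aggregate_high_confidence <- function(calls, min_samples = 10, min_edited = 2) {
  if (nrow(calls) == 0L)
    return(data.frame(site_id = character(0), n_samples_detected = integer(0),
                      mean_level = numeric(0), stringsAsFactors = FALSE))
  ok <- calls[calls$passes & calls$edited_count >= min_edited, , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(site_id = character(0), n_samples_detected = integer(0),
                      mean_level = numeric(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(level ~ site_id, data = ok,
                          FUN = function(x) c(n = length(x), mean = mean(x)))
  res <- data.frame(site_id = agg$site_id,
                    n_samples_detected = as.integer(agg$level[, "n"]),
                    mean_level = agg$level[, "mean"],
                    stringsAsFactors = FALSE)
  res <- res[res$n_samples_detected >= min_samples, , drop = FALSE]
  res[order(res$site_id), , drop = FALSE]
}
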