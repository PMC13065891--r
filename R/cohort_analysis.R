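# Cohort-level analysis of editing profiles: the sites x samples editing
# matrix, per-condition decision-tree imputation, discriminative-site
# selection, PCA, and between-condition comparisons.

#' Build the sites x samples editing-level matrix
#'
#' One row per site and one column per sample; cells hold the editing level
#' of every emitted call (passing or not) and NA where a site had no
#' coverage in a sample.
#'
#' @param calls row-bound per-sample call tables from [call_sites()]
#' @return numeric matrix with site rownames and sample colnames
#' @export
build_editing_matrix <- function(calls) {
  sites <- sort(unique(calls$site_id))
  samples <- unique(calls$sample_id)
  m <- matrix(NA_real_, length(sites), length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(calls$site_id, sites), match(calls$sample_id, samples))] <-
    calls$level
  m
}

#' Impute missing editing levels per condition
#'
#' Within each condition, every site with missing values is predicted from
#' the other sites with a regression tree: training samples are the
#' condition's samples where the target site is observed, predictor sites
#' are mean-filled within the condition (global site mean when a predictor
#' is entirely missing there). Imputed values are clipped to [0, 1] and
#' observed cells are never altered. A site missing in all samples of a
#' condition receives the global site mean, with a warning. The procedure
#' is deterministic; `seed` is accepted for interface stability.
#'
#' @param m editing matrix (sites x samples), NAs allowed
#' @param conditions condition label per sample (length ncol(m))
#' @param seed unused by the deterministic tree; kept for API stability
#' @return imputed matrix, same dimensions
#' @export
impute_missing <- function(m, conditions, seed = 1L) {
  stopifnot(ncol(m) == length(conditions))
  if (!anyNA(m)) return(m)
  global_mean <- rowMeans(m, na.rm = TRUE)
  out <- m
  for (cond in unique(conditions)) {
    cols <- which(conditions == cond)
    if (length(cols) < 2L)
      stop("condition '", cond, "' has fewer than 2 samples", call. = FALSE)
    sub <- m[, cols, drop = FALSE]
    # mean-fill a predictor copy of the condition block
    filled <- sub
    for (i in seq_len(nrow(filled))) {
      na <- is.na(filled[i, ])
      if (any(na)) {
        fill <- mean(filled[i, !na])
        if (!any(!na)) fill <- global_mean[i]
        filled[i, na] <- fill
      }
    }
    for (i in seq_len(nrow(sub))) {
      na <- is.na(sub[i, ])
      if (!any(na)) next
      if (all(na)) {
        gm <- global_mean[i]
        if (is.nan(gm)) stop("site ", rownames(m)[i],
                             " observed nowhere; cannot impute", call. = FALSE)
        warning("site ", rownames(m)[i], " missing in all samples of '",
                cond, "'; using its global mean")
        out[i, cols[na]] <- min(max(gm, 0), 1)
        next
      }
      x <- t(filled[-i, , drop = FALSE])       # samples x predictor sites
      fit <- rtree_fit(x[!na, , drop = FALSE], sub[i, !na])
      pred <- predict(fit, x[na, , drop = FALSE])
      out[i, cols[na]] <- pmin(pmax(pred, 0), 1)
    }
  }
  out
}

#' Two-sided rank-sum test (Wilcoxon-Mann-Whitney) with midranks
#'
#' Exact enumeration of the permutation null over all group assignments
#' when feasible (default up to 200000 combinations), handling ties by
#' midranks; normal approximation with tie correction and continuity
#' correction otherwise. stats::wilcox.test abandons the exact null under
#' ties, which these bounded editing fractions produce routinely -- hence
#' an own implementation.
#'
#' @param x,y numeric samples for the two groups
#' @param max_enum largest number of combinations enumerated exactly
#' @return list with `p_value`, `statistic` (rank sum of x) and `exact`
#' @export
ranksum_test <- function(x, y, max_enum = 2e5) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) stop("need at least 2 values per group", call. = FALSE)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  mu <- m * (m + n + 1) / 2
  if (choose(m + n, m) <= max_enum) {
    combs <- utils::combn(m + n, m)
    ws <- colSums(matrix(r[combs], nrow = m))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(list(p_value = p, statistic = w, exact = TRUE))
  }
  ties <- table(r)
  sigma2 <- m * n / 12 * ((m + n + 1) -
    sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  list(p_value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       statistic = w, exact = FALSE)
}

#' Select discriminative sites against a reference condition
#'
#' For every site, the reference (healthy) group is compared with each
#' other condition by the two-sided rank-sum test on raw, non-imputed
#' levels; a site is selected when any comparison yields p below `alpha`
#' (unadjusted). No missingness-based exclusion is applied. Conditions
#' with fewer than 2 non-missing values at a site are skipped with a
#' warning recorded once.
#'
#' @param m editing matrix (sites x samples), raw levels
#' @param conditions condition label per sample
#' @param healthy_label label of the reference condition
#' @param alpha selection threshold on the minimum p (default 0.1)
#' @return data.frame `site_id`, `min_p`, `selected`
#' @export
select_sites <- function(m, conditions, healthy_label, alpha = 0.1) {
  stopifnot(ncol(m) == length(conditions))
  if (!healthy_label %in% conditions)
    stop("reference condition '", healthy_label, "' not present", call. = FALSE)
  others <- setdiff(unique(conditions), healthy_label)
  hc <- conditions == healthy_label
  min_p <- rep(NA_real_, nrow(m))
  skipped <- FALSE
  for (i in seq_len(nrow(m))) {
    hx <- m[i, hc]; hx <- hx[!is.na(hx)]
    ps <- c()
    for (g in others) {
      gx <- m[i, conditions == g]; gx <- gx[!is.na(gx)]
      if (length(hx) < 2L || length(gx) < 2L) { skipped <- TRUE; next }
      ps <- c(ps, ranksum_test(hx, gx)$p_value)
    }
    if (length(ps)) min_p[i] <- min(ps)
  }
  if (skipped) warning("some comparisons skipped: fewer than 2 values per group")
  data.frame(site_id = rownames(m), min_p = min_p,
             selected = !is.na(min_p) & min_p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA of editing profiles
#'
#' Samples are observations, selected sites are variables. Columns are
#' centered (scaling optional: levels already share units). The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#'
#' @param m imputed editing matrix (sites x samples), no NAs among
#'   `sites` rows
#' @param sites site ids (rows of `m`) to use; default all
#' @param scale. scale variables to unit variance (default FALSE)
#' @return list with `scores` (samples x PCs), `loadings` (sites x PCs),
#'   `var_explained` (fractions)
#' @export
run_pca <- function(m, sites = rownames(m), scale. = FALSE) {
  x <- t(m[sites, , drop = FALSE])
  if (anyNA(x)) stop("matrix must be imputed before PCA", call. = FALSE)
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("need at least 2 sites and 3 samples", call. = FALSE)
  if (all(apply(x, 2L, stats::var) == 0))
    stop("constant matrix: zero variance", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Compare editing levels of one site between two conditions
#'
#' Two-sided rank-sum test on raw (non-imputed) levels. Direction is the
#' sign of the median difference (mean difference as tie fallback);
#' significance tiers follow the usual asterisk convention
#' (* p < 0.05, ** p < 0.01).
#'
#' @param m raw editing matrix (sites x samples)
#' @param site site id (row of `m`)
#' @param conditions condition label per sample
#' @param cond_a,cond_b the two conditions, compared as b relative to a
#' @return data.frame `site_id`, `condition_a`, `condition_b`, `p_value`,
#'   `direction`, `significance_tier`
#' @export
compare_groups <- function(m, site, conditions, cond_a, cond_b) {
  a <- m[site, conditions == cond_a]; a <- a[!is.na(a)]
  b <- m[site, conditions == cond_b]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("a group has no observed values at site ", site, call. = FALSE)
  rs <- ranksum_test(a, b)
  d <- stats::median(b) - stats::median(a)
  if (d == 0) d <- mean(b) - mean(a)
  tier <- if (rs$p_value < 0.01) "**" else if (rs$p_value < 0.05) "*" else "none"
  data.frame(site_id = site, condition_a = cond_a, condition_b = cond_b,
             p_value = rs$p_value,
             direction = if (d >= 0) "up" else "down",
             significance_tier = tier, stringsAsFactors = FALSE)
}
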