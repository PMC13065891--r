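# Mature-miRNA expression in reads per million (RPM) and the
# batch-correction hook.

#' Reads-per-million expression for one sample
#'
#' RPM = (miRNA mapped reads / total mapped reads) x 1e6, where "total
#' mapped reads" is the multiplicity-expanded, fractionally weighted sum of
#' all reads attributed to any mature arm. Before the retention filter the
#' RPM values of a sample sum to exactly 1e6. A miRNA is retained when its
#' RPM is at least `min_rpm`.
#'
#' @param attributions mature attributions from [attribute_mature()]
#' @param sample_id identifier recorded on each record
#' @param min_rpm retention threshold (default 10)
#' @return data.frame `sample_id`, `mature_id`, `mapped_reads`, `rpm`,
#'   `retained`
#' @export
compute_rpm <- function(attributions, sample_id = "sample", min_rpm = 10) {
  w <- attributions$count * attributions$weight
  total <- sum(w)
  if (!nrow(attributions) || total <= 0)
    stop("no reads attributed to mature arms in sample ", sample_id,
         call. = FALSE)
  per <- tapply(w, attributions$mature_id, sum)
  rpm <- as.numeric(per) / total * 1e6
  data.frame(sample_id = sample_id, mature_id = names(per),
             mapped_reads = as.numeric(per), rpm = rpm,
             retained = rpm >= min_rpm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Batch-correction hook for an expression matrix
#'
#' Delegates to a ComBat-compatible batch-effect remover
#' (default: [limma::removeBatchEffect()]); the method itself is out of
#' scope here, only the hook is provided. Both the raw and the corrected
#' matrix are returned. A single batch is an identity pass-through with a
#' warning.
#'
#' @param mat numeric matrix, samples x miRNAs
#' @param batches batch label per sample (no missing values)
#' @param method function(matrix genes x samples, batch) -> corrected
#'   matrix; defaults to limma::removeBatchEffect
#' @return list with `raw` and `corrected` matrices (samples x miRNAs)
#' @export
batch_correct_hook <- function(mat, batches, method = NULL) {
  mat <- as.matrix(mat)
  if (length(batches) != nrow(mat))
    stop("need one batch label per sample", call. = FALSE)
  if (anyNA(batches)) stop("missing batch label", call. = FALSE)
  batches <- as.character(batches)
  if (length(unique(batches)) < 2L) {
    warning("single batch: returning the matrix uncorrected")
    return(list(raw = mat, corrected = mat))
  }
  if (any(table(batches) < 2L))
    stop("every batch needs at least 2 samples", call. = FALSE)
  if (is.null(method))
    method <- function(m, batch) limma::removeBatchEffect(m, batch = batch)
  corrected <- t(method(t(mat), batches))
  dimnames(corrected) <- dimnames(mat)
  list(raw = mat, corrected = corrected)
}
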