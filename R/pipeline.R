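# Pipeline orchestration: references -> preprocess -> align -> call ->
# express -> rewire -> cohort, with every threshold carried in one config
# object, plain-text intermediate artifacts, and deterministic outputs.

#' Pipeline configuration
#'
#' Collects every input path and every threshold of the method as a named
#' parameter with its published default. Overriding any threshold is
#' recorded in the run log.
#'
#' @param premirna_fasta,mature_tsv,sites_tsv reference inputs
#' @param fastq named character vector: sample id -> FASTQ path
#' @param out_dir run directory (created)
#' @param genome_fasta optional genome FASTA for perfect-match exclusion
#' @param utr_fasta optional 3'UTR FASTA for target rewiring
#' @param metadata_tsv optional sample metadata TSV
#'   (sample_id, condition, batch, ...)
#' @param healthy_label reference condition for cohort analysis (optional)
#' @param max_n,qc_min_len,qc_max_len,min_mean_q per-read QC gates
#'   (N > 5 drop; length outside 15-25 drop; mean Phred <= 20 drop)
#' @param final_min,final_max final retention window (16-25)
#' @param min_base_q quality mask for G bases (30)
#' @param epsilon_ag fixed A-to-G miscall rate; NULL = estimate per sample
#' @param error_default fallback epsilon_ag when estimation lacks data
#' @param min_edited,min_level,max_q call filters (2 reads, 5%, q < 0.05)
#' @param min_rpm expression retention (10 RPM)
#' @param hc_min_samples,hc_min_edited high-confidence aggregation
#'   (10 samples, 2 reads)
#' @param min_clean_reads,min_frac_bases,min_mapped_reads dataset QC gates
#'   (1e6 clean reads, 60% bases, 1e5 mapped 16-25 nt reads)
#' @param select_alpha cohort site-selection threshold (p < 0.1)
#' @param seed RNG seed for the imputation stage
#' @return a `run_config` list
#' @export
pipeline_config <- function(premirna_fasta, mature_tsv, sites_tsv, fastq,
                            out_dir, genome_fasta = NULL, utr_fasta = NULL,
                            metadata_tsv = NULL, healthy_label = NULL,
                            max_n = 5L, qc_min_len = 15L, qc_max_len = 25L,
                            min_mean_q = 20, final_min = 16L, final_max = 25L,
                            min_base_q = 30, epsilon_ag = NULL,
                            error_default = 0.001,
                            min_edited = 2, min_level = 0.05, max_q = 0.05,
                            min_rpm = 10, hc_min_samples = 10,
                            hc_min_edited = 2,
                            min_clean_reads = 1e6, min_frac_bases = 0.60,
                            min_mapped_reads = 1e5, select_alpha = 0.1,
                            seed = 1L) {
  cfg <- as.list(environment())
  defaults <- formals(pipeline_config)
  overridden <- character(0)
  threshold_args <- c("max_n", "qc_min_len", "qc_max_len", "min_mean_q",
                      "final_min", "final_max", "min_base_q", "error_default",
                      "min_edited", "min_level", "max_q", "min_rpm",
                      "hc_min_samples", "hc_min_edited", "min_clean_reads",
                      "min_frac_bases", "min_mapped_reads", "select_alpha")
  for (nm in threshold_args) {
    if (!isTRUE(all.equal(as.numeric(cfg[[nm]]),
                          as.numeric(eval(defaults[[nm]])))))
      overridden <- c(overridden, nm)
  }
  if (!is.null(cfg$epsilon_ag)) overridden <- c(overridden, "epsilon_ag")
  cfg$overridden <- overridden
  structure(cfg, class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes all stages in order, writing each stage's TSV outputs into the
#' run directory before the next stage starts. Re-running with identical
#' config and inputs reproduces byte-identical outputs. A sample failing a
#' dataset QC gate is marked `excluded` and takes no further part;
#' downstream cohort stages run on the surviving samples.
#'
#' @param cfg a `run_config` from [pipeline_config()]
#' @return (invisibly) a list with all in-memory results and an
#'   `exit_status`: 0 ok, 2 all samples excluded by QC
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("miredit pipeline run",
                 paste0("samples: ", paste(names(cfg$fastq), collapse = ", ")),
                 if (length(cfg$overridden))
                   paste0("overridden thresholds: ",
                          paste(cfg$overridden, collapse = ", "))
                 else "all thresholds at published defaults")
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  refs <- load_references(cfg$premirna_fasta, cfg$mature_tsv)
  sites <- load_edit_sites(refs, cfg$sites_tsv)
  edited <- build_edited_references(refs, sites)
  write_tsv(edited[, c("site_id", "pre_id", "pre_pos")],
            file.path(cfg$out_dir, "edited_references.tsv"))
  say("references: ", length(refs$seq), " hairpins, ", nrow(sites), " sites")

  genome <- NULL
  if (!is.null(cfg$genome_fasta)) {
    g <- Biostrings::readBStringSet(cfg$genome_fasta)
    genome <- stats::setNames(toupper(as.character(g)),
                              sub("\\s.*$", "", names(g)))
  }

  metadata <- NULL
  if (!is.null(cfg$metadata_tsv))
    metadata <- utils::read.delim(cfg$metadata_tsv, stringsAsFactors = FALSE)

  qc_rows <- list(); calls <- list(); rpm <- list(); status <- character(0)
  for (sid in names(cfg$fastq)) {
    reads <- read_fastq(cfg$fastq[[sid]])
    pre <- preprocess_reads(reads, max_n = cfg$max_n,
                            min_len = cfg$qc_min_len, max_len = cfg$qc_max_len,
                            min_mean_q = cfg$min_mean_q,
                            final_min = cfg$final_min,
                            final_max = cfg$final_max)
    asn <- assign_reads(pre$collapsed, refs, edited)
    if (is.null(genome)) {
      asn <- withCallingHandlers(
        exclude_genome_matchers(asn, NULL),
        warning = function(w) {
          say(sid, ": ", conditionMessage(w)); invokeRestart("muffleWarning")
        })
    } else asn <- exclude_genome_matchers(asn, genome)
    mapped <- count_mapped_reads(asn)
    qc <- dataset_qc(pre$qc, mapped,
                     min_clean_reads = cfg$min_clean_reads,
                     min_frac_bases = cfg$min_frac_bases,
                     min_mapped_reads = cfg$min_mapped_reads)
    qc_rows[[sid]] <- data.frame(
      sample_id = sid, total_raw_reads = qc$total_raw_reads,
      clean_reads = qc$clean_reads,
      fraction_bases_retained = round(qc$fraction_bases_retained, 6),
      mapped_16_25_reads = qc$mapped_16_25_reads,
      pass = qc$pass, stringsAsFactors = FALSE)
    if (!qc$pass) {
      status[sid] <- "excluded"
      say(sid, ": excluded by dataset QC (",
          paste(names(qc$gates)[!qc$gates], collapse = ", "), ")")
      next
    }
    status[sid] <- "ok"
    e <- if (is.null(cfg$epsilon_ag))
      estimate_error_rate(pre$collapsed, asn, default = cfg$error_default)
    else error_model(cfg$epsilon_ag)
    pil <- pileup_sites(asn, pre$collapsed, sites,
                        min_base_q = cfg$min_base_q)
    calls[[sid]] <- call_sites(pil, e, sample_id = sid,
                               min_edited = cfg$min_edited,
                               min_level = cfg$min_level, max_q = cfg$max_q)
    att <- attribute_mature(asn, refs)
    rpm[[sid]] <- compute_rpm(att, sample_id = sid, min_rpm = cfg$min_rpm)
    say(sid, ": ", qc$clean_reads, " clean reads, ", mapped, " mapped, ",
        sum(calls[[sid]]$passes), " passing sites, epsilon_ag = ",
        signif(e$epsilon_ag, 4))
  }
  write_tsv(do.call(rbind, qc_rows), file.path(cfg$out_dir, "qc_report.tsv"))
  jsonlite::write_json(
    list(samples = do.call(rbind, qc_rows), status = as.list(status)),
    file.path(cfg$out_dir, "qc_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)

  out <- list(status = status, qc = do.call(rbind, qc_rows), sites = sites)
  if (!any(status == "ok")) {
    say("all samples excluded; stopping after preprocess/QC")
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
    out$exit_status <- 2L
    return(invisible(out))
  }

  all_calls <- do.call(rbind, calls); rownames(all_calls) <- NULL
  num <- c("coverage", "edited_count", "level", "p_value", "q_value")
  all_calls_io <- all_calls
  all_calls_io[num] <- lapply(all_calls_io[num], signif, 10)
  write_tsv(all_calls_io, file.path(cfg$out_dir, "editing_calls.tsv"))
  hc <- aggregate_high_confidence(all_calls,
                                  min_samples = cfg$hc_min_samples,
                                  min_edited = cfg$hc_min_edited)
  write_tsv(hc, file.path(cfg$out_dir, "high_confidence_sites.tsv"))
  say("high-confidence sites: ", nrow(hc))

  all_rpm <- do.call(rbind, rpm); rownames(all_rpm) <- NULL
  all_rpm$rpm <- signif(all_rpm$rpm, 10)
  write_tsv(all_rpm, file.path(cfg$out_dir, "expression_rpm.tsv"))
  out$calls <- all_calls; out$high_confidence <- hc; out$expression <- all_rpm

  if (!is.null(metadata) && "batch" %in% names(metadata)) {
    em <- stats::xtabs(rpm ~ sample_id + mature_id, data = all_rpm)
    em <- matrix(as.numeric(em), nrow(em), dimnames = dimnames(em))
    b <- metadata$batch[match(rownames(em), metadata$sample_id)]
    if (length(unique(b)) >= 2L && all(table(b) >= 2L)) {
      bc <- batch_correct_hook(em, b)
      write_tsv(data.frame(sample_id = rownames(bc$corrected),
                           signif(bc$corrected, 10),
                           check.names = FALSE),
                file.path(cfg$out_dir, "expression_rpm_corrected.tsv"))
      out$expression_corrected <- bc$corrected
      say("batch correction applied over ", length(unique(b)), " batches")
    } else say("batch correction skipped (fewer than 2 usable batches)")
  }

  if (!is.null(cfg$utr_fasta)) {
    u <- Biostrings::readBStringSet(cfg$utr_fasta)
    utrs <- stats::setNames(as.character(u), sub("\\s.*$", "", names(u)))
    rw <- list()
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      arm <- refs$arms[refs$arms$mature_id == s$mature_id, ]
      r <- rewire_targets(arm$mature_seq, s$mature_pos, utrs)
      rw[[i]] <- data.frame(site_id = s$site_id, mature_id = s$mature_id,
                            mature_pos = s$mature_pos, domain = r$domain,
                            n_targets_unedited = length(r$targets_unedited),
                            n_targets_edited = length(r$targets_edited),
                            overlap = round(r$overlap, 6),
                            stringsAsFactors = FALSE)
    }
    out$rewiring <- do.call(rbind, rw)
    write_tsv(out$rewiring, file.path(cfg$out_dir, "target_rewiring.tsv"))
    say("target rewiring computed for ", nrow(sites), " sites")
  }

  if (!is.null(metadata) && "condition" %in% names(metadata) &&
      !is.null(cfg$healthy_label)) {
    m <- build_editing_matrix(all_calls)
    cond <- metadata$condition[match(colnames(m), metadata$sample_id)]
    write_tsv(data.frame(site_id = rownames(m), signif(m, 10),
                         check.names = FALSE),
              file.path(cfg$out_dir, "editing_matrix.tsv"))
    sel <- select_sites(m, cond, cfg$healthy_label, alpha = cfg$select_alpha)
    write_tsv(sel, file.path(cfg$out_dir, "selected_sites.tsv"))
    out$selection <- sel
    picked <- sel$site_id[sel$selected]
    if (length(picked) >= 2L && ncol(m) >= 3L) {
      mi <- impute_missing(m, cond, seed = cfg$seed)
      pca <- run_pca(mi, picked)
      write_tsv(data.frame(sample_id = rownames(pca$scores),
                           condition = cond, signif(pca$scores, 10),
                           check.names = FALSE),
                file.path(cfg$out_dir, "pca_scores.tsv"))
      write_tsv(data.frame(component = seq_along(pca$var_explained),
                           var_explained = signif(pca$var_explained, 10)),
                file.path(cfg$out_dir, "pca_variance.tsv"))
      out$pca <- pca; out$imputed <- mi
      cmp <- list()
      for (s in picked) for (g in setdiff(unique(cond), cfg$healthy_label))
        cmp[[paste(s, g)]] <- compare_groups(m, s, cond, cfg$healthy_label, g)
      out$comparisons <- do.call(rbind, cmp); rownames(out$comparisons) <- NULL
      write_tsv(out$comparisons,
                file.path(cfg$out_dir, "group_comparisons.tsv"))
      say("cohort analysis: ", length(picked), " sites selected")
    } else say("cohort analysis skipped: fewer than 2 selected sites")
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  out$exit_status <- 0L
  invisible(out)
}
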