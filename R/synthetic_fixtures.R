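# Seeded synthetic-data generator: hairpin references with embedded mature
# arms, editing-site tables, decoy genomes, 3'UTR collections, and FASTQ
# read sets with planted editing under a Phred-calibrated miscall model,
# plus truth tables for validation.
#
# The generator emulates the statistical structure the caller assumes:
# edited-read counts are Bernoulli draws per read at the true editing
# level, and every base is miscalled independently according to its
# quality. It does not attempt RNA-ligase bias, isomiR diversity or
# vesicle-isolation batch artifacts.

BASES_RNA <- c("A", "C", "G", "U")

#' Simulation configuration
#'
#' @param n_hairpins number of hairpins (default 10)
#' @param n_sites number of editing sites, at most one per mature arm
#'   (default 5)
#' @param coverage reads simulated per mature arm per sample (default 1000)
#' @param epsilon fixed per-base miscall probability; when NULL (default
#'   NULL is not used here -- the packaged default is 0.001) miscalls
#'   instead follow each base's drawn Phred score as 10^(-Q/10)
#' @param phred_mean,phred_sd clipped-normal parameters for drawn Phred
#'   scores (defaults 35, 3)
#' @param n_samples number of samples (default 1)
#' @param editing_levels true editing level(s): scalar, per-site vector, or
#'   sites x samples matrix (default 0.3)
#' @param tail_fraction fraction of reads receiving a non-templated 3' A/U
#'   tail of 1-2 nt (default 0.2)
#' @param n_utrs,utr_len_range synthetic 3'UTR collection size and length
#'   range
#' @param plant_genome_decoy plant one edited-read sequence verbatim in the
#'   genome to exercise perfect-match exclusion (default FALSE)
#' @param seed mandatory RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_hairpins = 10L, n_sites = 5L, coverage = 1000L,
                       epsilon = 0.001, phred_mean = 35, phred_sd = 3,
                       n_samples = 1L, editing_levels = 0.3,
                       tail_fraction = 0.2, n_utrs = 50L,
                       utr_len_range = c(100L, 300L),
                       plant_genome_decoy = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(editing_levels >= 0 & editing_levels <= 1),
            is.null(epsilon) || (epsilon > 0 && epsilon < 1),
            tail_fraction >= 0 && tail_fraction <= 1)
  structure(list(n_hairpins = n_hairpins, n_sites = n_sites,
                 coverage = coverage, epsilon = epsilon,
                 phred_mean = phred_mean, phred_sd = phred_sd,
                 n_samples = n_samples, editing_levels = editing_levels,
                 tail_fraction = tail_fraction, n_utrs = n_utrs,
                 utr_len_range = utr_len_range,
                 plant_genome_decoy = plant_genome_decoy,
                 seed = as.integer(seed)), class = "sim_config")
}

rand_seq <- function(n, alphabet = BASES_RNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

draw_phred <- function(n, mean, sd) {
  as.integer(round(pmin(pmax(stats::rnorm(n, mean, sd), 2), 41)))
}

#' Simulate the reference world
#'
#' Hairpins of 60-90 nt with a 20-23 nt mature arm on each strand of the
#' duplex; editing sites on distinct arms at mature positions biased
#' towards 2 and 5 (the seed positions most often edited in vivo), with
#' the reference base forced to A during construction; a decoy genome
#' containing the hairpin loci plus unrelated sequence; and a random 3'UTR
#' collection.
#'
#' @param cfg a `sim_config`
#' @return list with `refs` (premirna_set), `sites` (validated table),
#'   `edited` (edited references), `genome` (named DNA vector), `utrs`
#'   (named RNA vector) and `cfg`
#' @export
simulate_references <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sprintf("hp%02d", seq_len(cfg$n_hairpins))
  seqs <- character(cfg$n_hairpins)
  arms <- list()
  for (i in seq_len(cfg$n_hairpins)) {
    l5 <- sample(20:23, 1); loop <- sample(8:15, 1); l3 <- sample(20:23, 1)
    seqs[i] <- rand_seq(l5 + loop + l3)
    arms[[i]] <- data.frame(
      pre_id = ids[i],
      mature_id = paste0(ids[i], c("-5p", "-3p")),
      start = c(1L, l5 + loop + 1L),
      end = c(l5, l5 + loop + l3),
      arm = c("5p", "3p"), stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  arms <- do.call(rbind, arms)
  if (cfg$n_sites > nrow(arms))
    stop("n_sites exceeds the number of mature arms", call. = FALSE)
  # one site per arm, 5p-weighted arm choice, position biased to 2 and 5
  w_arm <- ifelse(arms$arm == "5p", 8, 1)
  site_arms <- sample(nrow(arms), cfg$n_sites, prob = w_arm)
  site_rows <- list()
  for (k in seq_along(site_arms)) {
    a <- arms[site_arms[k], ]
    arm_len <- a$end - a$start + 1L
    pos_cand <- 2:min(15L, arm_len)
    w_pos <- ifelse(pos_cand %in% c(2L, 5L), 6, 1)
    mp <- sample(pos_cand, 1, prob = w_pos)
    pp <- a$start + mp - 1L
    substr(seqs[a$pre_id], pp, pp) <- "A"
    site_rows[[k]] <- data.frame(site_id = sprintf("site%02d", k),
                                 pre_id = a$pre_id, mature_id = a$mature_id,
                                 mature_pos = mp, stringsAsFactors = FALSE)
  }
  refs <- premirna_set(seqs, arms)
  sites <- load_edit_sites(refs, do.call(rbind, site_rows))
  edited <- build_edited_references(refs, sites)
  genome <- character(0)
  for (i in seq_len(cfg$n_hairpins)) {
    locus <- paste0(rand_seq(50), seqs[i], rand_seq(50))
    genome <- c(genome, stats::setNames(rna_to_dna(locus),
                                        paste0("chr_", ids[i])))
  }
  genome <- c(genome, decoy1 = rand_seq(200, c("A", "C", "G", "T")),
              decoy2 = rand_seq(200, c("A", "C", "G", "T")))
  if (cfg$plant_genome_decoy) {
    s <- sites[1, ]
    arm <- refs$arms[refs$arms$mature_id == s$mature_id, ]
    ed_arm <- substr(edited$sequence[1], arm$start, arm$end)
    genome <- c(genome, planted_decoy = rna_to_dna(
      paste0(rand_seq(30), ed_arm, rand_seq(30))))
  }
  utr_len <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], cfg$n_utrs,
                    replace = TRUE)
  utrs <- stats::setNames(vapply(utr_len, rand_seq, character(1)),
                          sprintf("utr%03d", seq_len(cfg$n_utrs)))
  list(refs = refs, sites = sites, edited = edited, genome = genome,
       utrs = utrs, cfg = cfg)
}

site_level_matrix <- function(cfg, sites) {
  lv <- cfg$editing_levels
  if (is.matrix(lv)) {
    stopifnot(nrow(lv) == nrow(sites), ncol(lv) == cfg$n_samples)
    return(lv)
  }
  if (length(lv) == 1L) lv <- rep(lv, nrow(sites))
  stopifnot(length(lv) == nrow(sites))
  matrix(lv, nrow(sites), cfg$n_samples)
}

#' Simulate one sample's FASTQ-equivalent read set
#'
#' For every mature arm, `coverage` full-length arm reads are drawn. Reads
#' over an editing site carry G there with probability equal to the
#' sample's true level. Each base is then miscalled independently: at the
#' fixed rate `cfg$epsilon` when set (written Phred strings are still
#' drawn around `phred_mean`, see the methods vignette for why the two are
#' decoupled in this mode), otherwise at 10^(-Q/10) from its own drawn
#' score. A fraction of reads gains a 1-2 nt non-templated 3' A/U tail.
#'
#' @param sim world from [simulate_references()]
#' @param sample_index which sample's level column to use (default 1)
#' @param sample_id identifier used in read names (default "s1")
#' @param seed RNG seed for this sample (default cfg seed + sample_index)
#' @return list with `reads` (data.frame read_id/seq/qual), `truth_sites`
#'   (site_id, true_level, true_edited, true_coverage), `truth_reads`
#'   (read_id, origin)
#' @export
simulate_reads <- function(sim, sample_index = 1L,
                           sample_id = paste0("s", sample_index),
                           seed = sim$cfg$seed + sample_index) {
  cfg <- sim$cfg
  set.seed(seed)
  levels <- site_level_matrix(cfg, sim$sites)[, sample_index]
  arms <- sim$refs$arms
  all_reads <- list(); truth_sites <- list(); origins <- list()
  for (ai in seq_len(nrow(arms))) {
    a <- arms[ai, ]
    n <- cfg$coverage
    L <- nchar(a$mature_seq)
    seqs <- rep(a$mature_seq, n)
    si <- which(sim$sites$mature_id == a$mature_id)
    origin <- rep("unedited", n)
    if (length(si) == 1L) {
      ed <- stats::runif(n) < levels[si]
      mp <- sim$sites$mature_pos[si]
      substr(seqs[ed], mp, mp) <- "G"
      origin[ed] <- paste0("edited:", sim$sites$site_id[si])
      truth_sites[[length(truth_sites) + 1L]] <-
        data.frame(site_id = sim$sites$site_id[si],
                   true_level = levels[si], true_edited = sum(ed),
                   true_coverage = n, stringsAsFactors = FALSE)
    }
    # qualities: one big draw, then split into per-read Phred+33 strings
    q <- draw_phred(n * L, cfg$phred_mean, cfg$phred_sd)
    bigq <- intToUtf8(q + 33L)
    quals <- substring(bigq, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
    # miscalls touch ~ n*L*epsilon reads; handle only those individually
    p_mis <- if (is.null(cfg$epsilon)) 10^(-q / 10) else cfg$epsilon
    mis <- which(stats::runif(n * L) < p_mis)
    while (length(mis)) {
      # vectorized substitution; reads with several miscalls are handled
      # over successive rounds so no substitution is lost
      first <- !duplicated((mis - 1L) %/% L)
      cell <- mis[first]
      row <- (cell - 1L) %/% L + 1L
      col <- (cell - 1L) %% L + 1L
      old <- match(substr(seqs[row], col, col), BASES_RNA)
      new <- BASES_RNA[(old - 1L + sample(3L, length(cell),
                                          replace = TRUE)) %% 4L + 1L]
      substr(seqs[row], col, col) <- new
      mis <- mis[!first]
    }
    tail_n <- ifelse(stats::runif(n) < cfg$tail_fraction,
                     sample(1:2, n, replace = TRUE), 0L)
    for (k in 1:2) {
      tk <- which(tail_n >= k)
      if (!length(tk)) next
      seqs[tk] <- paste0(seqs[tk],
                         sample(c("A", "U"), length(tk), replace = TRUE))
      qk <- draw_phred(length(tk), cfg$phred_mean, cfg$phred_sd)
      quals[tk] <- paste0(quals[tk],
                          strsplit(intToUtf8(qk + 33L), "")[[1]])
    }
    ids <- sprintf("%s:%s:%05d", sample_id, a$mature_id, seq_len(n))
    all_reads[[ai]] <- data.frame(read_id = ids, seq = seqs, qual = quals,
                                  stringsAsFactors = FALSE)
    origins[[ai]] <- data.frame(read_id = ids, origin = origin,
                                stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, all_reads),
       truth_sites = do.call(rbind, truth_sites),
       truth_reads = do.call(rbind, origins))
}

#' Write the simulated reference world to disk
#'
#' Emits exactly the formats the pipeline reads: hairpin FASTA, mature-arm
#' TSV, site TSV, genome FASTA (DNA) and 3'UTR FASTA.
#'
#' @param sim world from [simulate_references()]
#' @param dir output directory (created if needed)
#' @return named vector of written paths
#' @export
write_reference_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(premirna = file.path(dir, "hairpins.fa"),
             mature = file.path(dir, "mature.tsv"),
             sites = file.path(dir, "sites.tsv"),
             genome = file.path(dir, "genome.fa"),
             utrs = file.path(dir, "utr.fa"))
  writeLines(paste0(">", names(sim$refs$seq), "\n", sim$refs$seq),
             paths["premirna"])
  utils::write.table(sim$refs$arms[, c("pre_id", "mature_id", "start",
                                       "end", "arm")],
                     paths["mature"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$sites[, c("site_id", "pre_id", "mature_id",
                                   "mature_pos")],
                     paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(paste0(">", names(sim$genome), "\n", sim$genome),
             paths["genome"])
  writeLines(paste0(">", names(sim$utrs), "\n", sim$utrs), paths["utrs"])
  paths
}

#' Simulate a cohort editing-level matrix directly
#'
#' Bypasses read simulation: baseline per-site levels are drawn uniformly,
#' one condition receives a mean shift at the planted sites, Gaussian noise
#' is added, values are clipped to [0, 1] and a fraction of cells is set
#' missing at random.
#'
#' @param n_sites total number of sites (default 30)
#' @param n_planted number of shifted sites (default 5)
#' @param shift mean-level shift in the second condition (default 0.2)
#' @param n_per_cond samples per condition (default 20)
#' @param noise_sd Gaussian noise sd (default 0.05)
#' @param baseline_range uniform range for baseline levels
#'   (default c(0.05, 0.4))
#' @param missing_frac fraction of missing cells (default 0.1)
#' @param conditions two condition labels
#' @param seed RNG seed
#' @return list with `matrix` (sites x samples), `conditions`,
#'   `planted` (site ids)
#' @export
simulate_editing_matrix <- function(n_sites = 30L, n_planted = 5L,
                                    shift = 0.2, n_per_cond = 20L,
                                    noise_sd = 0.05,
                                    baseline_range = c(0.05, 0.4),
                                    missing_frac = 0.1,
                                    conditions = c("healthy", "cancer"),
                                    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  base <- stats::runif(n_sites, baseline_range[1], baseline_range[2])
  planted <- sample(n_sites, n_planted)
  n <- 2L * n_per_cond
  cond <- rep(conditions, each = n_per_cond)
  m <- matrix(base, n_sites, n) + stats::rnorm(n_sites * n, 0, noise_sd)
  m[planted, cond == conditions[2]] <- m[planted, cond == conditions[2]] + shift
  m <- pmin(pmax(m, 0), 1)
  dimnames(m) <- list(sprintf("site%02d", seq_len(n_sites)),
                      sprintf("%s_%02d", cond, seq_len(n)))
  if (missing_frac > 0)
    m[sample(length(m), round(missing_frac * length(m)))] <- NA
  list(matrix = m, conditions = cond,
       planted = rownames(m)[sort(planted)])
}
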