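test_that("substring index agrees with a naive full-scan oracle", {
  set.seed(21)
  hp <- stats::setNames(random_rna(50, 70), sprintf("h%02d", 1:50))
  idx <- build_index(hp)
  # planted queries (true substrings) and random ones (mostly absent)
  planted <- substring(hp[sample(50, 100, TRUE)],
                       sample(1:40, 100, TRUE), sample(41:70, 100, TRUE))
  planted <- planted[nchar(planted) >= 16 & nchar(planted) <= 25]
  queries <- c(planted, random_rna(100, 20))
  for (q in queries) {
    got <- query_index(idx, q)
    want <- oracle_scan(q, hp)
    expect_equal(got[order(got$ref_id, got$start), ],
                 want[order(want$ref_id, want$start), ],
                 ignore_attr = TRUE)
  }
})

test_that("two-pass assignment routes unedited, edited, and unmatched reads", {
  refs <- make_refs()
  sites <- make_sites(refs)
  ed <- build_edited_references(refs, sites)
  arm <- refs$arms$mature_seq[1]              # hpA-5p, site at arm pos 5
  edited_arm <- arm
  substr(edited_arm, 5, 5) <- "G"
  # a window of the edited reference NOT covering pre_pos 5 (positions 6..25)
  off_site <- substr(ed$sequence[1], 6, 25)
  cc <- make_collapsed(c(arm, edited_arm, off_site, random_rna(1, 20)))
  asn <- assign_reads(cc, refs, ed)
  get <- function(s) asn[asn$seq == s, ]
  expect_equal(get(arm)$status, "unedited")
  expect_equal(get(edited_arm)$status, "edited")
  expect_equal(get(edited_arm)$site_id, "sA")
  expect_equal(get(edited_arm)$ref_id, "hpA")
  # off-site window equals unedited hairpin sequence: re-routed, not edited
  expect_equal(get(off_site)$status, "unedited")
  expect_equal(get(cc$seq[4])$status, "unassigned")
  # two-pass exclusivity
  expect_true(all(tapply(asn$status, asn$seq,
                         function(s) length(unique(s)) == 1L)))
})

test_that("planted edited reads are recovered with their site id", {
  cfg <- sim_config(seed = 31, n_hairpins = 6, n_sites = 3, coverage = 50,
                    epsilon = 1e-9, tail_fraction = 0, editing_levels = 0.5)
  sim <- simulate_references(cfg)
  sr <- simulate_reads(sim, 1)
  pre <- preprocess_reads(sr$reads)
  asn <- assign_reads(pre$collapsed, sim$refs, sim$edited)
  # error-free simulation: every planted edited read must carry its site id
  truth <- merge(sr$truth_reads, data.frame(read_id = sr$reads$read_id,
                                            seq = sr$reads$seq))
  truth$seq <- trim_three_prime_au(truth$seq)
  planted <- unique(truth[grepl("^edited:", truth$origin), c("seq", "origin")])
  for (i in seq_len(nrow(planted))) {
    row <- asn[asn$seq == planted$seq[i], ]
    expect_equal(row$status, "edited")
    expect_equal(paste0("edited:", row$site_id), planted$origin[i])
  }
})

test_that("genome exclusion demotes exactly the planted sequences", {
  refs <- make_refs()
  sites <- make_sites(refs)
  ed <- build_edited_references(refs, sites)
  edited_arm <- refs$arms$mature_seq[1]
  substr(edited_arm, 5, 5) <- "G"
  cc <- make_collapsed(c(edited_arm, refs$arms$mature_seq[3]))
  asn <- assign_reads(cc, refs, ed)
  # genome absent: warning, nothing demoted
  expect_warning(asn0 <- exclude_genome_matchers(asn, NULL), "skipped")
  expect_equal(asn0, asn)
  # genome without the read: retained
  g1 <- c(chr1 = paste(rep("ACGT", 50), collapse = ""))
  expect_equal(sum(exclude_genome_matchers(asn, g1)$status == "edited"), 1L)
  # planted forward and reverse-complement decoys: demoted with reason
  fw <- chartr("U", "T", edited_arm)
  for (decoy in c(fw, paste(rev(strsplit(chartr("ACGT", "TGCA", fw),
                                         "")[[1]]), collapse = ""))) {
    g2 <- c(chr1 = paste0("AAAA", decoy, "TTTT"))
    out <- exclude_genome_matchers(asn, g2)
    expect_equal(sum(out$status == "edited"), 0L)
    expect_equal(out$reason[out$seq == edited_arm], "genomic")
    # the unedited read is untouched
    expect_equal(out$status[out$seq == refs$arms$mature_seq[3]], "unedited")
  }
})

test_that("mature attribution honours the +/-2 window and splits paralogs", {
  refs <- make_refs()
  ed <- build_edited_references(refs, make_sites(refs))
  arm <- refs$arms[1, ]                       # hpA-5p: 1-20
  inside <- substr(refs$seq[["hpA"]], 1, 20)
  within2 <- substr(refs$seq[["hpA"]], 3, 22)   # ends 2 nt past arm end
  outside <- substr(refs$seq[["hpA"]], 6, 25)   # ends 5 nt past arm end
  asn <- assign_reads(make_collapsed(c(inside, within2, outside)), refs, ed)
  att <- attribute_mature(asn, refs)
  expect_equal(att$weight[att$seq == inside], 1)
  expect_equal(att$mature_id[att$seq == inside], "hpA-5p")
  expect_equal(att$weight[att$seq == within2], 1)
  expect_false(outside %in% att$seq)

  # paralog hairpins with identical arms: weight 0.5 each
  seqs <- c(p1 = paste0("GCAUAGCAUCAUACGAUGCA", paste(rep("C", 12), collapse = ""),
                        "UUGGCCAAUUGGCCAAUUGG"),
            p2 = paste0("GCAUAGCAUCAUACGAUGCA", paste(rep("G", 12), collapse = ""),
                        "AAGGCCUUAAGGCAUUAAGG"))
  arms <- data.frame(pre_id = c("p1", "p2"), mature_id = c("p1-5p", "p2-5p"),
                     start = 1L, end = 20L, arm = "5p")
  prefs <- premirna_set(seqs, arms)
  asn2 <- assign_reads(make_collapsed("GCAUAGCAUCAUACGAUGCA"), prefs,
                       data.frame(site_id = character(0),
                                  pre_id = character(0),
                                  pre_pos = integer(0),
                                  sequence = character(0)))
  att2 <- attribute_mature(asn2, prefs)
  expect_equal(sort(att2$mature_id), c("p1-5p", "p2-5p"))
  expect_equal(att2$weight, c(0.5, 0.5))
})
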