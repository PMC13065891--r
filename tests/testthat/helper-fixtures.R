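# Shared fixtures, built in code.

# a well-formed two-hairpin reference set (60-nt hairpins, 20-nt arms)
make_refs <- function() {
  set.seed(99)
  h1 <- paste0("GCAUAGCAUCAUACGAUGCA",           # 5p arm, 1-20
               "CGCGCGCGCG",                     # loop
               "UUGGCCAAUUGGCCAAUUGG")           # 3p arm, 31-50
  h2 <- paste0("AAGGCCUUAAGGCAUUAAGG",
               "UAUAUAUAUA",
               "CCGGAAUUCCGGAAUUCCGG")
  seqs <- c(hpA = h1, hpB = h2)
  arms <- data.frame(
    pre_id = c("hpA", "hpA", "hpB", "hpB"),
    mature_id = c("hpA-5p", "hpA-3p", "hpB-5p", "hpB-3p"),
    start = c(1L, 31L, 1L, 31L),
    end = c(20L, 50L, 20L, 50L),
    arm = c("5p", "3p", "5p", "3p"), stringsAsFactors = FALSE)
  premirna_set(seqs, arms)
}

# sites on hpA-5p: position 5 of the arm is A ("GCAUAGC...")
make_sites <- function(refs) {
  load_edit_sites(refs, data.frame(
    site_id = "sA", pre_id = "hpA", mature_id = "hpA-5p", mature_pos = 5L,
    stringsAsFactors = FALSE))
}

# reads data.frame from sequences with constant quality
make_reads <- function(seqs, q = 35L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(read_id = ids, seq = seqs,
             qual = vapply(nchar(seqs),
                           function(L) intToUtf8(rep(q + 33L, L)),
                           character(1)),
             stringsAsFactors = FALSE)
}

# collapsed-read row constructor
make_collapsed <- function(seqs, counts = 1L, q = 35) {
  out <- data.frame(seq = seqs, count = rep_len(counts, length(seqs)),
                    stringsAsFactors = FALSE)
  out$qual <- lapply(nchar(seqs), function(L) rep(q, L))
  out
}

# naive full-scan substring oracle, independent of the package index:
# enumerates every window of each reference and compares strings
oracle_scan <- function(query, subjects) {
  hits <- data.frame(ref_id = character(0), start = integer(0))
  L <- nchar(query)
  for (nm in names(subjects)) {
    s <- subjects[[nm]]
    n <- nchar(s) - L + 1L
    if (n < 1L) next
    wins <- substring(s, seq_len(n), seq_len(n) + L - 1L)
    at <- which(wins == query)
    if (length(at))
      hits <- rbind(hits, data.frame(ref_id = nm, start = at,
                                     stringsAsFactors = FALSE))
  }
  hits
}

random_rna <- function(n, len) {
  vapply(rep(len, n), function(L)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
    character(1))
}
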