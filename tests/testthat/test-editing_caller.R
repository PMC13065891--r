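# assignment-table rows crafted directly: the pileup contract is defined on
# the (documented) assignment + collapsed-read interfaces
make_asn <- function(seqs, status, ref_id, start, site_id = NA_character_,
                     count = 1L, weight = 1) {
  n <- length(seqs)
  data.frame(seq = seqs, count = rep_len(count, n),
             status = rep_len(status, n), ref_id = rep_len(ref_id, n),
             start = rep_len(start, n),
             end = rep_len(start, n) + nchar(seqs) - 1L,
             site_id = rep_len(site_id, n), weight = rep_len(weight, n),
             reason = NA_character_, stringsAsFactors = FALSE)
}

test_that("pileup counts coverage and quality-masked edited reads", {
  refs <- make_refs()
  sites <- make_sites(refs)           # pre_pos 5 on hpA
  arm <- refs$arms$mature_seq[1]
  edited_arm <- arm; substr(edited_arm, 5, 5) <- "G"
  un <- make_asn(arm, "unedited", "hpA", 1L, count = 8L)
  ed <- make_asn(edited_arm, "edited", "hpA", 1L, site_id = "sA", count = 2L)
  cc <- make_collapsed(c(arm, edited_arm), q = 35)

  p <- pileup_sites(rbind(un, ed), cc, sites)
  expect_equal(p$coverage, 10)
  expect_equal(p$edited_count, 2)

  # edited base quality 25: the G reads leave numerator AND denominator
  cc_low <- cc
  cc_low$qual[[2]][5] <- 25
  p2 <- pileup_sites(rbind(un, ed), cc_low, sites)
  expect_equal(p2$coverage, 8)
  expect_equal(p2$edited_count, 0)

  # boundary: mask is >= 30
  cc_29 <- cc; cc_29$qual[[2]][5] <- 29
  cc_30 <- cc; cc_30$qual[[2]][5] <- 30
  expect_equal(pileup_sites(rbind(un, ed), cc_29, sites)$edited_count, 0)
  expect_equal(pileup_sites(rbind(un, ed), cc_30, sites)$edited_count, 2)

  # fractional weights: two half-weight edited reads sum to 1.0
  ed_frac <- make_asn(edited_arm, "edited", "hpA", 1L, site_id = "sA",
                      count = 2L, weight = 0.5)
  p3 <- pileup_sites(rbind(un, ed_frac), cc, sites)
  expect_equal(p3$edited_count, 1.0)

  # zero coverage: empty pileup row, no crash
  p4 <- pileup_sites(un[0, ], cc, sites)
  expect_equal(p4$coverage, 0)
})

test_that("editing level is the exact ratio", {
  expect_equal(editing_level(2, 10), 0.2)
  expect_equal(editing_level(0, 5), 0)
  expect_equal(editing_level(7, 7), 1)
  expect_true(is.na(editing_level(0, 0)))
})

test_that("binomial upper-tail test matches a direct pmf-summation oracle", {
  e <- error_model(0.001)
  expect_equal(site_test(0, 100, e), 1.0)
  expect_equal(site_test(10, 10, e), 1e-30, tolerance = 1e-12)
  # oracle: naive tail summation
  for (case in list(c(100, 10), c(50, 3), c(1000, 7), c(10, 0))) {
    n <- case[1]; k <- case[2]
    oracle <- sum(stats::dbinom(k:n, n, 0.001))
    expect_equal(site_test(k, n, e), oracle, tolerance = 1e-12)
  }
  # monotone in edited count at fixed coverage
  p_seq <- site_test(0:20, 100, e)
  expect_true(all(diff(p_seq) <= 0))
  # fractional counts round half-up
  expect_equal(site_test(2.5, 10.2, e), site_test(3, 10, e))
  expect_error(error_model(0.3), "0.25")
  expect_error(error_model(0), "0.25")
})

test_that("BH step-up equals the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.05), 0.05)
  set.seed(77)
  for (i in 1:5) {
    p <- runif(100)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  # permutation invariance
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("call filters enforce read support, level, and q-value", {
  e <- error_model(1e-4)
  mk <- function(ed, cov) data.frame(site_id = "s", coverage = cov,
                                     edited_count = ed)
  # 1 edited read: significant and high level, but support gate fails
  c1 <- call_sites(mk(1, 2), e)
  expect_false(c1$passes)
  expect_equal(c1$level, 0.5)
  # 3 edited reads at 3% level: level gate fails
  c2 <- call_sites(mk(3, 100), e)
  expect_false(c2$passes)
  # all gates met
  c3 <- call_sites(mk(3, 10), e)
  expect_true(c3$passes)
  # boundary: exactly 2 reads and exactly 5% pass; 1 read or 4% fail
  expect_true(call_sites(mk(2, 40), e)$passes)
  expect_false(call_sites(mk(2, 50), e)$passes)  # level 0.04
  # q threshold is strict '<'
  cx <- call_sites(mk(3, 10), e)
  expect_false(call_sites(mk(3, 10), e, max_q = cx$q_value)$passes)
  expect_true(call_sites(mk(3, 10), e, max_q = cx$q_value * 1.01)$passes)
  # zero-coverage sites emit no call
  expect_equal(nrow(call_sites(mk(0, 0), e)), 0L)
})

test_that("high-confidence aggregation needs 10 passing samples", {
  mk_calls <- function(n_pass) {
    do.call(rbind, lapply(seq_len(n_pass), function(i)
      data.frame(sample_id = paste0("s", i), site_id = "site1",
                 coverage = 100, edited_count = 10, level = 0.1,
                 p_value = 1e-9, q_value = 1e-9, passes = TRUE)))
  }
  expect_equal(nrow(aggregate_high_confidence(mk_calls(9))), 0L)
  hc <- aggregate_high_confidence(mk_calls(10))
  expect_equal(hc$site_id, "site1")
  expect_equal(hc$n_samples_detected, 10L)
  expect_equal(hc$mean_level, 0.1)
  # passing with only 1 edited read does not count
  one_read <- mk_calls(12)
  one_read$edited_count <- 1
  expect_equal(nrow(aggregate_high_confidence(one_read)), 0L)
  expect_equal(nrow(aggregate_high_confidence(mk_calls(10)[0, ])), 0L)
})

test_that("error-rate estimation averages miscall probabilities over thirds", {
  refs <- make_refs()
  arm <- refs$arms$mature_seq[1]
  # enough bases: 600 copies of a 20-nt read at Q30
  cc <- make_collapsed(arm, counts = 600L, q = 30)
  asn <- make_asn(arm, "unedited", "hpA", 1L, count = 600L)
  e30 <- estimate_error_rate(cc, asn)
  expect_equal(e30$epsilon_ag, 0.001 / 3, tolerance = 1e-12)
  cc20 <- make_collapsed(arm, counts = 600L, q = 20)
  expect_equal(estimate_error_rate(cc20, asn)$epsilon_ag, 0.01 / 3,
               tolerance = 1e-12)
  # mixed qualities: brute-force mean(10^(-q/10))/3 on the same records
  cc_mix <- make_collapsed(c(arm, substr(arm, 1, 18)), counts = c(400L, 350L))
  cc_mix$qual <- list(rep(c(30, 40), 10), rep(c(20, 35), 9))
  asn_mix <- make_asn(cc_mix$seq, "unedited", "hpA", 1L,
                      count = cc_mix$count)
  oracle <- {
    probs <- c(rep(10^(-rep(c(30, 40), 10) / 10), 400),
               rep(10^(-rep(c(20, 35), 9) / 10), 350))
    mean(probs) / 3
  }
  expect_equal(estimate_error_rate(cc_mix, asn_mix)$epsilon_ag, oracle,
               tolerance = 1e-12)
  # insufficient data falls back with a warning
  few <- make_collapsed(arm, counts = 3L)
  asn_few <- make_asn(arm, "unedited", "hpA", 1L, count = 3L)
  expect_warning(e_def <- estimate_error_rate(few, asn_few), "default")
  expect_equal(e_def$epsilon_ag, 0.001)
})
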