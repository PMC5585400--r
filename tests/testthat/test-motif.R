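test_that("PWM scoring is additive and validates its input", {
  zero <- scoring_matrix(matrix(0, 7, 4,
                                dimnames = list(NULL, c("A", "C", "G", "T"))))
  expect_equal(pwm_score("GGGACCA", zero), 0)
  expect_error(pwm_score("GGGA", zero), "length")
  expect_error(pwm_score("GGGACCN", zero), "A,C,G,T")

  m <- esefinder_srsf1_matrix()
  expect_equal(m$width, 7L)
  expect_equal(pwm_score("GGGACCA", m), 1.74, tolerance = 1e-9)
  expect_equal(pwm_score("AGAATCA", m), -3.77, tolerance = 1e-9)
  # RNA input maps U to T
  expect_equal(pwm_score("GGGACCA", m), pwm_score("gggacca", m))
  expect_equal(pwm_score("GGGACCU", m), pwm_score("GGGACCT", m))
})

test_that("pwm_scan enumerates windows and the max matches brute force", {
  m <- esefinder_srsf1_matrix()
  s1 <- "GGGACCA"
  one <- pwm_scan(s1, m)
  expect_equal(nrow(one), 1L)
  expect_true(one$is_max)

  set.seed(19)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  hits <- pwm_scan(s, m)
  expect_equal(nrow(hits), nchar(s) - m$width + 1L)
  brute <- vapply(seq_len(nchar(s) - 6L), function(i)
    pwm_score(substr(s, i, i + 6L), m), numeric(1))
  expect_equal(hits$score, brute)
  expect_equal(which(hits$is_max), which(brute == max(brute)))

  # an embedded strong ESE is found as the max
  s2 <- paste0("TTTTTTT", "GGGACCA", "TTTTTTT")
  h2 <- pwm_scan(s2, m)
  expect_equal(h2$window[h2$is_max], "GGGACCA")

  expect_error(pwm_scan("GGG", m), "shorter")
})

test_that("donor WMM log-odds is zero for background-matched matrices and
           invariant to joint rescaling", {
  bg <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  f_bg <- scoring_matrix(matrix(rep(bg, each = 9), 9, 4,
                                dimnames = list(NULL, names(bg))),
                         kind = "donor_wmm")
  d <- donor_score("CAGGTAAGT", wmm = f_bg, background = bg)
  expect_equal(d$wmm_score, 0, tolerance = 1e-12)
  expect_true(d$gt_donor)
  expect_false(donor_score("CAGCAAAGT")$gt_donor)

  set.seed(7)
  f <- matrix(runif(36, 0.05, 1), 9, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  f <- f / rowSums(f)
  m1 <- scoring_matrix(f, kind = "donor_wmm")
  m2 <- scoring_matrix(2 * f, kind = "donor_wmm")
  bg2 <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  s1 <- donor_score("CAGGTAAGT", wmm = m1, background = bg2)$wmm_score
  # scaling frequencies and background jointly leaves the log-odds fixed
  s2 <- sum(log2((2 * f)[cbind(1:9, match(strsplit("CAGGTAAGT", "")[[1]],
                                          c("A", "C", "G", "T")))] /
                   (2 * bg2[strsplit("CAGGTAAGT", "")[[1]]])))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("model-table scores are looked up exactly or reported missing", {
  tbl <- scoring_matrix(kind = "kmer_lookup",
                        lookup = c(CAGGTAAGT = 10.86, GAGGTAAGT = 9.1))
  d <- donor_score("CAGGTAAGT", maxent_table = tbl)
  expect_equal(d$maxent_score, 10.86)
  miss <- donor_score("TTTGTTTTT", maxent_table = tbl)
  expect_true(is.na(miss$maxent_score))
  # absent model: unavailable, never 0
  expect_true(is.na(donor_score("CAGGTAAGT")$sd_score))
})

test_that("block-scanning mutants substitute exactly one block each", {
  set.seed(23)
  exon <- paste(sample(c("A", "C", "G", "T"), 195, TRUE), collapse = "")
  reps <- neutral_block_sequences()
  # 12 blocks of 15 nt starting after the first 3 nt; the last block takes
  # the 19-nt replacement
  blocks <- data.frame(start = 4L + (0:11) * 15L,
                       end = 4L + (0:11) * 15L + 14L)
  repl <- c(rep(reps["block15"], 11), reps["block19"])
  mut <- block_scan_mutants(exon, blocks, repl)
  expect_equal(nrow(mut), 12L)
  expect_equal(mut$length_change, c(rep(0L, 11), 4L))
  expect_equal(nchar(mut$mutant_seq[12]), 199L)
  # non-block positions untouched
  for (i in c(1L, 12L)) {
    expect_equal(substr(mut$mutant_seq[i], 1, blocks$start[i] - 1L),
                 substr(exon, 1, blocks$start[i] - 1L))
    expect_equal(substring(mut$mutant_seq[i],
                           blocks$start[i] + nchar(repl[i])),
                 substring(exon, blocks$end[i] + 1L))
  }

  # replacement identical to the original block: identity mutant, delta 0
  m <- esefinder_srsf1_matrix()
  b5 <- data.frame(start = 10L, end = 24L)
  same <- block_scan_mutants(exon, b5, substr(exon, 10, 24), ese_matrix = m)
  expect_equal(same$mutant_seq, exon)
  expect_equal(same$delta_max_ese, 0)

  # destroying the unique max-scoring ESE window lowers the max score
  host <- paste0(strrep("T", 30), "GGGACCA", strrep("T", 30))
  hit <- pwm_scan(host, m)
  st <- hit$start[hit$is_max][1]
  kill <- block_scan_mutants(host, data.frame(start = st, end = st + 6L),
                             strrep("T", 7), ese_matrix = m)
  expect_lt(kill$delta_max_ese, 0)

  expect_error(block_scan_mutants(exon,
                                  data.frame(start = c(1, 5),
                                             end = c(10, 20)), "AAA"),
               "overlap")
})
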