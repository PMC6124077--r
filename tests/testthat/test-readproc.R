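test_that("quality trimming matches the exhaustive cut-point oracle", {
  # identity case: all bases at Q40, nothing removed
  t <- trim_reads("ACGTACGT", qstr(40, 8), q_threshold = 20)
  expect_equal(t$seq, "ACGTACGT")

  # last 20 bases at Q2 under a Q20 threshold are removed
  s <- rand_dna(100)
  q <- paste0(qstr(38, 80), qstr(2, 20))
  t <- trim_reads(s, q, q_threshold = 20)
  expect_equal(nchar(t$seq), 80)
  expect_equal(t$seq, substr(s, 1, 80))

  # random quality profiles agree with the brute-force argmax
  set.seed(101)
  for (i in 1:25) {
    L <- sample(20:80, 1)
    s <- rand_dna(L)
    q <- paste(intToUtf8(sample(2:40, L, replace = TRUE) + 33L,
                         multiple = TRUE), collapse = "")
    t <- trim_reads(s, q, q_threshold = 20)
    expect_equal(nchar(t$seq), oracle_trim_len(q, 20))
  }
})

test_that("primer and adapter occurrences at read ends are removed", {
  primer <- "TACTCCTTGAAAAAGCCCATTGTA"
  insert <- rand_dna(60)
  t <- trim_reads(paste0(primer, insert), qstr(40, 24 + 60),
                  primers = primer, q_threshold = 0)
  expect_equal(t$seq, insert)

  # up to 10% mismatches tolerated (2 of 24)
  mm <- primer
  substr(mm, 3, 3) <- "G"
  substr(mm, 10, 10) <- "C"
  t2 <- trim_reads(paste0(mm, insert), qstr(40, 24 + 60),
                   primers = primer, q_threshold = 0)
  expect_equal(t2$seq, insert)

  # 3' occurrence of the reverse complement is also removed
  t3 <- trim_reads(paste0(insert, rc_oracle(primer)), qstr(40, 24 + 60),
                   primers = primer, q_threshold = 0)
  expect_equal(t3$seq, insert)

  # malformed quality string drops the read with a warning
  expect_warning(t4 <- trim_reads(c("ACGT", "ACGT"), c("IIII", "III")),
                 "malformed")
  expect_equal(t4$n_dropped, 1L)
  expect_identical(t4$dropped, c(FALSE, TRUE))
})

test_that("pair merging recovers zero-noise geometry and enforces the overlap minimum", {
  template <- rand_dna(450)
  r1 <- substr(template, 1, 300)
  r2 <- rc_oracle(substr(template, 151, 450))
  rd <- data.frame(id = "p1", seq1 = r1, qual1 = qstr(38, 300),
                   seq2 = r2, qual2 = qstr(38, 300),
                   stringsAsFactors = FALSE)
  m <- merge_pairs(rd, min_overlap = 50)
  expect_equal(m$merged$seq, template)
  expect_equal(m$merged$overlap_len, 150)
  expect_equal(m$merged$mismatches_in_overlap, 0)

  # a true overlap of only 49 bp is rejected at min_overlap = 50
  t2 <- rand_dna(551)  # 2*300 - 551 = 49
  rd2 <- data.frame(id = "p2", seq1 = substr(t2, 1, 300),
                    qual1 = qstr(38, 300),
                    seq2 = rc_oracle(substr(t2, 252, 551)),
                    qual2 = qstr(38, 300), stringsAsFactors = FALSE)
  set.seed(33)
  m2 <- merge_pairs(rd2, min_overlap = 50)
  # any overlap >= 50 found must be spurious; the true 49 bp one is barred
  if (nrow(m2$merged) == 1) expect_true(m2$merged$overlap_len != 49)
})

test_that("chosen merge overlap equals the exhaustive-search argmax", {
  set.seed(202)
  for (i in 1:30) {
    L <- sample(40:80, 1)
    t <- rand_dna(L)
    rl <- sample(25:35, 1)
    s1 <- substr(t, 1, rl)
    s2rc <- substr(t, L - rl + 1, L)
    # sprinkle a few substitutions
    s1 <- mutate_some(s1, sample(0:3, 1))
    s2rc <- mutate_some(s2rc, sample(0:3, 1))
    rd <- data.frame(id = "x", seq1 = s1, qual1 = qstr(30, rl),
                     seq2 = rc_oracle(s2rc), qual2 = qstr(30, rl),
                     stringsAsFactors = FALSE)
    m <- merge_pairs(rd, min_overlap = 10, max_mismatch_frac = 1)
    o <- oracle_merge_offset(s1, s2rc, 10)
    expect_equal(m$merged$overlap_len, o$o)
    expect_equal(m$merged$mismatches_in_overlap, o$mm)
  }
})

test_that("mismatched overlap bases resolve to the higher-quality mate", {
  # 20 bp reads overlapping by 10; one mismatch in the overlap
  a <- paste0(strrep("A", 10), strrep("C", 10))
  b <- paste0(strrep("C", 10), strrep("G", 10))  # as merged orientation
  b_mm <- b
  substr(b_mm, 5, 5) <- "T"  # disagree with mate 1's C at overlap pos 5
  rd <- data.frame(id = "x", seq1 = a,
                   qual1 = paste0(qstr(30, 10), qstr(10, 10)),
                   seq2 = rc_oracle(b_mm),
                   qual2 = qstr(35, 20), stringsAsFactors = FALSE)
  m <- merge_pairs(rd, min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(nrow(m$merged), 1)
  # mate 2 quality (35) beats mate 1 (10) at the mismatch -> T retained
  expect_equal(substr(m$merged$seq, 15, 15), "T")
  # merged quality at the mismatch is the absolute difference
  expect_equal(utf8ToInt(substr(m$merged$qual, 15, 15)) - 33L, 25L)
})

test_that("dereplication conserves counts, filters length and orders output", {
  seqs <- c(rep(strrep("A", 400), 1000))
  u <- dereplicate(seqs)
  expect_equal(nrow(u), 1)
  expect_equal(u$count, 1000)
  expect_equal(u$frequency, 1.0)
  expect_equal(attr(u, "denominator"), 1000L)

  # sequences shorter than 379 are dropped before grouping
  u2 <- dereplicate(rep(strrep("A", 378), 10))
  expect_equal(nrow(u2), 0)
  expect_equal(attr(u2, "denominator"), 0L)

  # conservation + ordering with ties broken lexicographically
  s1 <- strrep("C", 380); s2 <- strrep("G", 380); s3 <- strrep("T", 380)
  u3 <- dereplicate(c(rep(s1, 3), rep(s2, 5), rep(s3, 3), strrep("A", 100)))
  expect_equal(sum(u3$count), 11)
  expect_equal(u3$seq, c(s2, s1, s3))
  expect_equal(sum(u3$frequency), 1, tolerance = 1e-9)
})

test_that("read conservation holds exactly through process_sample", {
  cfg <- sim_config(seed = 5, n_haplotypes = 3, reads_per_sample = 400,
                    per_base_error_rate = 0.01)
  db <- generate_reference_db(cfg)
  set.seed(55)
  rd <- simulate_sample_reads(cfg, c("CR001", "CR002"), c(0.7, 0.3), "edna",
                              db, contaminant_seq = rand_dna(450),
                              sample_id = "S")
  pr <- process_sample(rd, primers = c(cfg$forward_primer,
                                       cfg$reverse_primer),
                       sample_id = "S")
  r <- pr$report
  expect_equal(r$n_input, r$n_merged + r$n_merge_rejected + r$n_trim_dropped)
  expect_equal(r$n_merged - r$n_length_filtered, r$denominator)
  expect_equal(sum(pr$uniques$count), r$denominator)
  if (r$denominator > 0)
    expect_equal(sum(pr$uniques$frequency), 1, tolerance = 1e-9)
})

test_that("the read-depth criterion excludes atypically shallow samples", {
  expect_false(depth_criterion_ok(510, 221922))
  expect_true(depth_criterion_ok(2220, 221922))
  expect_false(depth_criterion_ok(0, 0))
})
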