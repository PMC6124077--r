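test_that("reference database has distinct equal-length haplotypes near an ancestor", {
  cfg <- sim_config(seed = 3, n_haplotypes = 58, amplicon_length_bp = 450)
  db <- generate_reference_db(cfg)
  expect_length(db, 58)
  expect_true(all(nchar(db) == 450))
  expect_equal(anyDuplicated(unname(db)), 0L)
  expect_equal(names(db)[1:3], c("CR001", "CR002", "CR003"))
  anc <- attr(db, "ancestral")
  d_anc <- vapply(db, function(s) hamming_oracle(s, anc), numeric(1))
  expect_true(all(d_anc >= 1 & d_anc <= 30))

  db1 <- generate_reference_db(sim_config(seed = 9, n_haplotypes = 1))
  expect_length(db1, 1)
})

test_that("reference FASTA output is byte-identical for the same seed", {
  cfg <- sim_config(seed = 17, n_haplotypes = 10)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  generate_reference_db(cfg, f1)
  generate_reference_db(cfg, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_reference_fasta(f1)
  expect_identical(as.character(rt), as.character(generate_reference_db(cfg)))
})

test_that("impossible distinctness is a configuration error", {
  # 4^1 = 4 possible sequences of length 1 < 5 requested haplotypes
  set.seed(1)
  expect_error(ednahap:::reference_db_draw(list(amplicon_length_bp = 1L,
                                                n_haplotypes = 5L)),
               "distinct")
})

test_that("zero-noise reads reconstruct the primer-flanked template exactly", {
  cfg <- sim_config(seed = 5, n_haplotypes = 3, per_base_error_rate = 0,
                    chimera_fraction = 0, contaminant_fraction = 0,
                    reads_per_sample = 50)
  db <- generate_reference_db(cfg)
  set.seed(42)
  rd <- simulate_sample_reads(cfg, "CR002", 1, "edna", db, sample_id = "S")
  template <- paste0(cfg$forward_primer, db[["CR002"]],
                     rc_oracle(cfg$reverse_primer))
  rl <- cfg$read_length_bp
  expect_true(all(rd$seq1 == substr(template, 1, rl)))
  expect_true(all(rd$seq2 ==
                    rc_oracle(substr(template, nchar(template) - rl + 1,
                                     nchar(template)))))
  m <- merge_pairs(rd, min_overlap = 50)
  expect_equal(nrow(m$merged), 50)
  expect_true(all(m$merged$seq == template))
  expect_true(all(m$merged$mismatches_in_overlap == 0))
})

test_that("quality strings encode the configured error rate", {
  cfg <- sim_config(seed = 5, n_haplotypes = 2, per_base_error_rate = 0.01,
                    reads_per_sample = 5)
  db <- generate_reference_db(cfg)
  set.seed(1)
  rd <- simulate_sample_reads(cfg, "CR001", 1, "edna", db,
                              contaminant_seq = rand_dna(450),
                              sample_id = "S")
  q <- utf8ToInt(substr(rd$qual1[1], 1, 1)) - 33L
  expect_equal(q, 20L)  # -10*log10(0.01)
})

test_that("two-haplotype mixtures realise the minor fraction within binomial bounds", {
  cfg <- sim_config(seed = 5, n_haplotypes = 4, per_base_error_rate = 0,
                    chimera_fraction = 0, contaminant_fraction = 0,
                    reads_per_sample = 10000)
  db <- generate_reference_db(cfg)
  set.seed(7)
  rd <- simulate_sample_reads(cfg, c("CR001", "CR002"), c(0.78, 0.22),
                              "edna", db, sample_id = "S")
  truth <- attr(rd, "truth")
  k <- truth$hap_counts[["CR002"]]
  ci <- qbinom(c(0.005, 0.995), 10000, 0.22)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("negative controls emit zero target-derived reads", {
  cfg <- sim_config(seed = 5, n_haplotypes = 2, reads_per_sample = 100)
  db <- generate_reference_db(cfg)
  set.seed(1)
  rd <- simulate_sample_reads(cfg, character(0), numeric(0),
                              "negative_control", db, sample_id = "NEG")
  expect_equal(nrow(rd), 0)
  expect_equal(attr(rd, "truth")$n_contaminant, 0)
})

test_that("realised error, chimera and contaminant rates match nominal within 3 sigma", {
  cfg <- sim_config(seed = 5, n_haplotypes = 3, per_base_error_rate = 0.01,
                    chimera_fraction = 0.05, contaminant_fraction = 0.03,
                    reads_per_sample = 4000)
  db <- generate_reference_db(cfg)
  cont <- rand_dna(cfg$amplicon_length_bp)
  set.seed(11)
  rd <- simulate_sample_reads(cfg, c("CR001", "CR003"), c(0.6, 0.4), "edna",
                              db, contaminant_seq = cont, sample_id = "S")
  truth <- attr(rd, "truth")
  n <- nrow(rd)
  for (x in list(c(truth$n_chimeric, cfg$chimera_fraction),
                 c(truth$n_contaminant, cfg$contaminant_fraction))) {
    sigma <- sqrt(n * x[2] * (1 - x[2]))
    expect_lt(abs(x[1] - n * x[2]), 3 * sigma)
  }
  # per-base error rate over >= 1e5 bases: compare error-free fwd reads of
  # a zero-chimera sim against the template
  cfg2 <- sim_config(seed = 5, n_haplotypes = 1, per_base_error_rate = 0.01,
                     chimera_fraction = 0, contaminant_fraction = 0,
                     reads_per_sample = 1000)
  db2 <- generate_reference_db(cfg2)
  set.seed(13)
  rd2 <- simulate_sample_reads(cfg2, "CR001", 1, "edna", db2, sample_id = "S")
  template <- paste0(cfg2$forward_primer, db2[["CR001"]],
                     rc_oracle(cfg2$reverse_primer))
  pref <- substr(template, 1, cfg2$read_length_bp)
  tv <- strsplit(pref, "")[[1]]
  errs <- sum(vapply(rd2$seq1, function(s) {
    sum(strsplit(s, "")[[1]] != tv)
  }, numeric(1)))
  total <- 1000 * cfg2$read_length_bp
  sigma <- sqrt(total * 0.01 * 0.99)
  expect_lt(abs(errs - total * 0.01), 3 * sigma)
})

test_that("qPCR plate follows the instrument model and flags undetermined wells", {
  set.seed(1)
  p <- simulate_qpcr_plate(standards = c(1, 0.1), unknowns = c(0.1, 0),
                           slope = -3.3219, intercept = 21, noise_sd = 0)
  expect_equal(p$ct[p$role == "standard"][2], 24.3219, tolerance = 1e-6)
  expect_equal(p$ct[p$sample_id == "UNK01"], 24.3219, tolerance = 1e-6)
  expect_true(p$undetermined[p$sample_id == "UNK02"])
  expect_true(is.na(p$ct[p$sample_id == "UNK02"]))

  # the 1:10 dilution series spanning 1.3 to 1.3e-5 gives 6 standard wells
  p2 <- simulate_qpcr_plate(standards = 1.3 * 10^-(0:5), unknowns = numeric(0),
                            slope = -3.3219, intercept = 21, noise_sd = 0)
  expect_equal(sum(p2$role == "standard"), 6)

  # concentration so small its predicted Ct exceeds the cutoff
  p3 <- simulate_qpcr_plate(standards = c(1, 0.1, 0.01), unknowns = 1e-12,
                            slope = -3.3219, intercept = 21, noise_sd = 0,
                            detection_cutoff = 45)
  expect_true(p3$undetermined[p3$role == "unknown"])
})

test_that("sim_config rejects invalid parameters", {
  expect_error(sim_config(per_base_error_rate = 1.5), "probabilities")
  expect_error(sim_config(stratum_haplotype_freqs =
                            matrix(c(0.6, 0.5, 0.3, 0.5), 2)), "sum to 1")
  expect_error(sim_config(minor_fraction_range = c(0.2, 0.7)), "0.5")
  expect_error(sim_config(amplicon_length_bp = 300), "379")
  expect_error(sim_config(read_length_bp = 200), "mergeable")
})
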