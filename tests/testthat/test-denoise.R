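make_uniques <- function(seqs, counts, sample_id = "S") {
  if (length(seqs) == 0L) {
    u <- data.frame(seq = character(0), count = integer(0),
                    frequency = numeric(0), sample_id = character(0),
                    stringsAsFactors = FALSE)
    attr(u, "denominator") <- 0L
    return(u)
  }
  ord <- order(-counts, seqs, method = "radix")
  u <- data.frame(seq = seqs[ord], count = counts[ord],
                  frequency = counts[ord] / sum(counts),
                  sample_id = sample_id, stringsAsFactors = FALSE)
  attr(u, "denominator") <- sum(counts)
  u
}

test_that("chimera detector flags constructed crossovers and respects the skew rule", {
  set.seed(71)
  A <- rand_dna(450)
  B <- mutate_some(A, 20)
  cross <- paste0(substr(A, 1, 200), substr(B, 201, 450))

  u <- make_uniques(c(A, B, cross), c(40, 20, 10))
  f <- detect_chimeras(u)
  expect_identical(f$chimera, u$seq == cross)

  # skew < 2: parents only 20 vs candidate 15 -> not flagged
  u2 <- make_uniques(c(A, B, cross), c(20, 20, 15))
  f2 <- detect_chimeras(u2)
  expect_false(any(f2$chimera))

  # single-haplotype error cloud: no two-parent model exists
  errs <- vapply(1:8, function(i) mutate_some(A, 1), character(1))
  u3 <- make_uniques(c(A, errs), c(1000, rep(2, 8)))
  expect_false(any(detect_chimeras(u3)$chimera))
})

test_that("chimera flags equal the brute-force breakpoint/parent-pair oracle", {
  set.seed(72)
  for (rep in 1:10) {
    L <- 60
    A <- rand_dna(L)
    B <- mutate_some(A, sample(5:12, 1))
    C <- mutate_some(A, sample(5:12, 1))
    p <- sample(10:(L - 10), 1)
    cross <- paste0(substr(A, 1, p), substr(B, p + 1, L))
    extra <- replicate(3, mutate_some(A, sample(1:3, 1)))
    seqs <- c(A, B, C, cross, extra)
    counts <- c(50, 40, 30, sample(3:12, 1), sample(1:3, 3, replace = TRUE))
    u <- make_uniques(seqs, counts)
    got <- detect_chimeras(u)$chimera
    want <- oracle_chimera(u$seq, u$count)
    expect_identical(got, want)
  }
})

test_that("a crossover differing from a parent by fewer than min_diffs is not flagged", {
  set.seed(73)
  A <- rand_dna(450)
  flip <- function(s, p) {
    substr(s, p, p) <- if (substr(s, p, p) == "A") "C" else "A"
    s
  }
  # B differs from A at 100, 448, 449; crossover at breakpoint 445 differs
  # from A by 2 (positions 448, 449) but from B by only 1 (position 100)
  B <- flip(flip(flip(A, 100), 448), 449)
  cross <- paste0(substr(A, 1, 445), substr(B, 446, 450))
  u <- make_uniques(c(A, B, cross), c(40, 30, 5))
  expect_false(any(detect_chimeras(u, min_diffs_to_parent = 2L)$chimera))
  expect_identical(detect_chimeras(u, min_diffs_to_parent = 1L)$chimera,
                   u$seq == cross)
})

test_that("error calibration reproduces the defining arithmetic and rounding", {
  known_seq <- strrep("A", 400)
  err1 <- paste0(strrep("A", 399), "C")
  err2 <- paste0(strrep("A", 399), "G")
  u <- make_uniques(c(known_seq, err1, err2), c(9700L, 200L, 100L))
  cal <- calibrate_error(list(P1 = u), c(P1 = known_seq))
  expect_equal(unname(cal$per_control_rate["P1"]), 0.02)

  # 100% known haplotype -> rate 0
  u0 <- make_uniques(known_seq, 10000L)
  cal0 <- calibrate_error(list(P1 = u0), c(P1 = known_seq))
  expect_equal(unname(cal0$max_rate), 0)
  expect_equal(cal0$threshold, 0)

  # observed max 1.70% rounds up to the 2% working threshold
  u17 <- make_uniques(c(known_seq, err1, err2), c(9730L, 170L, 100L))
  cal17 <- calibrate_error(list(P1 = u17), c(P1 = known_seq))
  expect_equal(unname(cal17$max_rate), 0.017)
  expect_equal(cal17$threshold, 0.02)
  cal_raw <- calibrate_error(list(P1 = u17), c(P1 = known_seq),
                             rounding = "raw_max")
  expect_equal(cal_raw$threshold, 0.017)

  # summary statistics across controls
  cal2 <- calibrate_error(list(P1 = u, P2 = u17),
                          c(P1 = known_seq, P2 = known_seq))
  expect_equal(cal2$max_rate, 0.02)
  expect_equal(cal2$mean_rate, mean(c(0.02, 0.017)))
  expect_equal(cal2$sd_rate, sd(c(0.02, 0.017)))

  # empty control excluded with a warning; all empty is an error
  ue <- make_uniques(character(0), integer(0))
  expect_warning(cal3 <- calibrate_error(list(P1 = u, P2 = ue),
                                         c(P1 = known_seq, P2 = known_seq)),
                 "zero surviving")
  expect_equal(cal3$n_controls, 1L)
  expect_error(suppressWarnings(
    calibrate_error(list(P1 = ue), c(P1 = known_seq))), "empty")
})

test_that("threshold filter keeps >= threshold, drops chimeras, is idempotent and monotone", {
  s <- vapply(1:3, function(i) rand_dna(400), character(1))
  u <- make_uniques(s, c(850L, 21L, 15L))
  u$frequency <- c(0.85, 0.021, 0.015)
  r <- apply_threshold(u, 0.02)
  expect_equal(nrow(r), 2)
  expect_equal(r$frequency, c(0.85, 0.021))

  # identity at threshold 0 (minus chimeras)
  u$chimera <- c(FALSE, TRUE, FALSE)
  r0 <- apply_threshold(u, 0)
  expect_equal(nrow(r0), 2)
  expect_false(any(r0$chimera))

  # idempotence and monotonicity
  expect_identical(apply_threshold(r, 0.02)$seq, r$seq)
  set.seed(99)
  for (i in 1:10) {
    fr <- runif(6)
    uu <- make_uniques(vapply(1:6, function(i) rand_dna(390), character(1)),
                       as.integer(1000 * fr / sum(fr)) + 1L)
    t1 <- runif(1); t2 <- runif(1, t1, 1)
    r1 <- apply_threshold(uu, t1)
    r2 <- apply_threshold(uu, t2)
    expect_true(all(r2$seq %in% r1$seq))
  }
})

test_that("calibrated rates on simulated controls are bounded and stable across replicates", {
  cfg <- sim_config(seed = 5, n_haplotypes = 6, reads_per_sample = 1000,
                    per_base_error_rate = 0.003)
  db <- generate_reference_db(cfg)
  set.seed(301)
  rates <- numeric(20)
  for (i in 1:20) {
    hap <- sample(names(db), 1)
    rd <- simulate_sample_reads(cfg, hap, 1, "positive_control", db,
                                sample_id = "P")
    pr <- process_sample(rd, primers = c(cfg$forward_primer,
                                         cfg$reverse_primer),
                         sample_id = "P")
    cal <- calibrate_error(list(P = pr$uniques),
                           c(P = unname(db[hap])))
    # the most-abundant-error rate never exceeds the total error fraction
    total_err <- 1 - pr$uniques$frequency[pr$uniques$seq == db[hap]]
    expect_lte(cal$per_control_rate[["P"]], total_err + 1e-12)
    rates[i] <- cal$per_control_rate[["P"]]
  }
  expect_lt(sd(rates) / mean(rates), 0.5)  # CV < 50%
})
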