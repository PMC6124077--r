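#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' a single MiSeq run of a ~450 bp mitochondrial control-region amplicon
#' sequenced 2 x 300 bp: a reference database of 58 known haplotypes, eDNA
#' samples carrying one or (with probability `multi_haplotype_prob`) two
#' haplotypes, positive-control libraries of known haplotype, negative
#' controls with no target DNA, plus PCR chimeras and non-target
#' contaminant reads.
#'
#' @param seed Integer seed; all simulator output is deterministic given it.
#' @param n_haplotypes Size of the reference haplotype database.
#' @param amplicon_length_bp Length of each haplotype (insert between the
#'   primers). Must be at least 379.
#' @param read_length_bp Length of each mate (default 300, V3-600 paired-end
#'   chemistry).
#' @param per_base_error_rate Per-base substitution error probability
#'   applied independently to every sequenced base (PCR + sequencing
#'   error combined).
#' @param chimera_fraction Probability a read derives from a two-parent
#'   single-breakpoint PCR chimera (only realised in samples carrying two
#'   or more templates).
#' @param contaminant_fraction Probability a read derives from the
#'   non-target contaminant sequence (<70% identity to any reference).
#' @param reads_per_sample Read pairs emitted per sequenced sample.
#' @param n_samples Number of eDNA (seawater) samples.
#' @param n_positive_controls,n_negative_controls Control sample counts.
#'   Negative controls emit zero reads (no detectable PCR product).
#' @param n_strata Number of geographic strata the eDNA samples span.
#' @param stratum_haplotype_freqs Numeric matrix, `n_strata` rows, one
#'   column per haplotype drawn on (named by haplotype index among the
#'   reference ids); rows sum to 1. Default: two strata (northern and
#'   southern inland waters) over the first 8 haplotypes, with a shared
#'   dominant haplotype but diverging minor-haplotype frequencies.
#' @param multi_haplotype_prob Probability an eDNA sample mixes two
#'   haplotypes (about 3/29 samples in typical fluke-print surveys).
#' @param minor_fraction_range Interval in (0, 0.5] the minor haplotype's
#'   mixing proportion is drawn from.
#' @param forward_primer,reverse_primer Amplification primer sequences; the
#'   simulated template is `forward_primer + haplotype +
#'   revcomp(reverse_primer)`.
#' @param qpcr_slope,qpcr_intercept,qpcr_noise_sd,qpcr_detection_cutoff
#'   Parameters of the simulated qPCR instrument response
#'   (Ct = slope * log10(conc) + intercept + N(0, noise_sd), undetermined
#'   beyond the cutoff cycle).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_haplotypes = 58L,
                       amplicon_length_bp = 450L,
                       read_length_bp = 300L,
                       per_base_error_rate = 0.003,
                       chimera_fraction = 0.01,
                       contaminant_fraction = 0.005,
                       reads_per_sample = 10000L,
                       n_samples = 20L,
                       n_positive_controls = 4L,
                       n_negative_controls = 2L,
                       n_strata = 2L,
                       stratum_haplotype_freqs = NULL,
                       multi_haplotype_prob = 0.10,
                       minor_fraction_range = c(0.20, 0.40),
                       forward_primer = "TACTCCTTGAAAAAGCCCATTGTA",
                       reverse_primer = "ATGGTCCTGAAGTAAGAACCAGATG",
                       qpcr_slope = -3.4,
                       qpcr_intercept = 21,
                       qpcr_noise_sd = 0.2,
                       qpcr_detection_cutoff = 45) {
  if (is.null(stratum_haplotype_freqs)) {
    stratum_haplotype_freqs <- rbind(
      north = c(0.50, 0.20, 0.10, 0.08, 0.05, 0.03, 0.02, 0.02),
      south = c(0.30, 0.05, 0.25, 0.05, 0.15, 0.05, 0.10, 0.05)
    )
    if (n_strata != 2L) {
      stratum_haplotype_freqs <- matrix(
        rep(stratum_haplotype_freqs[1L, ], n_strata),
        nrow = n_strata, byrow = TRUE
      )
      rownames(stratum_haplotype_freqs) <- paste0("stratum", seq_len(n_strata))
    }
    if (n_haplotypes < ncol(stratum_haplotype_freqs)) {
      m <- stratum_haplotype_freqs[, seq_len(n_haplotypes), drop = FALSE]
      stratum_haplotype_freqs <- m / rowSums(m)
    }
  }
  cfg <- list(
    seed = as.integer(seed),
    n_haplotypes = as.integer(n_haplotypes),
    amplicon_length_bp = as.integer(amplicon_length_bp),
    read_length_bp = as.integer(read_length_bp),
    per_base_error_rate = per_base_error_rate,
    chimera_fraction = chimera_fraction,
    contaminant_fraction = contaminant_fraction,
    reads_per_sample = as.integer(reads_per_sample),
    n_samples = as.integer(n_samples),
    n_positive_controls = as.integer(n_positive_controls),
    n_negative_controls = as.integer(n_negative_controls),
    n_strata = as.integer(n_strata),
    stratum_haplotype_freqs = stratum_haplotype_freqs,
    multi_haplotype_prob = multi_haplotype_prob,
    minor_fraction_range = minor_fraction_range,
    forward_primer = toupper(gsub("[ \t]", "", forward_primer)),
    reverse_primer = toupper(gsub("[ \t]", "", reverse_primer)),
    qpcr_slope = qpcr_slope,
    qpcr_intercept = qpcr_intercept,
    qpcr_noise_sd = qpcr_noise_sd,
    qpcr_detection_cutoff = qpcr_detection_cutoff
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_haplotypes >= 1L,
    cfg$amplicon_length_bp >= 379L,
    cfg$read_length_bp >= 50L
  )
  probs <- c(cfg$per_base_error_rate, cfg$chimera_fraction,
             cfg$contaminant_fraction, cfg$multi_haplotype_prob)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$chimera_fraction + cfg$contaminant_fraction > 1)
    stop("chimera_fraction + contaminant_fraction must not exceed 1",
         call. = FALSE)
  f <- cfg$stratum_haplotype_freqs
  if (!is.matrix(f) || nrow(f) != cfg$n_strata)
    stop("stratum_haplotype_freqs must be a matrix with n_strata rows",
         call. = FALSE)
  if (any(abs(rowSums(f) - 1) > 1e-9))
    stop("stratum haplotype frequency vectors must sum to 1 (tol 1e-9)",
         call. = FALSE)
  if (ncol(f) > cfg$n_haplotypes)
    stop("more haplotype frequencies than haplotypes in the reference db",
         call. = FALSE)
  mfr <- cfg$minor_fraction_range
  if (length(mfr) != 2L || mfr[1] <= 0 || mfr[2] > 0.5 || mfr[1] > mfr[2])
    stop("minor_fraction_range must be an interval within (0, 0.5]",
         call. = FALSE)
  # read pairs must be mergeable at the default minimum overlap of 50 bp,
  # accounting for the primer flanks on the template
  template_len <- cfg$amplicon_length_bp +
    nchar(cfg$forward_primer) + nchar(cfg$reverse_primer)
  if (2L * cfg$read_length_bp - template_len < 50L)
    stop("2 * read_length_bp - template length < 50 bp: ",
         "read pairs would not be mergeable", call. = FALSE)
  if (!grepl("^[ACGT]+$", cfg$forward_primer) ||
      !grepl("^[ACGT]+$", cfg$reverse_primer))
    stop("primers must be A/C/G/T strings", call. = FALSE)
  invisible(cfg)
}

# run code under a seeded, restored RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
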