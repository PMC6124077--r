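#' @title Synthetic data generation
#' @description Ground-truth simulator for the whole pipeline: reference
#'   haplotype databases, per-sample paired-end reads (eDNA samples,
#'   positive and negative controls) with recorded truth, and qPCR plates.
#' @name synthdata
NULL

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq, positions) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# draws the reference database from the current RNG stream
reference_db_draw <- function(cfg) {
  L <- cfg$amplicon_length_bp
  n <- cfg$n_haplotypes
  if (log(n) > L * log(4))
    stop("cannot generate ", n, " distinct sequences of length ", L,
         call. = FALSE)
  ancestral <- random_dna(L)
  max_subs <- min(30L, L)
  seqs <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      k <- sample(seq_len(max_subs), 1L)
      cand <- substitute_bases(ancestral, sample(L, k))
      if (!(cand %in% seen)) break
    }
    seqs[i] <- cand
    seen <- c(seen, cand)
  }
  names(seqs) <- sprintf("CR%03d", seq_len(n))
  attr(seqs, "ancestral") <- ancestral
  seqs
}

#' Generate a reference haplotype database
#'
#' Draws `n_haplotypes` equal-length, pairwise-distinct control-region
#' haplotypes, each 1-30 substitutions away from a common random ancestral
#' sequence. Deterministic given `config$seed`; ids are `CR001`, `CR002`, ...
#'
#' @param config A [sim_config()].
#' @param fasta_path Optional path; if given, the database is also written
#'   as FASTA.
#' @return Named character vector of haplotype sequences (invisibly also
#'   written to `fasta_path` if requested).
#' @export
generate_reference_db <- function(config, fasta_path = NULL) {
  db <- with_seed(config$seed, reference_db_draw(config))
  if (!is.null(fasta_path)) write_reference_fasta(db, fasta_path)
  db
}

#' Write a reference database as FASTA
#' @param db Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_reference_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(unclass(db)[seq_along(db)])
  names(x) <- names(db)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference database from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

phred_char <- function(rate) {
  q <- if (rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(rate))))
  intToUtf8(q + 33L)
}

#' Simulate paired-end reads for one sample
#'
#' Each read pair derives from one template: a primer-flanked haplotype, a
#' two-parent single-breakpoint chimera (only when the sample carries two or
#' more haplotypes), or the primer-flanked contaminant. The forward read is
#' the first `read_length_bp` bases of the template, the reverse read the
#' reverse complement of the last `read_length_bp` bases; i.i.d.
#' substitution errors are applied at `per_base_error_rate`, and the quality
#' string is the constant Phred score matching that rate (capped at 40).
#' Chimera breakpoints are uniform on `[50, L - 50]` of the template.
#'
#' Draws from the current RNG stream; seed via [set.seed()] or use
#' [simulate_cohort()] for a fully seeded run.
#'
#' @param config A [sim_config()].
#' @param hap_ids Character vector of haplotype ids present (empty for
#'   negative controls).
#' @param props Mixing proportions, same length as `hap_ids`, summing to 1.
#' @param role One of `"edna"`, `"positive_control"`, `"negative_control"`.
#' @param reference Named character vector from [generate_reference_db()].
#' @param contaminant_seq Optional non-target insert sequence; required when
#'   `config$contaminant_fraction > 0` and `role = "edna"`.
#' @param sample_id Sample identifier used in read names.
#' @return A data.frame with columns `id, seq1, qual1, seq2, qual2`;
#'   attribute `"truth"` records realised per-haplotype, chimeric and
#'   contaminant read counts.
#' @export
simulate_sample_reads <- function(config, hap_ids, props, role, reference,
                                  contaminant_seq = NULL,
                                  sample_id = "sample") {
  stopifnot(all(hap_ids %in% names(reference)))
  if (role == "negative_control" || length(hap_ids) == 0L) {
    reads <- data.frame(id = character(0), seq1 = character(0),
                        qual1 = character(0), seq2 = character(0),
                        qual2 = character(0), stringsAsFactors = FALSE)
    attr(reads, "truth") <- list(hap_counts = integer(0), n_chimeric = 0L,
                                 n_contaminant = 0L)
    return(reads)
  }
  stopifnot(abs(sum(props) - 1) < 1e-9, length(props) == length(hap_ids))
  n <- config$reads_per_sample
  rl <- config$read_length_bp
  fp <- config$forward_primer
  rp_rc <- revcomp_cpp(config$reverse_primer)
  templates_hap <- paste0(fp, reference[hap_ids], rp_rc)
  Lt <- nchar(templates_hap[1L])

  is_control <- role == "positive_control"
  p_cont <- if (is_control) 0 else config$contaminant_fraction
  p_chim <- if (length(hap_ids) >= 2L) config$chimera_fraction else 0
  u <- runif(n)
  category <- ifelse(u < p_cont, "contaminant",
                     ifelse(u < p_cont + p_chim, "chimera", "target"))

  templates <- character(n)
  idx_t <- which(category == "target")
  hap_draw <- rep(NA_character_, n)
  if (length(idx_t) > 0L) {
    hap_draw[idx_t] <- if (length(hap_ids) == 1L) hap_ids else
      sample(hap_ids, length(idx_t), replace = TRUE, prob = props)
    templates[idx_t] <- templates_hap[match(hap_draw[idx_t], hap_ids)]
  }
  idx_c <- which(category == "chimera")
  for (i in idx_c) {
    par <- sample(seq_along(hap_ids), 2L, prob = props)
    b <- sample(50:(Lt - 50L), 1L)
    templates[i] <- paste0(substr(templates_hap[par[1L]], 1L, b),
                           substr(templates_hap[par[2L]], b + 1L, Lt))
  }
  idx_k <- which(category == "contaminant")
  if (length(idx_k) > 0L) {
    if (is.null(contaminant_seq))
      stop("contaminant_seq required when contaminant reads are drawn",
           call. = FALSE)
    templates[idx_k] <- paste0(fp, contaminant_seq, rp_rc)
  }

  tl <- nchar(templates)
  fwd <- substr(templates, 1L, rl)
  rev <- revcomp_cpp(substr(templates, tl - rl + 1L, tl))
  rate <- config$per_base_error_rate
  fwd <- mutate_seqs_cpp(fwd, rate)
  rev <- mutate_seqs_cpp(rev, rate)
  qc <- phred_char(rate)
  qual <- strrep(qc, rl)
  reads <- data.frame(
    id = sprintf("%s_%06d", sample_id, seq_len(n)),
    seq1 = fwd, qual1 = qual, seq2 = rev, qual2 = qual,
    stringsAsFactors = FALSE
  )
  hap_counts <- vapply(hap_ids, function(h) sum(hap_draw == h, na.rm = TRUE),
                       integer(1))
  attr(reads, "truth") <- list(hap_counts = hap_counts,
                               n_chimeric = length(idx_c),
                               n_contaminant = length(idx_k))
  reads
}

draw_contaminant <- function(cfg, reference) {
  L <- cfg$amplicon_length_bp
  repeat {
    cand <- random_dna(L)
    ident <- 1 - hamming_matrix_cpp(c(cand, unname(reference)))[1L, -1L] / L
    if (all(ident < 0.70)) return(cand)
  }
}

#' Simulate a complete sequencing cohort with ground truth
#'
#' Generates the reference database, sample metadata (strata, coordinates,
#' dates), positive/negative controls, per-sample paired-end reads and a
#' qPCR plate, all deterministically from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `edna_cohort`: a list with elements `config`,
#'   `reference`, `contaminant_seq`, `metadata` (one row per sample),
#'   `truth` (per-sample composition and realised read counts), `reads`
#'   (named list of read data.frames) and `qpcr` (plate + true
#'   concentrations).
#' @export
simulate_cohort <- function(config) {
  with_seed(config$seed, {
    reference <- reference_db_draw(config)
    contaminant_seq <- draw_contaminant(config, reference)
    freqs <- config$stratum_haplotype_freqs
    hap_pool <- names(reference)[seq_len(ncol(freqs))]
    strata <- rownames(freqs)
    if (is.null(strata)) strata <- paste0("stratum", seq_len(nrow(freqs)))

    n_e <- config$n_samples
    edna_ids <- sprintf("EDNA%02d", seq_len(n_e))
    stratum <- sample(rep_len(strata, n_e))
    lat <- ifelse(stratum == strata[1L], runif(n_e, 57.3, 58.4),
                  runif(n_e, 54.6, 55.8))
    lon <- runif(n_e, -134.5, -131.0)
    date <- sample(c(
      seq(as.Date("2016-06-05"), as.Date("2016-06-18"), by = "day"),
      seq(as.Date("2016-09-05"), as.Date("2016-09-18"), by = "day")
    ), n_e, replace = TRUE)

    pos_ids <- sprintf("POS%02d", seq_len(config$n_positive_controls))
    pos_haps <- names(reference)[sample(config$n_haplotypes,
                                        config$n_positive_controls)]
    neg_ids <- sprintf("NEG%02d", seq_len(config$n_negative_controls))

    truth <- list()
    reads <- list()
    for (i in seq_len(n_e)) {
      f <- freqs[match(stratum[i], strata), ]
      multi <- runif(1) < config$multi_haplotype_prob
      if (multi) {
        haps <- sample(hap_pool, 2L, prob = f)
        minor <- runif(1, config$minor_fraction_range[1L],
                       config$minor_fraction_range[2L])
        props <- c(1 - minor, minor)
      } else {
        haps <- sample(hap_pool, 1L, prob = f)
        props <- 1
      }
      reads[[edna_ids[i]]] <- simulate_sample_reads(
        config, haps, props, "edna", reference, contaminant_seq, edna_ids[i])
      truth[[edna_ids[i]]] <- list(role = "edna", hap_ids = haps,
                                   props = props, stratum = stratum[i])
    }
    for (i in seq_along(pos_ids)) {
      reads[[pos_ids[i]]] <- simulate_sample_reads(
        config, pos_haps[i], 1, "positive_control", reference,
        contaminant_seq, pos_ids[i])
      truth[[pos_ids[i]]] <- list(role = "positive_control",
                                  hap_ids = pos_haps[i], props = 1,
                                  stratum = NA_character_)
    }
    for (i in seq_along(neg_ids)) {
      reads[[neg_ids[i]]] <- simulate_sample_reads(
        config, character(0), numeric(0), "negative_control", reference,
        contaminant_seq, neg_ids[i])
      truth[[neg_ids[i]]] <- list(role = "negative_control",
                                  hap_ids = character(0), props = numeric(0),
                                  stratum = NA_character_)
    }
    for (sid in names(truth)) {
      truth[[sid]]$realized <- attr(reads[[sid]], "truth")
    }

    metadata <- data.frame(
      sample_id = c(edna_ids, pos_ids, neg_ids),
      role = c(rep("edna", n_e),
               rep("positive_control", length(pos_ids)),
               rep("negative_control", length(neg_ids))),
      known_haplotype = c(rep(NA_character_, n_e), pos_haps,
                          rep(NA_character_, length(neg_ids))),
      stratum = c(stratum, rep(NA_character_,
                               length(pos_ids) + length(neg_ids))),
      latitude = c(round(lat, 4), rep(NA_real_,
                                      length(pos_ids) + length(neg_ids))),
      longitude = c(round(lon, 4), rep(NA_real_,
                                       length(pos_ids) + length(neg_ids))),
      date = c(as.character(date), rep(NA_character_,
                                       length(pos_ids) + length(neg_ids))),
      stringsAsFactors = FALSE
    )

    true_conc <- rlnorm(n_e, meanlog = log(0.0033), sdlog = 1.5)
    plate <- simulate_qpcr_plate(
      standards = 1.3 * 10^-(0:5),
      unknowns = c(true_conc, rep(0, length(neg_ids))),
      slope = config$qpcr_slope, intercept = config$qpcr_intercept,
      noise_sd = config$qpcr_noise_sd,
      detection_cutoff = config$qpcr_detection_cutoff,
      unknown_ids = c(edna_ids, neg_ids)
    )

    out <- list(config = config, reference = reference,
                contaminant_seq = contaminant_seq, metadata = metadata,
                truth = truth, reads = reads,
                qpcr = list(plate = plate,
                            true_concentration = stats::setNames(true_conc,
                                                                 edna_ids)))
    class(out) <- "edna_cohort"
    out
  })
}

#' Simulate a qPCR plate
#'
#' Ct values follow the instrument model
#' `Ct = slope * log10(concentration) + intercept + N(0, noise_sd)`. Wells
#' whose Ct falls beyond `detection_cutoff` cycles (or with non-amplifying
#' template, concentration <= 0) are flagged undetermined with `Ct = NA`.
#'
#' @param standards Concentrations (ng/ul) of the standard dilution series.
#' @param unknowns True concentrations of unknown wells (0 = no template).
#' @param slope,intercept Standard-curve parameters; `slope` must be < 0.
#' @param noise_sd Gaussian noise on the Ct scale.
#' @param detection_cutoff Maximum cycle considered detected.
#' @param unknown_ids Optional sample ids for the unknown wells.
#' @return data.frame with columns `well, sample_id, role, concentration,
#'   ct, undetermined`.
#' @export
simulate_qpcr_plate <- function(standards, unknowns, slope = -3.4,
                                intercept = 21, noise_sd = 0.2,
                                detection_cutoff = 45,
                                unknown_ids = NULL) {
  stopifnot(slope < 0, all(standards > 0))
  if (is.null(unknown_ids))
    unknown_ids <- sprintf("UNK%02d", seq_along(unknowns))
  conc <- c(standards, unknowns)
  role <- c(rep("standard", length(standards)),
            rep("unknown", length(unknowns)))
  ids <- c(sprintf("STD%02d", seq_along(standards)), unknown_ids)
  ct <- rep(NA_real_, length(conc))
  amp <- conc > 0
  ct[amp] <- slope * log10(conc[amp]) + intercept +
    rnorm(sum(amp), 0, noise_sd)
  undet <- !amp | ct > detection_cutoff
  ct[undet] <- NA_real_
  data.frame(
    well = sprintf("W%02d", seq_along(conc)),
    sample_id = ids, role = role,
    concentration = ifelse(role == "standard", conc, NA_real_),
    ct = ct, undetermined = undet,
    stringsAsFactors = FALSE
  )
}

#' Write a cohort's files to disk
#'
#' Writes the reference FASTA, per-sample paired FASTQ files, metadata and
#' truth TSVs, the qPCR plate TSV and the configuration JSON. Output is
#' byte-deterministic given the cohort.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(file.path(outdir, "fastq"), recursive = TRUE,
             showWarnings = FALSE)
  write_reference_fasta(cohort$reference,
                        file.path(outdir, "reference.fasta"))
  for (sid in names(cohort$reads)) {
    write_sample_fastq(cohort$reads[[sid]],
                       file.path(outdir, "fastq", sid))
  }
  write_tsv(cohort$metadata, file.path(outdir, "metadata.tsv"))
  tr <- do.call(rbind, lapply(names(cohort$truth), function(sid) {
    t <- cohort$truth[[sid]]
    data.frame(sample_id = sid, role = t$role,
               hap_ids = paste(t$hap_ids, collapse = ","),
               props = paste(format(t$props, digits = 10), collapse = ","),
               n_chimeric = t$realized$n_chimeric,
               n_contaminant = t$realized$n_contaminant,
               stringsAsFactors = FALSE)
  }))
  write_tsv(tr, file.path(outdir, "truth.tsv"))
  write_tsv(cohort$qpcr$plate, file.path(outdir, "qpcr.tsv"))
  cfg <- cohort$config
  cfg$stratum_haplotype_freqs <- apply(cfg$stratum_haplotype_freqs, 1,
                                       identity, simplify = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Write one sample's reads as a FASTQ pair
#' @param reads Read data.frame (`id, seq1, qual1, seq2, qual2`).
#' @param prefix Path prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @export
write_sample_fastq <- function(reads, prefix) {
  for (mate in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", mate)]])
    names(s) <- reads$id
    q <- Biostrings::BStringSet(reads[[paste0("qual", mate)]])
    x <- Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(q))
    Biostrings::writeQualityScaledXStringSet(
      x, sprintf("%s_R%d.fastq", prefix, mate))
  }
  invisible(prefix)
}

#' Read a FASTQ pair into a read data.frame
#' @param r1,r2 Paths to the two mate files (optionally gzipped).
#' @return Read data.frame (`id, seq1, qual1, seq2, qual2`).
#' @export
read_fastq_pair <- function(r1, r2) {
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  stopifnot(length(x1) == length(x2))
  quals <- function(x) {
    q <- S4Vectors::mcols(x)$qualities
    if (is.null(q)) character(0) else as.character(q)
  }
  data.frame(
    id = if (length(x1)) names(x1) else character(0),
    seq1 = as.character(x1),
    qual1 = quals(x1),
    seq2 = as.character(x2),
    qual2 = quals(x2),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
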