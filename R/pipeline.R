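#' @title End-to-end pipeline
#' @description From per-sample paired reads to per-sample haplotype calls
#'   and differentiation statistics: trim/merge/dereplicate, chimera
#'   flagging, positive-control error calibration, frequency thresholding,
#'   read-depth exclusion, haplotype calling, Phi-ST and chi-squared.
#' @name pipeline
NULL

#' Run the full eDNA haplotyping pipeline
#'
#' Stage order: per-sample read processing ([process_sample()]); chimera
#' flagging ([detect_chimeras()]); error calibration on positive controls
#' ([calibrate_error()]); per-sample frequency thresholding
#' ([apply_threshold()]); read-depth exclusion ([depth_criterion_ok()]);
#' haplotype calling ([call_cohort()]); and, when at least two strata are
#' observed, differentiation statistics ([phi_st()], [chi2_test()]).
#'
#' @param x An `edna_cohort` from [simulate_cohort()], or a named list of
#'   read data.frames (then `metadata` and `reference` are required).
#' @param metadata data.frame with columns `sample_id, role,
#'   known_haplotype, stratum` (roles: `edna`, `positive_control`,
#'   `negative_control`).
#' @param reference Named character vector of reference haplotypes.
#' @param primers Primer sequences trimmed from read ends; defaults to the
#'   cohort's configured primers when `x` is an `edna_cohort`.
#' @param adapters Adapter sequences trimmed from read ends.
#' @param q_threshold,min_overlap,max_mismatch_frac,min_length Read
#'   processing parameters (see [process_sample()]).
#' @param abundance_skew,min_diffs_to_parent Chimera detection parameters.
#' @param rounding Threshold rounding rule (see [calibrate_error()]).
#' @param threshold_denominator `"surviving"` (reads surviving merge +
#'   length filter; default) or `"merged"` (all merged-pair contigs) as the
#'   denominator of the thresholded frequencies.
#' @param depth_min_fraction Read-depth exclusion bound (default 0.01).
#' @param novel_min_fraction,nontarget_identity_floor Calling parameters
#'   (see [call_sample()]).
#' @param n_perm,seed Permutation settings for the differentiation tests.
#' @return Object of class `edna_pipeline_result`: list with
#'   `sample_reports`, `uniques` (chimera-flagged, per sample),
#'   `calibration`, `retained`, `calls`, `novel_sequences`, `strata`,
#'   `phi`, `chi2`, and `summary`.
#' @export
run_edna_pipeline <- function(x, metadata = NULL, reference = NULL,
                              primers = NULL, adapters = character(0),
                              q_threshold = 20, min_overlap = 50,
                              max_mismatch_frac = 0.1, min_length = 379,
                              abundance_skew = 2.0, min_diffs_to_parent = 2L,
                              rounding = "ceil_percent",
                              threshold_denominator = c("surviving",
                                                        "merged"),
                              depth_min_fraction = 0.01,
                              novel_min_fraction = 0.20,
                              nontarget_identity_floor = 0.98,
                              n_perm = 1000, seed = 1L) {
  threshold_denominator <- match.arg(threshold_denominator)
  if (inherits(x, "edna_cohort")) {
    reads <- x$reads
    metadata <- x$metadata
    reference <- x$reference
    if (is.null(primers))
      primers <- c(x$config$forward_primer, x$config$reverse_primer)
  } else {
    reads <- x
    stopifnot(!is.null(metadata), !is.null(reference))
    if (is.null(primers)) primers <- character(0)
  }
  sample_ids <- metadata$sample_id
  stopifnot(all(sample_ids %in% names(reads)))

  # stage 1-2: process + chimera flags
  processed <- list()
  uniques <- list()
  reports <- list()
  for (sid in sample_ids) {
    pr <- process_sample(reads[[sid]], primers = primers,
                         adapters = adapters, q_threshold = q_threshold,
                         min_overlap = min_overlap,
                         max_mismatch_frac = max_mismatch_frac,
                         min_length = min_length, sample_id = sid)
    u <- detect_chimeras(pr$uniques, abundance_skew, min_diffs_to_parent)
    attr(u, "denominator") <- pr$denominator
    processed[[sid]] <- pr
    uniques[[sid]] <- u
    reports[[sid]] <- pr$report
  }

  # stage 3: calibration on positive controls (chimeras removed first)
  pos <- metadata$sample_id[metadata$role == "positive_control"]
  if (length(pos) == 0L)
    stop("no positive controls in metadata: cannot calibrate", call. = FALSE)
  known <- stats::setNames(
    unname(reference[metadata$known_haplotype[match(pos,
                                                    metadata$sample_id)]]),
    pos)
  controls <- lapply(uniques[pos], function(u) {
    out <- u[!u$chimera, , drop = FALSE]
    attr(out, "denominator") <- attr(u, "denominator")
    out
  })
  calibration <- calibrate_error(controls, known, rounding = rounding)

  # stage 4-5: threshold + depth criterion on eDNA samples
  edna <- metadata$sample_id[metadata$role == "edna"]
  retained <- list()
  depth_ok <- stats::setNames(logical(length(edna)), edna)
  for (sid in edna) {
    u <- uniques[[sid]]
    denom <- attr(u, "denominator")
    n_merged <- reports[[sid]]$n_merged
    depth_ok[sid] <- depth_criterion_ok(denom, n_merged,
                                        depth_min_fraction)
    if (threshold_denominator == "merged" && n_merged > 0) {
      u$frequency <- u$count / n_merged
    }
    retained[[sid]] <- if (depth_ok[sid])
      apply_threshold(u, calibration$threshold)
    else u[0L, , drop = FALSE]
  }

  # stage 6: haplotype calls
  cc <- call_cohort(retained, reference, novel_min_fraction,
                    nontarget_identity_floor)
  calls <- cc$calls
  low_depth <- names(depth_ok)[!depth_ok]
  calls$status[calls$sample_id %in% low_depth] <- "failed_sample"
  calls$rank[calls$sample_id %in% low_depth] <- NA_character_

  # stage 7: differentiation over accepted calls
  acc <- calls[calls$status %in% c("known", "novel"), , drop = FALSE]
  acc$stratum <- metadata$stratum[match(acc$sample_id, metadata$sample_id)]
  strata <- NULL
  phi <- NULL
  chi2 <- NULL
  seqs <- c(reference, cc$novel_sequences)
  if (nrow(acc) >= 3L && length(unique(acc$stratum[!is.na(acc$stratum)])) >=
      2L && length(unique(acc$haplotype_id)) >= 2L) {
    strata <- strata_dataset(
      acc[, c("sample_id", "haplotype_id", "stratum")],
      seqs[unique(acc$haplotype_id)])
    phi <- phi_st(strata, n_perm = n_perm, seed = seed)
    chi2 <- chi2_test(strata, n_perm = n_perm, seed = seed)
  }

  n_success <- length(unique(acc$sample_id))
  summary <- list(
    n_edna_samples = length(edna),
    n_success = n_success,
    success_rate_pct = 100 * n_success / max(1L, length(edna)),
    n_failed_low_depth = sum(!depth_ok),
    n_haplotypes = length(unique(acc$haplotype_id)),
    n_novel_haplotypes = length(cc$novel_sequences),
    n_multi_haplotype_samples =
      sum(table(acc$sample_id) > 1L),
    threshold = calibration$threshold
  )
  out <- list(sample_reports = reports, uniques = uniques,
              calibration = calibration, retained = retained, calls = calls,
              novel_sequences = cc$novel_sequences, strata = strata,
              phi = phi, chi2 = chi2, summary = summary)
  class(out) <- "edna_pipeline_result"
  out
}

#' @export
print.edna_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("eDNA haplotyping pipeline: %d/%d samples successful (%.2f%%)\n",
              s$n_success, s$n_edna_samples, s$success_rate_pct))
  cat(sprintf("  threshold %.2f%% (max control error %.4f%%)\n",
              100 * s$threshold, 100 * x$calibration$max_rate))
  cat(sprintf("  %d haplotypes resolved (%d novel); %d multi-haplotype sample(s)\n",
              s$n_haplotypes, s$n_novel_haplotypes,
              s$n_multi_haplotype_samples))
  if (!is.null(x$phi)) print(x$phi)
  if (!is.null(x$chi2)) print(x$chi2)
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Writes the cohort call table, per-sample unique sequences with chimera
#' flags, per-sample processing reports, the calibration report, novel
#' haplotype FASTA and, when computed, the differentiation results. Output
#' bytes are deterministic given the result object.
#'
#' @param result An [run_edna_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$calls, file.path(outdir, "calls.tsv"))
  uq <- do.call(rbind, lapply(result$uniques, function(u) u))
  rownames(uq) <- NULL
  write_tsv(uq, file.path(outdir, "uniques.tsv"))
  rep_df <- do.call(rbind, lapply(names(result$sample_reports), function(s) {
    data.frame(sample_id = s,
               as.data.frame(result$sample_reports[[s]]),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rep_df, file.path(outdir, "sample_reports.tsv"))
  cal <- result$calibration
  jsonlite::write_json(
    list(per_control_rate = as.list(cal$per_control_rate),
         max_rate = cal$max_rate, mean_rate = cal$mean_rate,
         sd_rate = cal$sd_rate, threshold = cal$threshold,
         rounding = cal$rounding, n_controls = cal$n_controls),
    file.path(outdir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  if (length(result$novel_sequences) > 0L) {
    write_reference_fasta(result$novel_sequences,
                          file.path(outdir, "novel_haplotypes.fasta"))
  }
  if (!is.null(result$phi)) {
    jsonlite::write_json(
      list(phi_st = result$phi$phi_st, phi_p = result$phi$phi_p,
           sigma2_a = result$phi$sigma2_a, sigma2_w = result$phi$sigma2_w,
           chi2 = result$chi2$chi2, chi2_p_perm = result$chi2$chi2_p_perm,
           chi2_p_asymptotic = result$chi2$chi2_p_asymptotic,
           df = result$chi2$df, n_perm = result$phi$n_perm,
           seed = result$phi$seed),
      file.path(outdir, "differentiation.json"), auto_unbox = TRUE,
      digits = NA)
  }
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
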