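#' @title Denoising: chimera removal and error-threshold calibration
#' @description De-novo chimera flagging, positive-control error-rate
#'   calibration and the empirical frequency-threshold filter.
#' @name denoise
NULL

#' Flag de-novo chimeras
#'
#' Deterministic two-parent perfect-crossover variant of de-novo chimera
#' detection. Processing unique sequences in descending abundance, a
#' sequence is flagged chimeric iff two earlier-accepted parents exist, each
#' with count at least `abundance_skew` times its own, such that some single
#' breakpoint makes parent-A-prefix + parent-B-suffix reproduce it exactly,
#' while it differs from each single parent by at least
#' `min_diffs_to_parent` substitutions. This is a simplified, exactly
#' checkable variant of the chunked uchime-denovo heuristic, sufficient for
#' amplicon-scale chimeras.
#'
#' @param uniques Dereplicated data.frame from [dereplicate()], sorted by
#'   count descending.
#' @param abundance_skew Minimum parent/candidate abundance ratio
#'   (default 2).
#' @param min_diffs_to_parent Minimum substitutions between a chimera and
#'   each parent (default 2).
#' @return `uniques` with a logical `chimera` column added.
#' @export
detect_chimeras <- function(uniques, abundance_skew = 2.0,
                            min_diffs_to_parent = 2L) {
  if (nrow(uniques) == 0L) {
    uniques$chimera <- logical(0)
    return(uniques)
  }
  if (is.unsorted(-uniques$count))
    stop("uniques must be sorted by count descending", call. = FALSE)
  uniques$chimera <- chimera_flags_cpp(uniques$seq,
                                       as.integer(uniques$count),
                                       abundance_skew,
                                       as.integer(min_diffs_to_parent))
  uniques
}

#' Calibrate the error-frequency threshold from positive controls
#'
#' For each positive control (a library built from tissue DNA of known
#' haplotype), the error rate is the frequency of the most abundant unique
#' sequence that is not identical to the known haplotype: its read count
#' divided by the control's denominator. The downstream filter threshold is
#' a rounding of the maximum rate across controls; the default rule rounds
#' up to the next whole percent (an observed maximum of 1.70% yields a 2%
#' threshold).
#'
#' @param controls Named list of dereplicated data.frames, one per control,
#'   each with attribute `"denominator"` (or pass `denominators`).
#' @param known Named character vector: control id -> known haplotype
#'   sequence.
#' @param rounding `"ceil_percent"` (default) or `"raw_max"`.
#' @param denominators Optional named numeric vector overriding the
#'   per-control denominators.
#' @return An object of class `error_calibration`: list with
#'   `per_control_rate`, `max_rate`, `mean_rate`, `sd_rate`, `threshold`,
#'   `rounding`, `n_controls`.
#' @export
calibrate_error <- function(controls, known,
                            rounding = c("ceil_percent", "raw_max"),
                            denominators = NULL) {
  rounding <- match.arg(rounding)
  if (length(controls) == 0L) stop("at least one control required",
                                   call. = FALSE)
  ids <- names(controls)
  stopifnot(!is.null(ids), all(ids %in% names(known)))
  rates <- numeric(0)
  for (id in ids) {
    u <- controls[[id]]
    denom <- if (!is.null(denominators)) denominators[[id]] else
      attr(u, "denominator")
    if (is.null(denom) || denom == 0L) {
      warning("control ", id, " has zero surviving reads; excluded")
      next
    }
    err <- u[toupper(u$seq) != toupper(known[[id]]), , drop = FALSE]
    rate <- if (nrow(err) == 0L) 0 else max(err$count) / denom
    rates[id] <- rate
  }
  if (length(rates) == 0L)
    stop("all controls empty: cannot calibrate error rate", call. = FALSE)
  max_rate <- max(rates)
  threshold <- switch(rounding,
                      ceil_percent = ceiling(max_rate * 100) / 100,
                      raw_max = max_rate)
  out <- list(
    per_control_rate = rates,
    max_rate = max_rate,
    mean_rate = mean(rates),
    sd_rate = if (length(rates) > 1L) stats::sd(rates) else NA_real_,
    threshold = threshold,
    rounding = rounding,
    n_controls = length(rates)
  )
  class(out) <- "error_calibration"
  out
}

#' @export
print.error_calibration <- function(x, ...) {
  cat("Positive-control error calibration (", x$n_controls, " controls)\n",
      sep = "")
  cat(sprintf("  max rate  : %.4f%%\n", 100 * x$max_rate))
  cat(sprintf("  mean rate : %.4f%%  (sd %.4f%%)\n", 100 * x$mean_rate,
              100 * x$sd_rate))
  cat(sprintf("  threshold : %.2f%%  (rule: %s)\n", 100 * x$threshold,
              x$rounding))
  invisible(x)
}

#' Apply the frequency threshold
#'
#' Retains unique sequences whose frequency is at least `threshold`
#' (strictly-less removed); chimera-flagged sequences are removed
#' regardless. Idempotent and monotone in the threshold.
#'
#' @param uniques Dereplicated data.frame; if a `chimera` column is present
#'   flagged rows are dropped.
#' @param threshold Frequency threshold in `[0, 1]`.
#' @return The retained subset of `uniques` (denominator attribute
#'   preserved).
#' @export
apply_threshold <- function(uniques, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- uniques$frequency >= threshold
  if (!is.null(uniques$chimera)) keep <- keep & !uniques$chimera
  out <- uniques[keep, , drop = FALSE]
  attr(out, "denominator") <- attr(uniques, "denominator")
  rownames(out) <- NULL
  out
}
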