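#' @title qPCR relative standard curve quantification
#' @description Fits the relative standard curve from a dilution series and
#'   converts threshold-cycle (Ct) values of unknown wells to DNA
#'   concentrations.
#' @name qpcr
NULL

#' Fit a relative standard curve
#'
#' Ordinary least squares of Ct on log10(concentration) over the standard
#' dilution series. Amplification efficiency is `10^(-1/slope) - 1` (1.0 =
#' perfect doubling per cycle, slope -3.3219).
#'
#' @param standards data.frame with columns `concentration` (ng/ul, > 0) and
#'   `ct` (NA = undetermined).
#' @return Object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_standards`, `valid` (FALSE when the
#'   fitted slope is not negative).
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("concentration", "ct") %in% names(standards)))
  use <- standards$concentration > 0 & !is.na(standards$ct)
  d <- standards[use, , drop = FALSE]
  if (length(unique(d$concentration)) < 3L)
    stop("at least 3 standards with distinct concentrations and ",
         "determined Ct are required", call. = FALSE)
  fit <- stats::lm(ct ~ log10(concentration), data = d)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # noise-free dilution series fit exactly; the perfect-fit warning from
  # summary.lm is expected there and not informative
  r2 <- suppressWarnings(summary(fit)$r.squared)
  valid <- slope < 0
  if (!valid) warning("fitted slope is not negative: invalid curve")
  out <- list(slope = slope, intercept = intercept, r_squared = r2,
              efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
              n_standards = nrow(d), valid = valid)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Relative standard curve (%d standards): Ct = %.4f log10(conc) + %.4f\n",
    x$n_standards, x$slope, x$intercept))
  cat(sprintf("  r^2 = %.4f, efficiency = %.1f%%%s\n", x$r_squared,
              100 * x$efficiency, if (x$valid) "" else "  [INVALID]"))
  invisible(x)
}

#' Quantify unknown wells against a standard curve
#'
#' Replicate wells of the same sample are averaged on the Ct scale over
#' their determined replicates before conversion. A sample is detected when
#' it has a determined mean Ct at or below `detection_cutoff`; detected
#' concentrations are `10^((Ct - intercept)/slope)`. The cohort summary
#' (median, mean, sd, min, max) covers detected non-control samples only.
#'
#' @param ct_table data.frame with columns `sample_id`, `ct` (NA =
#'   undetermined); optional `role` column (rows with role `"standard"` are
#'   ignored, `"negative_control"`/`"field_negative"` rows are excluded from
#'   the summary).
#' @param curve A [fit_standard_curve()] result.
#' @param detection_cutoff Maximum cycle considered detected (default 45).
#' @return data.frame (`sample_id, ct, concentration, detected`) with a
#'   `"summary"` attribute (named numeric vector).
#' @export
quantify <- function(ct_table, curve, detection_cutoff = 45) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("invalid standard curve", call. = FALSE)
  if (!is.null(ct_table$role)) {
    ct_table <- ct_table[ct_table$role != "standard", , drop = FALSE]
  }
  ids <- unique(ct_table$sample_id)
  ct <- vapply(ids, function(s) {
    v <- ct_table$ct[ct_table$sample_id == s]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  detected <- !is.na(ct) & ct <= detection_cutoff
  conc <- rep(NA_real_, length(ids))
  conc[detected] <- 10^((ct[detected] - curve$intercept) / curve$slope)
  out <- data.frame(sample_id = ids, ct = ct, concentration = conc,
                    detected = detected, stringsAsFactors = FALSE,
                    row.names = NULL)
  in_summary <- detected
  if (!is.null(ct_table$role)) {
    role <- ct_table$role[match(ids, ct_table$sample_id)]
    in_summary <- detected & !(role %in% c("negative_control",
                                           "field_negative"))
  }
  v <- conc[in_summary]
  attr(out, "summary") <- c(
    n_detected = sum(in_summary),
    median = if (length(v)) stats::median(v) else NA_real_,
    mean = if (length(v)) mean(v) else NA_real_,
    sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
    min = if (length(v)) min(v) else NA_real_,
    max = if (length(v)) max(v) else NA_real_
  )
  out
}
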