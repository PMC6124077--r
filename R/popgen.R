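#' @title Population differentiation
#' @description Haplotype-by-stratum frequency tables and differentiation
#'   statistics: AMOVA-based Phi-ST and the chi-squared homogeneity test,
#'   both with permutation p-values.
#' @name popgen
NULL

#' Build a strata dataset
#'
#' One observation per accepted haplotype call (so a two-haplotype sample
#' contributes two observations, each reflecting a distinct contributing
#' animal), with the stratum label of its sample and the aligned haplotype
#' sequences used for the distance model.
#'
#' @param observations data.frame with columns `sample_id, haplotype_id,
#'   stratum`.
#' @param sequences Named character vector: haplotype id -> aligned
#'   sequence; equal lengths, every observed haplotype present.
#' @return An object of class `strata_dataset`.
#' @export
strata_dataset <- function(observations, sequences) {
  stopifnot(all(c("sample_id", "haplotype_id", "stratum") %in%
                  names(observations)))
  obs <- observations[!is.na(observations$stratum), , drop = FALSE]
  miss <- setdiff(unique(obs$haplotype_id), names(sequences))
  if (length(miss) > 0L)
    stop("haplotypes without sequences: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("haplotype sequences must be aligned to equal length", call. = FALSE)
  out <- list(observations = obs, sequences = sequences)
  class(out) <- "strata_dataset"
  out
}

#' Pairwise nucleotide-difference matrix between observations
#'
#' `d[i, j]` is the number of differing sites between the haplotype
#' sequences of observations `i` and `j` (0 on the diagonal, symmetric).
#'
#' @param dataset A [strata_dataset()].
#' @return Integer matrix, one row/column per observation.
#' @export
pairwise_distance_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "strata_dataset"))
  haps <- names(dataset$sequences)
  dh <- hamming_matrix_cpp(unname(dataset$sequences))
  idx <- match(dataset$observations$haplotype_id, haps)
  dh[idx, idx, drop = FALSE]
}

# AMOVA variance components and Phi-ST from a squared-distance matrix and
# integer stratum labels. Returns NULL phi when monomorphic.
phi_components <- function(d2, labels) {
  N <- nrow(d2)
  groups <- unique(labels)
  K <- length(groups)
  ss_total <- sum(d2) / (2 * N)
  ss_within <- 0
  nk <- integer(K)
  for (g in seq_len(K)) {
    idx <- labels == groups[g]
    nk[g] <- sum(idx)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * nk[g])
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (K - 1)
  ms_within <- if (N - K > 0) ss_within / (N - K) else 0
  n_prime <- (N - sum(nk^2) / N) / (K - 1)
  sigma2_w <- ms_within
  sigma2_a <- (ms_among - ms_within) / n_prime
  denom <- sigma2_a + sigma2_w
  phi <- if (denom > 0) sigma2_a / denom else NA_real_
  list(phi = phi, sigma2_a = sigma2_a, sigma2_w = sigma2_w,
       ss_total = ss_total, ss_within = ss_within, ss_among = ss_among)
}

check_strata <- function(ds) {
  labs <- ds$observations$stratum
  if (length(unique(labs)) < 2L)
    stop("at least two strata are required", call. = FALSE)
  if (length(labs) < 3L)
    stop("at least three observations are required", call. = FALSE)
  labs
}

#' AMOVA Phi-ST with permutation test
#'
#' Partitions squared pairwise nucleotide distances within and among strata
#' (analysis of molecular variance). With `SS_total = (1/N) sum_{i<j} d2`,
#' `SS_within = sum_k (1/n_k) sum_{i<j in k} d2`,
#' `MS_among = SS_among/(K-1)`, `MS_within = SS_within/(N-K)` and
#' `n' = (N - sum n_k^2 / N)/(K-1)`, the components are
#' `sigma2_w = MS_within`, `sigma2_a = (MS_among - MS_within)/n'` and
#' `Phi_ST = sigma2_a / (sigma2_a + sigma2_w)`. The permutation p-value
#' shuffles stratum labels over observations with a seeded generator and
#' includes the observed statistic: `p = (1 + #{perm >= obs})/(n_perm + 1)`.
#'
#' @param dataset A [strata_dataset()].
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation generator (required).
#' @return An object of class `diff_result` with fields `phi_st`, `phi_p`,
#'   `sigma2_a`, `sigma2_w`, `status` (`"ok"` or `"monomorphic"`),
#'   `n_perm`, `seed`.
#' @export
phi_st <- function(dataset, n_perm = 1000, seed) {
  labs <- check_strata(dataset)
  d <- pairwise_distance_matrix(dataset)
  d2 <- d^2
  if (all(d2 == 0)) {
    out <- list(phi_st = 0, phi_p = 1, sigma2_a = 0, sigma2_w = 0,
                status = "monomorphic", n_perm = n_perm, seed = seed)
    class(out) <- "diff_result"
    return(out)
  }
  obs <- phi_components(d2, labs)
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      p <- phi_components(d2, sample(labs))
      if (!is.na(p$phi) && p$phi >= obs$phi - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  out <- list(phi_st = obs$phi, phi_p = (1 + count) / (n_perm + 1),
              sigma2_a = obs$sigma2_a, sigma2_w = obs$sigma2_w,
              status = "ok", n_perm = n_perm, seed = seed)
  class(out) <- "diff_result"
  out
}

chi2_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- E > 0
  sum((tab[use] - E[use])^2 / E[use])
}

#' Chi-squared haplotype-frequency homogeneity test with permutation p-value
#'
#' Builds the haplotype-by-stratum contingency table and computes the
#' classical chi-squared statistic over cells with positive expectation. The
#' asymptotic p-value uses `(H-1)(K-1)` degrees of freedom; the permutation
#' p-value shuffles stratum labels as in [phi_st()].
#'
#' @inheritParams phi_st
#' @return An object of class `diff_result` with fields `chi2`,
#'   `chi2_p_perm`, `chi2_p_asymptotic`, `df`, `table`, `n_perm`, `seed`.
#' @export
chi2_test <- function(dataset, n_perm = 1000, seed) {
  labs <- check_strata(dataset)
  haps <- dataset$observations$haplotype_id
  if (length(unique(haps)) < 2L)
    stop("chi-squared test undefined with a single haplotype", call. = FALSE)
  tab <- table(haps, labs)
  stat <- chi2_stat(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p_asym <- stats::pchisq(stat, df, lower.tail = FALSE)
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (chi2_stat(table(haps, sample(labs))) >= stat - 1e-12)
        cnt <- cnt + 1L
    }
    cnt
  })
  out <- list(chi2 = stat, chi2_p_perm = (1 + count) / (n_perm + 1),
              chi2_p_asymptotic = p_asym, df = df, table = tab,
              n_perm = n_perm, seed = seed)
  class(out) <- "diff_result"
  out
}

#' @export
print.diff_result <- function(x, ...) {
  if (!is.null(x$phi_st)) {
    cat(sprintf("Phi_ST = %.4f (perm p = %.4g, %d permutations, %s)\n",
                x$phi_st, x$phi_p, x$n_perm, x$status))
    cat(sprintf("  sigma2_among = %.4f, sigma2_within = %.4f\n",
                x$sigma2_a, x$sigma2_w))
  }
  if (!is.null(x$chi2)) {
    cat(sprintf("chi2 = %.4f (df = %d, perm p = %.4g, asymptotic p = %.4g)\n",
                x$chi2, x$df, x$chi2_p_perm, x$chi2_p_asymptotic))
  }
  invisible(x)
}

#' Simulate haplotype observations across strata
#'
#' Draws observations i.i.d. from per-stratum haplotype frequency vectors —
#' a fast observation-level generator for studying the behaviour of the
#' differentiation tests without simulating reads.
#'
#' @param freqs Matrix, one row per stratum, one column per haplotype;
#'   rows sum to 1.
#' @param n_per_stratum Observations per stratum (recycled).
#' @param sequences Named character vector of haplotype sequences (column
#'   order of `freqs`).
#' @return A [strata_dataset()].
#' @export
simulate_haplotype_observations <- function(freqs, n_per_stratum,
                                            sequences) {
  stopifnot(ncol(freqs) == length(sequences))
  n_per_stratum <- rep_len(n_per_stratum, nrow(freqs))
  strata <- rownames(freqs)
  if (is.null(strata)) strata <- paste0("stratum", seq_len(nrow(freqs)))
  obs <- do.call(rbind, lapply(seq_len(nrow(freqs)), function(k) {
    haps <- sample(names(sequences), n_per_stratum[k], replace = TRUE,
                   prob = freqs[k, ])
    data.frame(sample_id = sprintf("%s_%03d", strata[k],
                                   seq_len(n_per_stratum[k])),
               haplotype_id = haps, stratum = strata[k],
               stringsAsFactors = FALSE)
  }))
  strata_dataset(obs, sequences)
}
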