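# Independent brute-force oracles used to cross-check the compiled kernels
# and the AMOVA/chi-squared statistics. All are deliberately naive: plain R
# loops written from the definitions, never calling the implementation under
# test.

rc_oracle <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

qstr <- function(q, len) strrep(intToUtf8(q + 33L), len)

# quality trim: try every cut point p (keep 1..p), keep the largest p that
# maximises sum_{i>p}(thr - q_i)
oracle_trim_len <- function(qual, thr) {
  q <- utf8ToInt(qual) - 33L
  L <- length(q)
  sums <- vapply(0:L, function(p) {
    if (p == L) 0 else sum(thr - q[(p + 1):L])
  }, numeric(1))
  max(which(sums == max(sums))) - 1L
}

# merge offset: exhaustive search over all overlaps >= min_overlap of
# score = matches - mismatches (N never a match), ties -> longest overlap.
# s2rc must already be the reverse complement of mate 2.
oracle_merge_offset <- function(s1, s2rc, min_overlap) {
  n1 <- nchar(s1)
  n2 <- nchar(s2rc)
  best <- list(score = -Inf, o = NA_integer_, mm = NA_integer_)
  if (min(n1, n2) < min_overlap) return(best)
  for (o in min_overlap:min(n1, n2)) {
    av <- strsplit(substring(s1, n1 - o + 1, n1), "")[[1]]
    bv <- strsplit(substring(s2rc, 1, o), "")[[1]]
    m <- sum(av == bv & av != "N")
    mm <- o - m
    sc <- m - mm
    if (sc >= best$score) best <- list(score = sc, o = o, mm = mm)
  }
  best
}

# substitute k random positions of a sequence
mutate_some <- function(s, k) {
  if (k == 0) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), min(k, length(v)))
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

hamming_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# chimera flags straight from the definition: descending-abundance pass,
# all ordered parent pairs, all breakpoints
oracle_chimera <- function(seqs, counts, skew = 2, min_diffs = 2) {
  n <- length(seqs)
  flags <- logical(n)
  accepted <- integer(0)
  for (i in seq_len(n)) {
    L <- nchar(seqs[i])
    par <- accepted[counts[accepted] >= skew * counts[i] &
                      nchar(seqs[accepted]) == L]
    fl <- FALSE
    if (length(par) >= 2) {
      for (a in par) {
        for (b in setdiff(par, a)) {
          if (fl) break
          if (hamming_oracle(seqs[i], seqs[a]) < min_diffs) next
          if (hamming_oracle(seqs[i], seqs[b]) < min_diffs) next
          for (p in 1:(L - 1)) {
            cand <- paste0(substr(seqs[a], 1, p), substr(seqs[b], p + 1, L))
            if (cand == seqs[i]) { fl <- TRUE; break }
          }
        }
        if (fl) break
      }
    }
    flags[i] <- fl
    if (!fl) accepted <- c(accepted, i)
  }
  flags
}

# AMOVA Phi-ST from the variance-component definitions, explicit i<j loops
oracle_phi <- function(d, labels) {
  N <- length(labels)
  groups <- unique(labels)
  K <- length(groups)
  ss_tot <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / N
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    nk <- length(idx)
    s <- 0
    if (nk >= 2) {
      for (ii in 1:(nk - 1)) for (jj in (ii + 1):nk)
        s <- s + d[idx[ii], idx[jj]]^2
    }
    ss_w <- ss_w + s / nk
  }
  ms_a <- (ss_tot - ss_w) / (K - 1)
  ms_w <- ss_w / (N - K)
  np <- (N - sum(table(labels)^2) / N) / (K - 1)
  sa <- (ms_a - ms_w) / np
  sa / (sa + ms_w)
}

oracle_chi2 <- function(haps, labels) {
  tab <- table(haps, labels)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(((tab - E)^2 / E)[E > 0])
}

# all permutations of a vector (N <= 8)
all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# exhaustive permutation p-value: proportion of all N! label orders whose
# statistic is >= observed
oracle_perm_p <- function(labels, stat_fn) {
  obs <- stat_fn(labels)
  vals <- vapply(all_perms(labels), stat_fn, numeric(1))
  mean(vals >= obs - 1e-12)
}

# closed-form OLS via normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# a tiny strata dataset builder for popgen tests
make_ds <- function(haps, labels, sequences) {
  strata_dataset(
    data.frame(sample_id = sprintf("s%02d", seq_along(haps)),
               haplotype_id = haps, stratum = labels,
               stringsAsFactors = FALSE),
    sequences)
}
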