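#' @title Read processing
#' @description Adapter/primer trimming, 3' quality trimming, pair merging,
#'   dereplication and length filtering of paired-end amplicon reads.
#' @name readproc
NULL

#' Trim adapters, primers and low-quality 3' tails
#'
#' Each mate is processed independently, in the order adapter -> primer ->
#' quality. Adapter and primer occurrences are removed by simple end
#' matching: a full-length occurrence at the 5' end (pattern as given) or at
#' the 3' end (reverse complement), allowing up to 10% mismatches of the
#' pattern length. Quality trimming uses the BWA-style running-sum rule: the
#' read is cut at the position maximising the partial sum of
#' `(q_threshold - q_i)` taken from the 3' end, which removes a 3' tail
#' whose qualities fall below the threshold. Reads whose quality string does
#' not match the sequence length are dropped and counted.
#'
#' @param seqs,quals Character vectors of sequences and Phred+33 qualities.
#' @param adapters,primers Character vectors of patterns to remove.
#' @param q_threshold Phred quality threshold (default 20).
#' @param max_error_rate Mismatch tolerance for end matching (default 0.1).
#' @return list with `seq`, `qual` (trimmed, same length as input),
#'   `dropped` (logical: malformed records) and `n_dropped`.
#' @export
trim_reads <- function(seqs, quals, adapters = character(0),
                       primers = character(0), q_threshold = 20,
                       max_error_rate = 0.1) {
  stopifnot(length(seqs) == length(quals), q_threshold >= 0)
  if (length(seqs) == 0L) {
    return(list(seq = character(0), qual = character(0),
                dropped = logical(0), n_dropped = 0L))
  }
  malformed <- nchar(seqs) != nchar(quals) | is.na(seqs) | is.na(quals)
  if (any(malformed)) {
    warning(sum(malformed), " read(s) with malformed quality strings dropped")
  }
  out_seq <- seqs
  out_qual <- quals
  ok <- which(!malformed)
  s <- seqs[ok]
  q <- quals[ok]
  for (patset in list(adapters, primers)) {
    if (length(patset) > 0L && length(s) > 0L) {
      tr <- trim_end_patterns_cpp(s, q, patset, max_error_rate)
      s <- tr$seq
      q <- tr$qual
    }
  }
  if (length(s) > 0L) {
    keep_len <- quality_trim_length_cpp(q, as.integer(q_threshold))
    s <- substr(s, 1L, keep_len)
    q <- substr(q, 1L, keep_len)
  }
  out_seq[ok] <- s
  out_qual[ok] <- q
  out_seq[malformed] <- NA_character_
  out_qual[malformed] <- NA_character_
  list(seq = out_seq, qual = out_qual, dropped = malformed,
       n_dropped = sum(malformed))
}

#' Merge paired-end reads
#'
#' Mate 2 is reverse-complemented and all overlaps of at least `min_overlap`
#' bases are scored as `matches - mismatches` (an `N` never counts as a
#' match). The best-scoring overlap wins, ties going to the longest overlap.
#' A pair is rejected when no admissible overlap exists or when the best
#' overlap's mismatch fraction exceeds `max_mismatch_frac`. At a mismatch
#' the higher-quality base is kept; merged quality is the maximum of the two
#' at matches and the absolute difference at mismatches.
#'
#' @param reads Read data.frame (`id, seq1, qual1, seq2, qual2`), e.g. from
#'   [read_fastq_pair()] after [trim_reads()].
#' @param min_overlap Minimum acceptable overlap in bp (default 50).
#' @param max_mismatch_frac Maximum mismatch fraction in the chosen overlap.
#' @return list with `merged` (data.frame `id, seq, qual, overlap_len,
#'   mismatches_in_overlap`), `n_rejected`, and `status` per input pair
#'   (`"merged"`, `"no_overlap"`, `"too_many_mismatches"`).
#' @export
merge_pairs <- function(reads, min_overlap = 50, max_mismatch_frac = 0.1) {
  stopifnot(min_overlap >= 1)
  if (nrow(reads) == 0L) {
    return(list(
      merged = data.frame(id = character(0), seq = character(0),
                          qual = character(0), overlap_len = integer(0),
                          mismatches_in_overlap = integer(0),
                          stringsAsFactors = FALSE),
      n_rejected = 0L, status = character(0)))
  }
  nonempty <- nchar(reads$seq1) > 0L & nchar(reads$seq2) > 0L
  res <- merge_pairs_cpp(reads$seq1[nonempty], reads$qual1[nonempty],
                         reads$seq2[nonempty], reads$qual2[nonempty],
                         as.integer(min_overlap), max_mismatch_frac)
  status <- rep("no_overlap", nrow(reads))
  st <- c("merged", "no_overlap", "too_many_mismatches")[res$status + 1L]
  status[nonempty] <- st
  keep <- which(nonempty)[st == "merged"]
  idx <- which(st == "merged")
  merged <- data.frame(
    id = reads$id[keep],
    seq = res$seq[idx],
    qual = res$qual[idx],
    overlap_len = res$overlap_len[idx],
    mismatches_in_overlap = res$mismatches_in_overlap[idx],
    stringsAsFactors = FALSE
  )
  list(merged = merged, n_rejected = nrow(reads) - nrow(merged),
       status = status)
}

#' Dereplicate merged reads
#'
#' Upper-cases, drops sequences shorter than `min_length`, then groups
#' identical strings. Frequencies are relative to the number of reads
#' surviving the length filter (the denominator). Output is sorted by count
#' descending, ties broken lexicographically by sequence.
#'
#' @param seqs Character vector of merged sequences.
#' @param min_length Minimum sequence length retained (default 379).
#' @param sample_id Optional sample label attached to the output.
#' @return data.frame (`seq, count, frequency, sample_id`) with attribute
#'   `"denominator"` = reads surviving the length filter.
#' @export
dereplicate <- function(seqs, min_length = 379, sample_id = NA_character_) {
  seqs <- toupper(seqs)
  seqs <- seqs[nchar(seqs) >= min_length]
  denom <- length(seqs)
  if (denom == 0L) {
    out <- data.frame(seq = character(0), count = integer(0),
                      frequency = numeric(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "denominator") <- 0L
    return(out)
  }
  tab <- table(seqs)
  cnt <- as.integer(tab)
  sq <- names(tab)
  ord <- order(-cnt, sq, method = "radix")
  out <- data.frame(seq = sq[ord], count = cnt[ord],
                    frequency = cnt[ord] / denom,
                    sample_id = sample_id, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "denominator") <- denom
  out
}

#' Process one sample: trim, merge, dereplicate
#'
#' Runs the full read-processing stage for one sample and keeps the
#' stagewise accounting needed downstream (the read-conservation invariant
#' `reads_in = merged + merge_rejected + trim_dropped` holds exactly).
#'
#' @param reads Read data.frame (`id, seq1, qual1, seq2, qual2`).
#' @param primers Primer sequences to trim (forward and reverse).
#' @param adapters Adapter sequences to trim.
#' @param q_threshold Phred quality threshold.
#' @param min_overlap Minimum merge overlap (bp).
#' @param max_mismatch_frac Maximum mismatch fraction in the merge overlap.
#' @param min_length Minimum merged length retained (bp).
#' @param sample_id Sample label.
#' @return list with `uniques` (dereplicated data.frame), `denominator`
#'   (reads surviving merge + length filter), and `report` (named counts:
#'   `n_input, n_trim_dropped, n_merged, n_merge_rejected,
#'   n_length_filtered, denominator`).
#' @export
process_sample <- function(reads, primers = character(0),
                           adapters = character(0), q_threshold = 20,
                           min_overlap = 50, max_mismatch_frac = 0.1,
                           min_length = 379, sample_id = NA_character_) {
  n_input <- nrow(reads)
  t1 <- trim_reads(reads$seq1, reads$qual1, adapters, primers, q_threshold)
  t2 <- trim_reads(reads$seq2, reads$qual2, adapters, primers, q_threshold)
  dropped <- t1$dropped | t2$dropped |
    nchar(ifelse(is.na(t1$seq), "", t1$seq)) == 0L |
    nchar(ifelse(is.na(t2$seq), "", t2$seq)) == 0L
  if (n_input > 0L) {
    trimmed <- data.frame(id = reads$id, seq1 = t1$seq, qual1 = t1$qual,
                          seq2 = t2$seq, qual2 = t2$qual,
                          stringsAsFactors = FALSE)[!dropped, , drop = FALSE]
  } else {
    trimmed <- reads
    dropped <- logical(0)
  }
  m <- merge_pairs(trimmed, min_overlap, max_mismatch_frac)
  uniques <- dereplicate(m$merged$seq, min_length, sample_id)
  denom <- attr(uniques, "denominator")
  report <- list(
    n_input = n_input,
    n_trim_dropped = sum(dropped),
    n_merged = nrow(m$merged),
    n_merge_rejected = m$n_rejected,
    n_length_filtered = nrow(m$merged) - denom,
    denominator = denom
  )
  list(uniques = uniques, denominator = denom, report = report)
}

#' Read-depth criterion for sample inclusion
#'
#' A sample whose surviving dereplicated read depth is an atypically small
#' fraction of its merged-pair contigs is excluded: at such depth even a
#' high-identity consensus may be sequencing error. The bound is 1% of
#' merged contigs; e.g. 510 dereplicated reads out of 221,922 contigs
#' (0.23%) fails.
#'
#' @param n_dereplicated Reads surviving dereplication (the denominator).
#' @param n_contigs Merged-pair contigs for the sample.
#' @param min_fraction Minimum acceptable fraction (default 0.01).
#' @return `TRUE` if the sample passes the criterion.
#' @export
depth_criterion_ok <- function(n_dereplicated, n_contigs,
                               min_fraction = 0.01) {
  if (n_contigs <= 0) return(FALSE)
  n_dereplicated / n_contigs >= min_fraction
}
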