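#' @title Haplotype calling
#' @description Assignment of retained unique sequences to a reference
#'   haplotype database, with novel- and secondary-haplotype rules.
#' @name hapcall
NULL

#' Best reference hit by global pairwise alignment
#'
#' Aligns the query globally (match +1, mismatch -1, gap open -2, gap extend
#' -1) against every reference sequence and its reverse complement, and
#' returns the maximum-identity hit; identity is matches divided by
#' alignment columns. Ties go to the lexicographically smallest haplotype
#' id. Reverse-complement hits are reported in forward reference
#' orientation.
#'
#' @param query Query sequence (character scalar).
#' @param db Named character vector of reference haplotypes.
#' @return list with `haplotype_id`, `identity`, `aligned_length`.
#' @export
best_reference_hit <- function(query, db) {
  if (length(db) == 0L) stop("empty reference database", call. = FALSE)
  db <- db[order(names(db), method = "radix")]
  query <- toupper(query)
  exact <- match(query, toupper(unname(db)))
  if (!is.na(exact)) {
    return(list(haplotype_id = names(db)[exact], identity = 1.0,
                aligned_length = nchar(query)))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  refs <- Biostrings::DNAStringSet(unname(db))
  best_id <- NA_character_
  best_ident <- -1
  best_len <- NA_integer_
  for (orient in 1:2) {
    pat <- if (orient == 1L) refs else Biostrings::reverseComplement(refs)
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = Biostrings::DNAString(query),
      type = "global", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- Biostrings::nmatch(aln) / cols
    k <- which.max(ident)  # db already id-sorted; first max = smallest id
    if (ident[k] > best_ident + 1e-12) {
      best_ident <- ident[k]
      best_id <- names(db)[k]
      best_len <- cols[k]
    }
  }
  list(haplotype_id = best_id, identity = best_ident,
       aligned_length = best_len)
}

empty_calls <- function() {
  data.frame(sample_id = character(0), haplotype_id = character(0),
             status = character(0), best_hit_id = character(0),
             identity = numeric(0), read_count = integer(0),
             fraction_of_processed_reads = numeric(0), rank = character(0),
             seq = character(0), stringsAsFactors = FALSE)
}

#' Call haplotypes for one sample
#'
#' Applies the decision rules to already threshold-filtered unique
#' sequences: an exact match to a reference is a known haplotype; a
#' non-exact sequence with identity at least `nontarget_identity_floor` is a
#' novel haplotype when supported by at least `novel_min_fraction` of
#' processed reads (the >20% secondary-haplotype evidence rule, applied
#' symmetrically to primaries) and otherwise rejected as low-fraction;
#' identity below the floor is rejected as non-target. A sample with no
#' accepted call yields a single `failed_sample` record. The most abundant
#' accepted call is ranked primary, any others secondary.
#'
#' @param retained Data.frame from [apply_threshold()] (columns `seq, count,
#'   frequency`), sorted by count descending.
#' @param db Named character vector of reference haplotypes.
#' @param novel_min_fraction Minimum read fraction supporting a novel
#'   haplotype (default 0.20).
#' @param nontarget_identity_floor Identity below which a sequence is
#'   considered non-target (default 0.98).
#' @param sample_id Sample label.
#' @return data.frame of haplotype calls (one row per retained sequence,
#'   or one `failed_sample` row).
#' @export
call_sample <- function(retained, db, novel_min_fraction = 0.20,
                        nontarget_identity_floor = 0.98,
                        sample_id = NA_character_) {
  if (length(db) == 0L) stop("empty reference database", call. = FALSE)
  if (nrow(retained) == 0L) {
    out <- data.frame(sample_id = sample_id, haplotype_id = NA_character_,
                      status = "failed_sample", best_hit_id = NA_character_,
                      identity = NA_real_, read_count = 0L,
                      fraction_of_processed_reads = 0,
                      rank = NA_character_, seq = NA_character_,
                      stringsAsFactors = FALSE)
    return(out)
  }
  retained <- retained[order(-retained$count, retained$seq,
                             method = "radix"), , drop = FALSE]
  n <- nrow(retained)
  rows <- vector("list", n)
  novel_n <- 0L
  for (i in seq_len(n)) {
    hit <- best_reference_hit(retained$seq[i], db)
    ident <- hit$identity
    if (ident >= 1) {
      status <- "known"
      hap <- hit$haplotype_id
    } else if (ident >= nontarget_identity_floor) {
      if (retained$frequency[i] >= novel_min_fraction) {
        status <- "novel"
        novel_n <- novel_n + 1L
        hap <- sprintf("novel-%d", novel_n)
      } else {
        status <- "rejected_low_fraction"
        hap <- NA_character_
      }
    } else {
      status <- "rejected_nontarget"
      hap <- NA_character_
    }
    rows[[i]] <- data.frame(
      sample_id = sample_id, haplotype_id = hap, status = status,
      best_hit_id = hit$haplotype_id, identity = ident,
      read_count = retained$count[i],
      fraction_of_processed_reads = retained$frequency[i],
      rank = NA_character_, seq = retained$seq[i],
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  accepted <- calls$status %in% c("known", "novel")
  if (!any(accepted)) {
    fail <- calls[1L, , drop = FALSE]
    fail$haplotype_id <- NA_character_
    fail$status <- "failed_sample"
    fail$rank <- NA_character_
    rownames(fail) <- NULL
    return(fail)
  }
  acc_idx <- which(accepted)
  calls$rank[acc_idx[1L]] <- "primary"   # most abundant accepted
  if (length(acc_idx) > 1L) calls$rank[acc_idx[-1L]] <- "secondary"
  rownames(calls) <- NULL
  calls
}

#' Call haplotypes across a cohort
#'
#' Runs [call_sample()] per sample and harmonises provisional novel ids
#' across the cohort: identical novel sequences share one id, assigned
#' `novel-1`, `novel-2`, ... in order of first appearance (sample order,
#' then descending abundance). Deterministic given the inputs.
#'
#' @param retained_by_sample Named list of threshold-filtered unique
#'   data.frames, one per sample.
#' @param db Named character vector of reference haplotypes.
#' @param novel_min_fraction,nontarget_identity_floor See [call_sample()].
#' @return list with `calls` (one cohort-level data.frame) and
#'   `novel_sequences` (named character vector of novel haplotype
#'   sequences).
#' @export
call_cohort <- function(retained_by_sample, db, novel_min_fraction = 0.20,
                        nontarget_identity_floor = 0.98) {
  per <- lapply(names(retained_by_sample), function(sid) {
    call_sample(retained_by_sample[[sid]], db, novel_min_fraction,
                nontarget_identity_floor, sample_id = sid)
  })
  calls <- do.call(rbind, per)
  novel_reg <- character(0)
  for (i in seq_len(nrow(calls))) {
    if (identical(calls$status[i], "novel")) {
      s <- calls$seq[i]
      j <- match(s, novel_reg)
      if (is.na(j)) {
        novel_reg <- c(novel_reg, s)
        j <- length(novel_reg)
      }
      calls$haplotype_id[i] <- sprintf("novel-%d", j)
    }
  }
  names(novel_reg) <- sprintf("novel-%d", seq_along(novel_reg))
  rownames(calls) <- NULL
  list(calls = calls, novel_sequences = novel_reg)
}
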