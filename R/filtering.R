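#' Mean PHRED quality of each record
#'
#' Arithmetic mean of the integer per-base PHRED scores (the convention of
#' classic mean-quality read filters), not a probability-domain mean.
#'
#' @param records a [seq_records()] data frame with qualities.
#' @return A numeric vector, one mean per record.
#' @export
mean_phred <- function(records) {
  if (!all(has_quals(records))) {
    stop("mean_phred() requires per-base qualities on every record")
  }
  vapply(records$quals, mean, numeric(1))
}

#' Mean-quality read filter
#'
#' Removes every read whose mean PHRED score is strictly below the
#' threshold; reads exactly at the threshold are kept.
#'
#' @param records a [seq_records()] data frame with qualities.
#' @param min_mean_q threshold in `[0, 93]`.
#' @return A list with elements `kept` and `removed`, a partition of the
#'   input.
#' @export
quality_filter <- function(records, min_mean_q) {
  stopifnot(min_mean_q >= 0, min_mean_q <= 93)
  if (nrow(records) == 0L) return(list(kept = records, removed = records))
  keep <- mean_phred(records) >= min_mean_q
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Demultiplex reads by barcode prefix
#'
#' Assigns each read to the sample whose barcode is an exact prefix of its
#' bases; when several barcodes match, the longest wins. Reads matching no
#' barcode go to the `undetermined` bin. Nothing is trimmed here (see
#' [trim_extras()]).
#'
#' @param records a [seq_records()] data frame.
#' @param table a primer table from [read_primer_table()] with barcodes.
#' @return A named list of record sets, one per sample plus
#'   `undetermined`.
#' @export
demultiplex <- function(records, table) {
  rows <- table[!is.na(table$barcode), , drop = FALSE]
  if (nrow(rows) == 0L) stop("primer table contains no barcodes")
  rows <- rows[order(-nchar(rows$barcode)), , drop = FALSE]  # longest match wins
  assign1 <- function(bases) {
    for (i in seq_len(nrow(rows))) {
      if (startsWith(bases, rows$barcode[i])) return(rows$sample[i])
    }
    "undetermined"
  }
  sample <- vapply(records$bases, assign1, character(1), USE.NAMES = FALSE)
  out <- lapply(c(table$sample, "undetermined"), function(s) {
    records[sample == s, , drop = FALSE]
  })
  stats::setNames(out, c(table$sample, "undetermined"))
}

#' Reverse complement
#'
#' @param bases a sequence string over `A`,`C`,`G`,`T`,`N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(bases) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

#' Trim barcodes and primers from reads
#'
#' Removes, from the 5' end, the sample barcode and then the forward
#' primer (matched in place with at most `mismatches` Hamming mismatches),
#' and from the 3' end the reverse complement of the reverse primer, if
#' configured. When a side is given as a trim length instead of a
#' sequence, that many bases are removed unconditionally. Qualities are
#' trimmed in lockstep. Reads whose expected barcode or primer is not
#' found within the mismatch budget are routed to the `rejected` stream
#' with a `reason` tag, never silently passed through.
#'
#' @param records a [seq_records()] data frame (one demultiplexed sample).
#' @param row a single row of a [read_primer_table()] result.
#' @param mismatches allowed Hamming mismatches for sequence-based primer
#'   and barcode matching (default 0).
#' @return A list with elements `kept` (trimmed records) and `rejected`.
#' @export
trim_extras <- function(records, row, mismatches = 0L) {
  stopifnot(nrow(row) == 1L)
  kept_idx <- logical(nrow(records))
  reason <- character(nrow(records))
  out <- records
  hamming_prefix_ok <- function(s, pat) {
    nchar(s) >= nchar(pat) &&
      sum(strsplit(substr(s, 1, nchar(pat)), "")[[1]] !=
            strsplit(pat, "")[[1]]) <= mismatches
  }
  for (i in seq_len(nrow(records))) {
    s <- records$bases[i]
    q <- records$quals[[i]]
    cut5 <- 0L; cut3 <- 0L; ok <- TRUE
    for (pat in c(row$barcode, row$fprimer_seq)) {
      if (is.na(pat)) next
      rest <- substr(s, cut5 + 1L, nchar(s))
      if (!hamming_prefix_ok(rest, pat)) {
        ok <- FALSE
        reason[i] <- "5prime_not_found"
        break
      }
      cut5 <- cut5 + nchar(pat)
    }
    if (ok && !is.na(row$fprimer_len)) cut5 <- cut5 + row$fprimer_len
    if (ok && !is.na(row$rprimer_seq)) {
      tail_pat <- revcomp(row$rprimer_seq)
      tl <- nchar(tail_pat)
      body <- substr(s, cut5 + 1L, nchar(s))
      tail_s <- substr(body, nchar(body) - tl + 1L, nchar(body))
      if (nchar(body) < tl ||
          sum(strsplit(tail_s, "")[[1]] != strsplit(tail_pat, "")[[1]]) > mismatches) {
        ok <- FALSE
        reason[i] <- "3prime_not_found"
      } else {
        cut3 <- tl
      }
    }
    if (ok && !is.na(row$rprimer_len)) cut3 <- cut3 + row$rprimer_len
    if (ok && cut5 + cut3 > nchar(s)) {
      ok <- FALSE
      reason[i] <- "read_shorter_than_trim"
    }
    if (ok) {
      out$bases[i] <- substr(s, cut5 + 1L, nchar(s) - cut3)
      if (!is.null(q)) out$quals[[i]] <- q[seq.int(cut5 + 1L, length.out = nchar(s) - cut5 - cut3)]
      kept_idx[i] <- TRUE
    }
  }
  rejected <- records[!kept_idx, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$tags <- lapply(seq_len(nrow(rejected)), function(j) {
      c(rejected$tags[[j]], paste0("rejected:", reason[!kept_idx][j]))
    })
  }
  list(kept = out[kept_idx, , drop = FALSE], rejected = rejected)
}

#' Remove constraint-violating reads
#'
#' The input-filter mode of constraint handling: reads with any rule
#' violation are removed, so downstream decoding sees only sequences the
#' code could have produced. Removed records are tagged with the violated
#' rule names.
#'
#' @param records a [seq_records()] data frame.
#' @param cs a [constraint_set()].
#' @return A list with elements `kept` and `removed`, a partition of the
#'   input.
#' @export
constraint_filter <- function(records, cs) {
  if (nrow(records) == 0L) return(list(kept = records, removed = records))
  reasons <- lapply(records$bases, function(b) unique(find_violations(b, cs)$rule))
  keep <- lengths(reasons) == 0L
  removed <- records[!keep, , drop = FALSE]
  if (nrow(removed)) {
    rr <- reasons[!keep]
    removed$tags <- lapply(seq_len(nrow(removed)), function(j) {
      c(removed$tags[[j]], paste0("violates:", rr[[j]]))
    })
  }
  list(kept = records[keep, , drop = FALSE], removed = removed)
}

#' Sort reads by constraint compliance and quality
#'
#' The sort mode of constraint handling: nothing is removed; records are
#' ordered so that decoders that consume sequences in order (e.g. fountain
#' code decoders) read compliant, high-quality sequences first. The sort
#' key is `violation_penalty - lambda * mean_phred / 93`, ascending; ties
#' are broken by abundance (descending) then id (ascending). Records
#' without qualities contribute 0 for the quality term.
#'
#' @param records a [seq_records()] data frame.
#' @param cs a [constraint_set()].
#' @param lambda non-negative weight of the (normalized) mean quality in
#'   the key (default 1).
#' @return The input records, permuted.
#' @export
constraint_sort <- function(records, cs, lambda = 1) {
  stopifnot(lambda >= 0)
  if (nrow(records) == 0L) return(records)
  pen <- vapply(records$bases, violation_penalty, numeric(1), cs = cs,
                USE.NAMES = FALSE)
  mq <- vapply(records$quals, function(q) if (is.null(q)) 0 else mean(q),
               numeric(1))
  key <- pen - lambda * mq / 93
  records[order(key, -records$abundance, records$id), , drop = FALSE]
}
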