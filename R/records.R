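#' Sequence record sets
#'
#' A `seq_records` object is a data frame with one row per read and columns
#' `id` (character), `bases` (character over `A`,`C`,`G`,`T`,`N`), `quals`
#' (list column of integer PHRED vectors, or `NULL` entries for FASTA
#' input), `abundance` (positive integer, default 1) and `tags` (list column
#' of character processing flags such as `"repaired:2"`).
#'
#' @param id character vector of read identifiers.
#' @param bases character vector of sequences over `A`,`C`,`G`,`T`,`N`.
#' @param quals list of integer PHRED vectors (one per read, each the same
#'   length as its sequence, values in 0..93), or `NULL` for quality-less
#'   records.
#' @param abundance integer vector of per-record abundances (recycled).
#' @param tags list of character vectors of processing flags (recycled).
#' @return A `seq_records` data frame.
#' @examples
#' seq_records("r1", "ACGT", quals = list(c(40L, 40L, 38L, 12L)))
#' @export
seq_records <- function(id, bases, quals = NULL, abundance = 1L, tags = list(character())) {
  n <- length(bases)
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  if (length(id) != n) stop("id and bases must have the same length")
  if (is.null(quals)) quals <- rep(list(NULL), n)
  if (!is.list(quals)) stop("quals must be a list of integer vectors or NULL")
  quals <- lapply(quals, function(q) if (is.null(q)) NULL else as.integer(q))
  abundance <- rep_len(as.integer(abundance), n)
  if (!is.list(tags)) tags <- list(tags)
  tags <- rep_len(tags, n)
  x <- data.frame(id = id, bases = bases, abundance = abundance,
                  stringsAsFactors = FALSE)
  x$quals <- quals
  x$tags <- tags
  class(x) <- c("seq_records", "data.frame")
  validate_seq_records(x)
}

#' Validate a seq_records object
#'
#' Checks the container invariants: alphabet, quality/base length agreement,
#' quality range 0..93, and positive abundance.
#'
#' @param x a `seq_records` data frame.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_seq_records <- function(x) {
  stopifnot(is.data.frame(x))
  bad <- grepl("[^ACGTN]", x$bases)
  if (any(bad)) {
    stop("record ", which(bad)[1], " ('", x$id[which(bad)[1]],
         "') contains characters outside {A,C,G,T,N}")
  }
  if (any(x$abundance < 1L)) stop("abundance must be >= 1")
  for (i in seq_len(nrow(x))) {
    q <- x$quals[[i]]
    if (is.null(q)) next
    if (length(q) != nchar(x$bases[i])) {
      stop("record ", i, " ('", x$id[i], "'): quality length ", length(q),
           " does not match sequence length ", nchar(x$bases[i]))
    }
    if (anyNA(q) || any(q < 0L) || any(q > 93L)) {
      stop("record ", i, " ('", x$id[i], "'): PHRED scores must be in [0, 93]")
    }
  }
  x
}

#' @export
print.seq_records <- function(x, ...) {
  cat("<seq_records> ", nrow(x), " record(s), total abundance ",
      sum(x$abundance), "\n", sep = "")
  show <- utils::head(x, 10L)
  for (i in seq_len(nrow(show))) {
    q <- show$quals[[i]]
    cat(sprintf("  %s  %s%s  size=%d%s\n", show$id[i],
                substr(show$bases[i], 1, 40),
                if (nchar(show$bases[i]) > 40) "..." else "",
                show$abundance[i],
                if (is.null(q)) "" else sprintf("  meanQ=%.1f", mean(q))))
  }
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

has_quals <- function(x) vapply(x$quals, Negate(is.null), logical(1))

# rbind that preserves the seq_records class and list columns
bind_records <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (length(parts) == 0) return(empty_records())
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

empty_records <- function() {
  seq_records(character(), character(), quals = list())
}
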