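#' Read a FASTQ file into a record set
#'
#' Parses 4-line FASTQ records with Sanger (+33) quality encoding. Record
#' ids are taken from the header up to the first whitespace. Each record is
#' validated; a malformed record (missing `+` separator, quality line whose
#' length differs from the sequence line, truncated final record) raises an
#' error naming the record index.
#'
#' @param path path to a FASTQ file (plain text or gzip; `gzfile()` handles
#'   the decompression transparently).
#' @return A [seq_records()] data frame with qualities, abundance 1.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(empty_records())
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L,
         " in ", path, " (file length is not a multiple of 4 lines)")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad)) stop("FASTQ record ", bad[1], ": header does not start with '@'")
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad)) stop("FASTQ record ", bad[1], ": missing '+' separator line")
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad)) {
    stop("FASTQ record ", bad[1], ": quality line length ", nchar(quals[bad[1]]),
         " does not match sequence length ", nchar(seqs[bad[1]]))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  seq_records(ids, seqs, quals = lapply(quals, decode_quals))
}

#' Write a record set as FASTQ
#'
#' @param records a [seq_records()] data frame; every record must carry
#'   qualities.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (!all(has_quals(records))) stop("cannot write FASTQ: records without qualities")
  lines <- character(4L * nrow(records))
  for (i in seq_len(nrow(records))) {
    lines[4L * i - 3L] <- paste0("@", records$id[i])
    lines[4L * i - 2L] <- records$bases[i]
    lines[4L * i - 1L] <- "+"
    lines[4L * i] <- encode_quals(records$quals[[i]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a record set
#'
#' Uses Biostrings for parsing. Headers of the form `id;size=N` (the
#' USEARCH dereplication dialect) are decoded into the `abundance` column;
#' other headers get abundance 1.
#'
#' @param path path to a FASTA file.
#' @return A [seq_records()] data frame without qualities.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  size <- rep(1L, length(ss))
  hit <- grepl(";size=\\d+;?$", nm)
  size[hit] <- as.integer(sub("^.*;size=(\\d+);?$", "\\1", nm[hit]))
  nm[hit] <- sub(";size=\\d+;?$", "", nm[hit])
  seq_records(nm, as.character(ss), abundance = size)
}

#' Write a dereplicated record set as FASTA
#'
#' Headers carry the abundance as a `;size=N` suffix so that downstream
#' tools (and [read_fasta()]) can restore the per-sequence counts.
#'
#' @param records a [seq_records()] data frame with abundances set.
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' \dontrun{
#' write_fasta_derep(seq_records("s1", "ACGT", abundance = 7), "out.fasta")
#' # header written: >s1;size=7
#' }
#' @export
write_fasta_derep <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$bases)
  names(ss) <- sprintf("%s;size=%d", records$id, records$abundance)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a primer table
#'
#' The table is delimited text (comma or tab, auto-detected) with header
#' `sample,barcode,fprimer,rprimer`. Per side, a cell holds either a primer
#' sequence over `A`,`C`,`G`,`T` or a non-negative integer trim length;
#' empty cells mean "nothing to remove". Sample names and barcodes must be
#' unique.
#'
#' @param path path to the table.
#' @return A data frame with columns `sample`, `barcode`, `fprimer_seq`,
#'   `fprimer_len`, `rprimer_seq`, `rprimer_len` (`NA` where unused).
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", fill = TRUE,
                           na.strings = character(), strip.white = TRUE)
  names(tab) <- tolower(names(tab))
  need <- c("sample", "barcode", "fprimer", "rprimer")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("primer table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample)) {
    stop("duplicate sample name(s) in primer table: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  }
  bc <- toupper(tab$barcode)
  if (any(nzchar(bc) & grepl("[^ACGT]", bc))) stop("barcodes must be strings over {A,C,G,T}")
  if (anyDuplicated(bc[nzchar(bc)])) stop("two samples share a barcode")
  parse_side <- function(cell, col) {
    cell <- toupper(trimws(cell))
    seqs <- rep(NA_character_, length(cell))
    lens <- rep(NA_integer_, length(cell))
    for (i in seq_along(cell)) {
      if (!nzchar(cell[i])) next
      if (grepl("^\\d+$", cell[i])) {
        lens[i] <- as.integer(cell[i])
      } else if (!grepl("[^ACGT]", cell[i])) {
        seqs[i] <- cell[i]
      } else {
        stop(col, " for sample '", tab$sample[i],
             "' is neither a base sequence nor a trim length: ", cell[i])
      }
    }
    list(seq = seqs, len = lens)
  }
  fw <- parse_side(tab$fprimer, "fprimer")
  rv <- parse_side(tab$rprimer, "rprimer")
  data.frame(sample = tab$sample,
             barcode = ifelse(nzchar(bc), bc, NA_character_),
             fprimer_seq = fw$seq, fprimer_len = fw$len,
             rprimer_seq = rv$seq, rprimer_len = rv$len,
             stringsAsFactors = FALSE)
}

#' Build and write a repair report
#'
#' `repair_report()` assembles the per-cluster outcome entries produced by
#' [repair_cluster()] into a report object; `write_report()` validates it
#' and serializes it to JSON. The field layout is published as a JSON
#' schema in `system.file("extdata", "repair_report_schema.json",
#' package = "oligorepair")`.
#'
#' @param file name of the processed input file.
#' @param entries list of per-cluster entries, each a list with fields
#'   `cluster_id`, `original_centroid`, `chosen`, `edits` (list of edit
#'   records), `n_changes`, `category` (one of `correct`, `substituted`,
#'   `repaired`, `unrecoverable`).
#' @return `repair_report()` returns a `repair_report` object.
#' @export
repair_report <- function(file, entries) {
  structure(list(file = file, entries = entries), class = "repair_report")
}

#' @rdname repair_report
#' @param report a `repair_report` object.
#' @return `validate_report()` returns the report invisibly, or errors.
#' @export
validate_report <- function(report) {
  stopifnot(inherits(report, "repair_report"))
  cats <- c("correct", "substituted", "repaired", "unrecoverable")
  for (e in report$entries) {
    need <- c("cluster_id", "original_centroid", "chosen", "edits",
              "n_changes", "category")
    miss <- setdiff(need, names(e))
    if (length(miss)) stop("report entry missing field(s): ", paste(miss, collapse = ", "))
    if (!e$category %in% cats) stop("unknown report category: ", e$category)
    if (e$n_changes != length(e$edits)) {
      stop("report entry for cluster ", e$cluster_id,
           ": n_changes (", e$n_changes, ") != number of edits (", length(e$edits), ")")
    }
    if (e$category == "correct" && length(e$edits) > 0) {
      stop("report entry for cluster ", e$cluster_id,
           ": category 'correct' must have an empty edit list")
    }
  }
  invisible(report)
}

#' @rdname repair_report
#' @param path output path for the JSON file.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname repair_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_report(structure(x, class = "repair_report"))
}
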