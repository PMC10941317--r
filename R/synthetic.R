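#' Parameters of the synthetic sequencing channel
#'
#' The simulator emulates a DNA storage experiment: a pool of
#' constraint-satisfying reference oligos, per-reference read counts with
#' log-normal abundance skew (PCR amplification bias), and per-read
#' substitution/insertion/deletion errors with two-level PHRED qualities
#' (correct bases drawn around `q_correct`, erroneous bases around
#' `q_error`, truncated to `[2, 41]`).
#'
#' @param n_refs number of reference oligos.
#' @param ref_length reference length in nt.
#' @param coverage mean reads per reference.
#' @param abundance_dispersion log-normal sigma of the per-reference read
#'   counts; 0 gives exactly `round(coverage)` reads each. Default 0.5.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities
#'   (substitution; insertion after each base; deletion).
#' @param q_correct,q_error mean PHRED of correct and erroneous bases.
#' @param seed integer seed making the whole dataset reproducible.
#' @return A `channel_params` object.
#' @export
channel_params <- function(n_refs = 50L, ref_length = 60L, coverage = 20,
                           abundance_dispersion = 0.5,
                           sub_rate = 0.01, ins_rate = 0.005, del_rate = 0.005,
                           q_correct = 38, q_error = 12, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate)
  stopifnot(n_refs >= 1, ref_length >= 1, coverage > 0,
            abundance_dispersion >= 0,
            all(rates >= 0), all(rates < 1),
            q_correct >= 0, q_correct <= 93, q_error >= 0, q_error <= 93)
  structure(list(n_refs = as.integer(n_refs),
                 ref_length = as.integer(ref_length),
                 coverage = coverage,
                 abundance_dispersion = abundance_dispersion,
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 q_correct = q_correct, q_error = q_error,
                 seed = as.integer(seed)),
            class = "channel_params")
}

#' Generate one constraint-satisfying reference oligo
#'
#' Builds the sequence base by base with backtracking: candidate bases are
#' tried in random order (ambient RNG; seed with `set.seed()` for
#' reproducibility), each prefix is checked against homopolymer, blacklist
#' and k-mer rules and against GC feasibility of the current window and of
#' the whole sequence, and dead ends are undone. After a bounded number of
#' restarts the constraint set is declared unsatisfiable at this length,
#' naming the last rule that blocked the search.
#'
#' @param cs a [constraint_set()]; its `target_length` is ignored in favor
#'   of `length`.
#' @param length requested sequence length.
#' @param max_restarts full restarts before giving up (default 50).
#' @return A sequence string with `find_violations()` empty (under `cs`
#'   with `target_length` set to `length`).
#' @export
generate_reference <- function(cs, length, max_restarts = 50L) {
  L <- as.integer(length)
  cs_len <- cs
  cs_len$target_length <- L
  last_block <- "gc_window"
  for (restart in seq_len(max_restarts)) {
    res <- build_one_reference(cs, L)
    if (!is.null(res$seq) && satisfies_constraints(res$seq, cs_len)) {
      return(res$seq)
    }
    if (!is.null(res$block)) last_block <- res$block
  }
  stop("could not generate a length-", L,
       " sequence satisfying the constraint set (binding rule: ",
       last_block, ")")
}

# One bounded-DFS attempt; returns list(seq = string or NULL, block = rule name)
build_one_reference <- function(cs, L) {
  ch <- character(L)
  isgc <- logical(L)
  opts <- vector("list", L)
  opts[[1L]] <- sample(BASES)
  w <- cs$window_size
  lo_g <- cs$gc_min; hi_g <- cs$gc_max
  lo_w <- cs$gc_window_min; hi_w <- cs$gc_window_max
  h <- cs$max_homopolymer
  eps <- 1e-9
  block <- NULL
  i <- 1L
  steps <- 0L; max_steps <- 400L * L
  while (i >= 1L && i <= L && steps < max_steps) {
    steps <- steps + 1L
    if (length(opts[[i]]) == 0L) {
      i <- i - 1L
      next
    }
    b <- opts[[i]][1L]
    opts[[i]] <- opts[[i]][-1L]
    ch[i] <- b
    isgc[i] <- b == "G" || b == "C"
    ok <- TRUE
    # homopolymer run ending at i
    run <- 1L
    while (i - run >= 1L && ch[i - run] == b) run <- run + 1L
    if (run > h) { ok <- FALSE; block <- "homopolymer" }
    # blacklist motif ending at i
    if (ok && length(cs$blacklist)) {
      for (motif in cs$blacklist) {
        ml <- nchar(motif)
        if (ml <= i && paste(ch[(i - ml + 1L):i], collapse = "") == motif) {
          ok <- FALSE; block <- "blacklist"; break
        }
      }
    }
    # k-mer repeat count in the prefix
    if (ok && !is.null(cs$kmer_k) && i >= cs$kmer_k) {
      k <- cs$kmer_k
      km <- paste(ch[(i - k + 1L):i], collapse = "")
      st <- seq_len(i - k + 1L)
      cnt <- sum(vapply(st, function(s) paste(ch[s:(s + k - 1L)], collapse = "") == km,
                        logical(1)))
      if (cnt > cs$kmer_max_occurrences) { ok <- FALSE; block <- "kmer" }
    }
    # GC feasibility: current window
    if (ok) {
      wstart <- ((i - 1L) %/% w) * w + 1L
      wlen <- min(w, L - wstart + 1L)
      g <- sum(isgc[wstart:i])
      rem <- wlen - (i - wstart + 1L)
      if (g > hi_w * wlen + eps || g + rem < lo_w * wlen - eps) {
        ok <- FALSE; block <- "gc_window"
      }
    }
    # GC feasibility: whole sequence
    if (ok) {
      g <- sum(isgc[1:i])
      rem <- L - i
      if (g > hi_g * L + eps || g + rem < lo_g * L - eps) {
        ok <- FALSE; block <- "gc_global"
      }
    }
    if (ok) {
      i <- i + 1L
      if (i <= L) opts[[i]] <- sample(BASES)
    }
  }
  if (i > L) list(seq = paste(ch, collapse = ""), block = block)
  else list(seq = NULL, block = block)
}

draw_qual <- function(n, mu) {
  pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, mean = mu, sd = 3)))))
}

#' Pass one sequence through the error channel
#'
#' Per reference position the base is deleted with probability `del_rate`,
#' otherwise substituted with probability `sub_rate` by a uniformly chosen
#' other base; after each position a uniform base is inserted with
#' probability `ins_rate`. Correct bases get qualities drawn around
#' `q_correct`, substituted and inserted bases around `q_error`. The
#' ground-truth edit list is returned in the coordinate convention of
#' [apply_edits()], so `apply_edits(bases, edits)` reproduces the read
#' exactly. Uses the ambient RNG.
#'
#' @param bases the reference sequence.
#' @param params a [channel_params()].
#' @return A list with `bases` (the read), `quals` (integer PHRED vector)
#'   and `edits` (ordered edit data frame).
#' @export
corrupt_read <- function(bases, params) {
  ref <- strsplit(bases, "", fixed = TRUE)[[1]]
  out <- character(0)
  qual <- integer(0)
  edits <- list()
  for (i in seq_along(ref)) {
    if (stats::runif(1) < params$del_rate) {
      edits[[length(edits) + 1L]] <- edit_row("deletion", length(out), from = ref[i])
    } else {
      if (stats::runif(1) < params$sub_rate) {
        b <- sample(setdiff(BASES, ref[i]), 1L)
        edits[[length(edits) + 1L]] <-
          edit_row("substitution", length(out), from = ref[i], to = b)
        out <- c(out, b)
        qual <- c(qual, draw_qual(1L, params$q_error))
      } else {
        out <- c(out, ref[i])
        qual <- c(qual, draw_qual(1L, params$q_correct))
      }
    }
    if (stats::runif(1) < params$ins_rate) {
      b <- sample(BASES, 1L)
      edits[[length(edits) + 1L]] <- edit_row("insertion", length(out), to = b)
      out <- c(out, b)
      qual <- c(qual, draw_qual(1L, params$q_error))
    }
  }
  list(bases = paste(out, collapse = ""), quals = qual,
       edits = if (length(edits)) do.call(rbind, edits) else empty_edits())
}

#' Serialize / parse a ground-truth edit list
#'
#' Compact text form used in the truth table written by
#' [simulate_dataset()]: edits joined by `;`, each `sub@P:X>Y`, `del@P:X`
#' or `ins@P:Y` with `P` the 0-based position in the [apply_edits()]
#' convention.
#'
#' @param edits an edit data frame.
#' @return `serialize_edits()` returns a single string (empty for no
#'   edits); `parse_edits()` inverts it.
#' @export
serialize_edits <- function(edits) {
  if (nrow(edits) == 0L) return("")
  paste(vapply(seq_len(nrow(edits)), function(i) {
    e <- edits[i, ]
    switch(e$op,
           substitution = sprintf("sub@%d:%s>%s", e$pos, e$from, e$to),
           deletion = sprintf("del@%d:%s", e$pos, e$from),
           insertion = sprintf("ins@%d:%s", e$pos, e$to))
  }, character(1)), collapse = ";")
}

#' @rdname serialize_edits
#' @param s a serialized edit string.
#' @export
parse_edits <- function(s) {
  if (!nzchar(s)) return(empty_edits())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  do.call(rbind, lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(sub|del|ins)@(\\d+):([ACGTN])?>?([ACGTN])?$", p))[[1]]
    if (length(m) == 0L) stop("malformed edit token: ", p)
    op <- c(sub = "substitution", del = "deletion", ins = "insertion")[[m[2]]]
    pos <- as.integer(m[3])
    switch(op,
           substitution = edit_row("substitution", pos, from = m[4], to = m[5]),
           deletion = edit_row("deletion", pos, from = m[4]),
           insertion = edit_row("insertion", pos, to = m[4]))
  }))
}

#' Simulate a full synthetic dataset
#'
#' Generates `n_refs` distinct constraint-satisfying references, draws a
#' read count per reference as `round(coverage * LogNormal(0,
#' abundance_dispersion))` (minimum 0), passes each read through the error
#' channel, and records the ground truth. Fully reproducible from
#' `params$seed`.
#'
#' @param cs a [constraint_set()] the references must satisfy.
#' @param params a [channel_params()].
#' @return A list with `references` (a [seq_records()] set), `reads` (a
#'   [seq_records()] set with qualities) and `truth` (a data frame with
#'   columns `read_id`, `ref_id`, `n_edits`, `edit_list`).
#' @export
simulate_dataset <- function(cs, params) {
  set.seed(params$seed)
  refs <- character(params$n_refs)
  for (i in seq_len(params$n_refs)) {
    repeat {
      s <- generate_reference(cs, params$ref_length)
      if (!s %in% refs[seq_len(i - 1L)]) break
    }
    refs[i] <- s
  }
  ref_ids <- sprintf("ref_%03d", seq_len(params$n_refs))
  counts <- pmax(0L, as.integer(round(
    params$coverage * stats::rlnorm(params$n_refs, 0, params$abundance_dispersion))))
  total <- sum(counts)
  read_id <- character(total); read_bases <- character(total)
  read_quals <- vector("list", total)
  t_ref <- character(total); t_n <- integer(total); t_edits <- character(total)
  k <- 0L
  for (i in seq_len(params$n_refs)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      r <- corrupt_read(refs[i], params)
      read_id[k] <- sprintf("read_%06d", k)
      read_bases[k] <- r$bases
      read_quals[[k]] <- r$quals
      t_ref[k] <- ref_ids[i]
      t_n[k] <- nrow(r$edits)
      t_edits[k] <- serialize_edits(r$edits)
    }
  }
  keep <- nchar(read_bases) > 0L  # fully deleted reads produce no record
  list(references = seq_records(ref_ids, refs),
       reads = seq_records(read_id[keep], read_bases[keep],
                           quals = read_quals[keep]),
       truth = data.frame(read_id = read_id[keep], ref_id = t_ref[keep],
                          n_edits = t_n[keep], edit_list = t_edits[keep],
                          stringsAsFactors = FALSE))
}

#' Write a simulated dataset to disk
#'
#' Writes `references.fasta`, `reads.fastq` and `truth.tsv` into a
#' directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_derep(sim$references, file.path(dir, "references.fasta"))
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
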