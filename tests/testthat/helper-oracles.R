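# Independent oracles used across the suite. These deliberately avoid the
# package's scan_constraints() engine: the violation scanners are naive
# brute-force loops, the edit distance is a hand-written DP, and the
# edit-neighbourhood search enumerates variants explicitly.

DNA <- c("A", "C", "G", "T")

random_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- naive constraint scanners -------------------------------------------

naive_violations <- function(s, cs) {
  L <- nchar(s)
  ch <- if (L > 0) strsplit(s, "", fixed = TRUE)[[1]] else character()
  rows <- list()
  add <- function(rule, start, end, mag) {
    rows[[length(rows) + 1L]] <<- data.frame(rule = rule, start = start,
                                             end = end, magnitude = mag,
                                             stringsAsFactors = FALSE)
  }
  gc_of <- function(idx) sum(ch[idx] %in% c("G", "C")) / length(idx)
  if (L > 0) {
    f <- gc_of(1:L)
    if (f < cs$gc_min) add("gc_global", 0L, L, cs$gc_min - f)
    if (f > cs$gc_max) add("gc_global", 0L, L, f - cs$gc_max)
    s0 <- 1L
    while (s0 <= L) {
      e0 <- min(s0 + cs$window_size - 1L, L)
      f <- gc_of(s0:e0)
      if (f < cs$gc_window_min) add("gc_window", s0 - 1L, e0, cs$gc_window_min - f)
      if (f > cs$gc_window_max) add("gc_window", s0 - 1L, e0, f - cs$gc_window_max)
      s0 <- s0 + cs$window_size
    }
    # maximal runs by explicit scan
    i <- 1L
    while (i <= L) {
      j <- i
      while (j < L && ch[j + 1L] == ch[i]) j <- j + 1L
      if (j - i + 1L > cs$max_homopolymer) {
        add("homopolymer", i - 1L, j, (j - i + 1L) - cs$max_homopolymer)
      }
      i <- j + 1L
    }
    for (motif in cs$blacklist) {
      ml <- nchar(motif)
      for (p in seq_len(max(0L, L - ml + 1L))) {
        if (substr(s, p, p + ml - 1L) == motif) add("blacklist", p - 1L, p + ml - 1L, 1)
      }
    }
    if (!is.null(cs$kmer_k) && L >= cs$kmer_k) {
      k <- cs$kmer_k
      km_at <- vapply(seq_len(L - k + 1L), function(p) substr(s, p, p + k - 1L), "")
      for (km in unique(km_at)) {
        occ <- which(km_at == km)
        if (length(occ) > cs$kmer_max_occurrences) {
          add("kmer", min(occ) - 1L, max(occ) + k - 1L,
              length(occ) - cs$kmer_max_occurrences)
        }
      }
    }
    for (p in which(ch == "N")) add("ambiguous", p - 1L, p, 1)
  }
  if (!is.null(cs$target_length)) {
    lo <- cs$target_length[1]; hi <- cs$target_length[length(cs$target_length)]
    if (L < lo) add("length", 0L, L, lo - L)
    if (L > hi) add("length", 0L, L, L - hi)
  }
  if (length(rows) == 0L) {
    return(data.frame(rule = character(), start = integer(), end = integer(),
                      magnitude = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

naive_valid <- function(s, cs) nrow(naive_violations(s, cs)) == 0L

sort_violations <- function(v) {
  v <- v[order(v$rule, v$start, v$end), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# --- independent Levenshtein DP ------------------------------------------

dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# --- exhaustive edit-neighbourhood search --------------------------------

variants_1edit <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- character(0)
  for (i in seq_len(L)) {
    for (b in setdiff(DNA, ch[i])) {
      v <- ch; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  for (i in seq_len(L)) out <- c(out, paste(ch[-i], collapse = ""))
  for (i in 0:L) {
    for (b in DNA) {
      out <- c(out, paste(c(ch[seq_len(i)], b, ch[seq_len(L - i) + i]),
                          collapse = ""))
    }
  }
  unique(out)
}

# TRUE iff some sequence within <= k edits of s satisfies cs (by the naive
# scanner). Breadth-first with dedup and early exit.
exists_valid_within <- function(s, k, cs) {
  if (naive_valid(s, cs)) return(TRUE)
  seen <- new.env(parent = emptyenv())
  frontier <- s
  for (depth in seq_len(k)) {
    nxt <- character(0)
    for (f in frontier) {
      for (v in variants_1edit(f)) {
        if (!nzchar(v) || !is.null(seen[[v]])) next
        assign(v, TRUE, envir = seen)
        if (naive_valid(v, cs)) return(TRUE)
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  FALSE
}

# --- small record helpers ------------------------------------------------

records_with_quals <- function(ids, seqs, mean_q = 35) {
  seq_records(ids, seqs,
              quals = lapply(nchar(seqs), function(n) rep(as.integer(mean_q), n)))
}
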