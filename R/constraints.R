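#' Declare a constraint set for encoded oligos
#'
#' A constraint set collects the design rules a DNA storage code imposes on
#' its output sequences. Rule names (also the config-file keys and the
#' `rule` labels in [find_violations()] output) are: `gc_global`,
#' `gc_window`, `homopolymer`, `blacklist`, `kmer`, `length` and
#' `ambiguous` (any `N` base).
#'
#' @param gc_min,gc_max allowed overall GC fraction, in `[0, 1]`.
#' @param window_size window width in bases for the per-window GC rule.
#'   Windows tile the sequence contiguously at offsets `0, w, 2w, ...`; a
#'   trailing remainder shorter than `w` is evaluated as its own window.
#' @param gc_window_min,gc_window_max per-window GC bounds; default to the
#'   overall bounds.
#' @param max_homopolymer maximum allowed run of identical bases.
#' @param blacklist character vector of forbidden motifs over
#'   `A`,`C`,`G`,`T`; overlapping occurrences each count.
#' @param kmer_k k-mer width for the repeat rule, or `NULL` to disable. No
#'   k-mer may occur more than `kmer_max_occurrences` times within one
#'   sequence.
#' @param kmer_max_occurrences maximum occurrences per k-mer (default 1).
#' @param target_length required sequence length: a single integer for an
#'   exact length, a length-2 vector `c(min, max)` for a range, or `NULL`
#'   to disable.
#' @param rule_weights named non-negative weights per rule, used by the
#'   per-base error metric and the count-based violation penalty. Missing
#'   rules default to weight 1.
#' @return A `constraint_set` object.
#' @examples
#' cs <- constraint_set(target_length = 30)
#' find_violations("CTGACAAAAATGCGTACGTTAGCATGCTAAGT", cs)
#' @export
constraint_set <- function(gc_min = 0.40, gc_max = 0.60,
                           window_size = 15L,
                           gc_window_min = NULL, gc_window_max = NULL,
                           max_homopolymer = 3L,
                           blacklist = character(),
                           kmer_k = NULL, kmer_max_occurrences = 1L,
                           target_length = NULL,
                           rule_weights = NULL) {
  stopifnot(gc_min <= gc_max, gc_min >= 0, gc_max <= 1,
            window_size >= 1, max_homopolymer >= 1,
            kmer_max_occurrences >= 1)
  if (is.null(gc_window_min)) gc_window_min <- gc_min
  if (is.null(gc_window_max)) gc_window_max <- gc_max
  stopifnot(gc_window_min <= gc_window_max)
  blacklist <- toupper(as.character(blacklist))
  if (any(!nzchar(blacklist)) || any(grepl("[^ACGT]", blacklist))) {
    stop("blacklist motifs must be nonempty strings over {A,C,G,T}")
  }
  if (!is.null(kmer_k)) stopifnot(kmer_k >= 1)
  if (!is.null(target_length)) {
    stopifnot(length(target_length) %in% c(1L, 2L), all(target_length >= 0))
    if (length(target_length) == 2L) stopifnot(target_length[1] <= target_length[2])
    target_length <- as.integer(target_length)
  }
  rules <- c("gc_global", "gc_window", "homopolymer", "blacklist",
             "kmer", "length", "ambiguous")
  w <- stats::setNames(rep(1, length(rules)), rules)
  if (!is.null(rule_weights)) {
    unknown <- setdiff(names(rule_weights), rules)
    if (length(unknown)) stop("unknown rule(s) in rule_weights: ", paste(unknown, collapse = ", "))
    if (any(rule_weights < 0)) stop("rule weights must be non-negative")
    w[names(rule_weights)] <- rule_weights
  }
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 window_size = as.integer(window_size),
                 gc_window_min = gc_window_min, gc_window_max = gc_window_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 blacklist = blacklist,
                 kmer_k = if (is.null(kmer_k)) NULL else as.integer(kmer_k),
                 kmer_max_occurrences = as.integer(kmer_max_occurrences),
                 target_length = target_length,
                 rule_weights = w),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set>\n")
  cat(sprintf("  GC global   [%.2f, %.2f]\n", x$gc_min, x$gc_max))
  cat(sprintf("  GC window   [%.2f, %.2f] per %d nt (tiling)\n",
              x$gc_window_min, x$gc_window_max, x$window_size))
  cat(sprintf("  homopolymer <= %d\n", x$max_homopolymer))
  if (length(x$blacklist)) cat("  blacklist  ", paste(x$blacklist, collapse = " "), "\n")
  if (!is.null(x$kmer_k)) {
    cat(sprintf("  kmer        k=%d, max %d occurrence(s)\n", x$kmer_k, x$kmer_max_occurrences))
  }
  if (!is.null(x$target_length)) {
    cat("  length     ", paste(x$target_length, collapse = "-"), "\n")
  }
  invisible(x)
}

#' GC fraction of a span
#'
#' Fraction `(#G + #C) / span length` over a 0-based half-open interval;
#' `N` counts as neither G/C nor A/T but contributes to the denominator.
#'
#' @param bases a sequence string.
#' @param span 0-based half-open interval `c(start, end)`; defaults to the
#'   whole sequence.
#' @return The GC fraction.
#' @examples
#' gc_fraction("ACGT")           # 0.5
#' gc_fraction("GGCCAA", c(0, 4)) # 1.0
#' @export
gc_fraction <- function(bases, span = c(0L, nchar(bases))) {
  L <- nchar(bases)
  start <- span[1]; end <- span[2]
  if (start < 0 || end > L || start >= end) stop("span must be a nonempty interval within the sequence")
  sub <- substr(bases, start + 1L, end)
  nGC <- nchar(gsub("[^GC]", "", sub))
  nGC / (end - start)
}

# Single pass over all rules. Returns violations (if collect_violations),
# per-base scores (if collect_scores), total and length_delta. Spans are
# 0-based half-open. This is the engine behind find_violations(),
# error_profile() and the repair loop's candidate evaluation.
scan_constraints <- function(bases, cs, collect_violations = TRUE,
                             collect_scores = TRUE) {
  L <- nchar(bases)
  w <- cs$rule_weights
  scores <- if (collect_scores) numeric(L) else NULL
  vr <- character(); vs <- integer(); ve <- integer(); vm <- numeric()
  add <- function(rule, start, end, mag) {
    vr[length(vr) + 1L] <<- rule
    vs[length(vs) + 1L] <<- start
    ve[length(ve) + 1L] <<- end
    vm[length(vm) + 1L] <<- mag
  }
  ch <- if (L > 0) strsplit(bases, "", fixed = TRUE)[[1]] else character()
  isGC <- ch == "G" | ch == "C"
  isAT <- ch == "A" | ch == "T"

  gc_span <- function(start, end, lo, hi, rule) {
    frac <- sum(isGC[start:end]) / (end - start + 1L)
    if (frac < lo) {
      dev <- lo - frac
      if (collect_violations) add(rule, start - 1L, end, dev)
      if (collect_scores) {
        idx <- start:end
        idx <- idx[isAT[idx]]
        scores[idx] <<- scores[idx] + w[[rule]] * dev
      }
    } else if (frac > hi) {
      dev <- frac - hi
      if (collect_violations) add(rule, start - 1L, end, dev)
      if (collect_scores) {
        idx <- start:end
        idx <- idx[isGC[idx]]
        scores[idx] <<- scores[idx] + w[[rule]] * dev
      }
    }
  }

  if (L > 0) {
    gc_span(1L, L, cs$gc_min, cs$gc_max, "gc_global")
    starts <- seq(1L, L, by = cs$window_size)
    for (s in starts) gc_span(s, min(s + cs$window_size - 1L, L),
                              cs$gc_window_min, cs$gc_window_max, "gc_window")

    r <- rle(ch)
    ends <- cumsum(r$lengths)
    h <- cs$max_homopolymer
    for (i in which(r$lengths > h)) {
      rl <- r$lengths[i]
      e <- ends[i]; s <- e - rl + 1L
      if (collect_violations) add("homopolymer", s - 1L, e, rl - h)
      if (collect_scores) scores[s:e] <- scores[s:e] + w[["homopolymer"]] * (rl - h) / rl
    }

    for (motif in cs$blacklist) {
      m <- gregexpr(paste0("(?=", motif, ")"), bases, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      ml <- nchar(motif)
      for (s in as.integer(m)) {
        if (collect_violations) add("blacklist", s - 1L, s + ml - 1L, 1)
        if (collect_scores) scores[s:(s + ml - 1L)] <- scores[s:(s + ml - 1L)] + w[["blacklist"]]
      }
    }

    if (!is.null(cs$kmer_k) && L >= cs$kmer_k) {
      k <- cs$kmer_k; m_max <- cs$kmer_max_occurrences
      st <- seq_len(L - k + 1L)
      kmers <- substring(bases, st, st + k - 1L)
      counts <- table(kmers)
      for (km in names(counts[counts > m_max])) {
        occ <- st[kmers == km]
        cnt <- length(occ)
        if (collect_violations) add("kmer", min(occ) - 1L, max(occ) + k - 1L, cnt - m_max)
        if (collect_scores) {
          for (s in occ[(m_max + 1L):cnt]) {
            scores[s:(s + k - 1L)] <- scores[s:(s + k - 1L)] + w[["kmer"]]
          }
        }
      }
    }

    nidx <- which(ch == "N")
    for (p in nidx) {
      if (collect_violations) add("ambiguous", p - 1L, p, 1)
      if (collect_scores) scores[p] <- scores[p] + w[["ambiguous"]]
    }
  }

  length_delta <- 0L
  if (!is.null(cs$target_length)) {
    tl <- cs$target_length
    lo <- tl[1]; hi <- tl[length(tl)]
    if (L < lo) length_delta <- L - lo
    if (L > hi) length_delta <- L - hi
    if (length_delta != 0L && collect_violations) {
      add("length", 0L, L, abs(length_delta))
    }
  }

  list(violations = data.frame(rule = vr, start = vs, end = ve,
                               magnitude = vm, stringsAsFactors = FALSE),
       scores = scores,
       total = if (collect_scores) sum(scores) else NA_real_,
       length_delta = length_delta)
}

#' Locate constraint violations in a sequence
#'
#' Applies every rule of the constraint set and returns all breaches with
#' exact spans. Spans are 0-based half-open intervals on the sequence; the
#' `length` rule spans the whole sequence. Magnitudes are rule-specific:
#' distance to the nearest GC bound, run length minus the homopolymer
#' bound, 1 per blacklist occurrence, excess occurrence count for the k-mer
#' rule, `|actual - target|` for length, 1 per `N`.
#'
#' @param bases a sequence string over `A`,`C`,`G`,`T`,`N`.
#' @param cs a [constraint_set()].
#' @return A data frame with columns `rule`, `start`, `end`, `magnitude`;
#'   zero rows when the sequence satisfies every rule.
#' @export
find_violations <- function(bases, cs) {
  scan_constraints(bases, cs, collect_violations = TRUE,
                   collect_scores = FALSE)$violations
}

#' Per-base error metric
#'
#' Converts the located violations into a non-negative score per base; the
#' repair loop edits the highest-scoring bases first. Contributions (each
#' multiplied by the rule's weight): a violating homopolymer run of length
#' `r` scores `(r - h)/r` at each run position; a GC violation scores the
#' deviation from the nearest bound at every position whose base aggravates
#' it (G/C when too GC-rich, A/T when too GC-poor); blacklist occurrences
#' score 1 at every covered position; k-mer occurrences beyond the allowed
#' count score 1 at every covered position; `N` scores 1; the length rule
#' contributes only to `length_delta`, not to per-base scores.
#'
#' @inheritParams find_violations
#' @return A list of class `error_profile` with fields `scores` (one per
#'   base), `total` (their sum) and `length_delta` (actual minus target
#'   length, 0 when the length rule is satisfied or disabled).
#' @export
error_profile <- function(bases, cs) {
  sc <- scan_constraints(bases, cs, collect_violations = FALSE,
                         collect_scores = TRUE)
  structure(list(scores = sc$scores, total = sc$total,
                 length_delta = sc$length_delta),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat("<error_profile> total =", format(x$total), " length_delta =",
      x$length_delta, "\n")
  invisible(x)
}

#' Count-based violation penalty
#'
#' Sum over all violations of the violated rule's weight; the key used by
#' the constraint-aware sort mode ([constraint_sort()]).
#'
#' @inheritParams find_violations
#' @return A non-negative number.
#' @export
violation_penalty <- function(bases, cs) {
  v <- find_violations(bases, cs)
  if (nrow(v) == 0) return(0)
  sum(cs$rule_weights[v$rule])
}

#' Does a sequence satisfy every constraint?
#'
#' @inheritParams find_violations
#' @return `TRUE` when [find_violations()] is empty.
#' @export
satisfies_constraints <- function(bases, cs) {
  nrow(find_violations(bases, cs)) == 0L
}

#' Longest run of identical bases
#'
#' @param bases a sequence string.
#' @return Length of the longest homopolymer run (0 for an empty string).
#' @export
max_homopolymer_run <- function(bases) {
  if (nchar(bases) == 0) return(0L)
  max(rle(strsplit(bases, "", fixed = TRUE)[[1]])$lengths)
}
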