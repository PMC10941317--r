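#' Levenshtein edit distance
#'
#' Unit-cost substitutions, insertions and deletions, computed by
#' `utils::adist()`. Vectorized over `b`.
#'
#' @param a a single sequence string.
#' @param b a character vector of sequences.
#' @return An integer vector of distances, one per element of `b`.
#' @examples
#' edit_distance("ACGT", c("ACGT", "AGT", "TTTT"))
#' @export
edit_distance <- function(a, b) {
  as.integer(drop(utils::adist(a, b)))
}

edit_row <- function(op, pos, from = NA_character_, to = NA_character_) {
  data.frame(op = op, pos = as.integer(pos), from = from, to = to,
             stringsAsFactors = FALSE)
}

empty_edits <- function() {
  data.frame(op = character(), pos = integer(), from = character(),
             to = character(), stringsAsFactors = FALSE)
}

#' Replay an edit list
#'
#' Applies an ordered list of edits to a sequence. Positions are 0-based
#' indices on the sequence *as it stands when the edit is applied* (edits
#' are applied sequentially); an insertion at position `p` places the new
#' base before index `p`, so `p == nchar(seq)` appends.
#'
#' @param bases the starting sequence.
#' @param edits a data frame with columns `op` (`substitution`, `deletion`,
#'   `insertion`), `pos`, `from`, `to`, as produced by [repair_sequence()]
#'   and [corrupt_read()].
#' @return The edited sequence string.
#' @export
apply_edits <- function(bases, edits) {
  s <- bases
  for (i in seq_len(nrow(edits))) {
    op <- edits$op[i]; p <- edits$pos[i]
    if (op == "substitution") {
      stopifnot(p >= 0, p < nchar(s), substr(s, p + 1L, p + 1L) == edits$from[i])
      substr(s, p + 1L, p + 1L) <- edits$to[i]
    } else if (op == "deletion") {
      stopifnot(p >= 0, p < nchar(s), substr(s, p + 1L, p + 1L) == edits$from[i])
      s <- paste0(substr(s, 1L, p), substr(s, p + 2L, nchar(s)))
    } else if (op == "insertion") {
      stopifnot(p >= 0, p <= nchar(s))
      s <- paste0(substr(s, 1L, p), edits$to[i], substr(s, p + 1L, nchar(s)))
    } else {
      stop("unknown edit op: ", op)
    }
  }
  s
}

BASES <- c("A", "C", "G", "T")

#' Greedy maximum-likelihood repair of one sequence
#'
#' Iteratively edits the sequence until every constraint holds or the edit
#' budget is spent. Each iteration recomputes the per-base error metric
#' ([error_profile()]) and then: if the sequence is too long, deletes the
#' highest-scoring position (ties: leftmost; all-zero scores: the last
#' position); if too short, appends the base that minimizes the resulting
#' total error (ties: `A < C < G < T`); otherwise substitutes, at the
#' highest-scoring position (ambiguous `N` positions first, then ties
#' leftmost), the alternative base that minimizes the resulting total
#' error, requiring a strict decrease. If no substitution at any scored
#' position strictly reduces the total error the repair is stuck and fails;
#' failure is a regular result with `success = FALSE`, not an error.
#'
#' @param bases the sequence to repair.
#' @param cs a [constraint_set()].
#' @param max_changes edit budget after which the sequence is treated as
#'   unrecoverable (default 8).
#' @return A `repair_result` list: `repaired` (the final sequence),
#'   `edits` (ordered edit data frame, replayable with [apply_edits()]),
#'   `n_changes`, `success`.
#' @examples
#' cs <- constraint_set(target_length = 30)
#' r <- repair_sequence(example_homopolymer_read(), cs)
#' r$success; nchar(r$repaired); max_homopolymer_run(r$repaired)
#' @export
repair_sequence <- function(bases, cs, max_changes = 8L) {
  stopifnot(max_changes >= 0)
  s <- bases
  edits <- empty_edits()
  eps <- 1e-9
  repeat {
    scan <- scan_constraints(s, cs)
    if (nrow(scan$violations) == 0L) {
      return(structure(list(repaired = s, edits = edits,
                            n_changes = nrow(edits), success = TRUE),
                       class = "repair_result"))
    }
    if (nrow(edits) >= max_changes) break
    L <- nchar(s)
    if (scan$length_delta > 0L) {
      pos <- if (all(scan$scores == 0)) L else which.max(scan$scores)
      from <- substr(s, pos, pos)
      s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 1L, L))
      edits <- rbind(edits, edit_row("deletion", pos - 1L, from = from))
    } else if (scan$length_delta < 0L) {
      cand_tot <- vapply(BASES, function(b) {
        scan_constraints(paste0(s, b), cs, collect_violations = FALSE)$total
      }, numeric(1))
      b <- BASES[which.min(cand_tot)]
      s <- paste0(s, b)
      edits <- rbind(edits, edit_row("insertion", L, to = b))
    } else {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      cand_pos <- which(scan$scores > 0 | ch == "N")
      if (length(cand_pos) == 0L) break
      ord <- order(ch[cand_pos] != "N", -scan$scores[cand_pos], cand_pos)
      cand_pos <- cand_pos[ord]
      applied <- FALSE
      for (pos in cand_pos) {
        cur <- ch[pos]
        best_tot <- Inf; best_base <- NA_character_
        for (b in BASES) {
          if (b == cur) next
          cand <- s
          substr(cand, pos, pos) <- b
          tot <- scan_constraints(cand, cs, collect_violations = FALSE)$total
          if (tot < best_tot - eps) { best_tot <- tot; best_base <- b }
        }
        if (best_tot < scan$total - eps) {
          edits <- rbind(edits, edit_row("substitution", pos - 1L,
                                         from = cur, to = best_base))
          substr(s, pos, pos) <- best_base
          applied <- TRUE
          break
        }
      }
      if (!applied) break
    }
  }
  structure(list(repaired = s, edits = edits, n_changes = nrow(edits),
                 success = FALSE),
            class = "repair_result")
}

#' @export
print.repair_result <- function(x, ...) {
  cat("<repair_result>", if (x$success) "success" else "FAILED",
      "with", x$n_changes, "edit(s)\n")
  if (nrow(x$edits)) print(x$edits)
  invisible(x)
}

#' Choose or repair a cluster representative
#'
#' Implements the per-cluster selection workflow: if the centroid already
#' satisfies every constraint the cluster is `correct`. Otherwise the
#' members (sorted by edit distance to the centroid, then abundance
#' descending, then id) are scanned for a violation-free sequence, which
#' replaces the centroid (`substituted`). Failing that, greedy repair is
#' attempted: with `exhaustive = TRUE` (the default) every member is
#' repaired and the success with the fewest changes wins (ties: sort
#' order); otherwise the first success wins (`repaired`, the chosen record
#' is tagged `repaired:k`). If no member can be repaired within the budget
#' the cluster is `unrecoverable` and is excluded from pipeline output.
#'
#' @param cluster an `oligo_cluster` as produced by [greedy_cluster()].
#' @param cs a [constraint_set()].
#' @param max_changes per-sequence edit budget (see [repair_sequence()]).
#' @param exhaustive repair every member and keep the cheapest success
#'   (default), or stop at the first success.
#' @return The cluster with `status`, `chosen` (a one-row [seq_records()]
#'   or `NULL`) and, for repaired clusters, `repair` (the winning
#'   `repair_result` plus the repaired member's id) filled in.
#' @export
repair_cluster <- function(cluster, cs, max_changes = 8L, exhaustive = TRUE) {
  stopifnot(inherits(cluster, "oligo_cluster"))
  members <- cluster$members
  if (is.null(members) || nrow(members) == 0L) stop("cluster has no members")
  ord <- order(members$distance, -members$abundance, members$id)
  members <- members[ord, , drop = FALSE]
  cluster$members <- members

  if (satisfies_constraints(cluster$centroid$bases, cs)) {
    cluster$status <- "correct"
    cluster$chosen <- tag_record(cluster$centroid, "correct")
    return(cluster)
  }

  for (i in seq_len(nrow(members))) {
    if (members$id[i] == cluster$centroid$id[1]) next
    if (satisfies_constraints(members$bases[i], cs)) {
      cluster$status <- "substituted"
      cluster$chosen <- tag_record(as_record_row(members, i), "substituted")
      return(cluster)
    }
  }

  best <- NULL; best_i <- NA_integer_
  for (i in seq_len(nrow(members))) {
    res <- repair_sequence(members$bases[i], cs, max_changes = max_changes)
    if (!res$success) next
    if (is.null(best) || res$n_changes < best$n_changes) {
      best <- res; best_i <- i
    }
    if (!exhaustive) break
  }
  if (!is.null(best)) {
    rec <- as_record_row(members, best_i)
    rec$bases <- best$repaired
    rec$quals <- list(NULL)  # edits invalidate the per-base qualities
    cluster$status <- "repaired"
    cluster$chosen <- tag_record(rec, sprintf("repaired:%d", best$n_changes))
    cluster$repair <- c(best, list(member_id = members$id[best_i]))
  } else {
    cluster$status <- "unrecoverable"
    cluster$chosen <- NULL
  }
  cluster
}

as_record_row <- function(members, i) {
  rec <- members[i, c("id", "bases", "abundance", "quals", "tags"), drop = FALSE]
  class(rec) <- c("seq_records", "data.frame")
  rownames(rec) <- NULL
  rec
}

tag_record <- function(rec, tag) {
  rec$tags[[1]] <- unique(c(rec$tags[[1]], tag))
  rec
}

#' Emit the output records of a processed cluster
#'
#' For `correct` clusters a single record (the centroid) is emitted. For
#' `substituted` and `repaired` clusters the chosen representative is
#' emitted; with `keep_original = TRUE` the discarded constraint-violating
#' centroid is additionally emitted, tagged `original`. `unrecoverable`
#' clusters emit nothing.
#'
#' @param cluster a cluster processed by [repair_cluster()].
#' @param keep_original also emit the original violating centroid.
#' @return A [seq_records()] data frame with 0, 1 or 2 rows.
#' @export
keep_original_option <- function(cluster, keep_original = FALSE) {
  stopifnot(inherits(cluster, "oligo_cluster"), !is.null(cluster$status))
  if (cluster$status == "unrecoverable") return(empty_records())
  out <- cluster$chosen
  if (keep_original && cluster$status %in% c("substituted", "repaired")) {
    out <- bind_records(tag_record(cluster$centroid, "original"), out)
  }
  out
}

#' Build a repair-report entry from a processed cluster
#'
#' @param cluster a cluster processed by [repair_cluster()].
#' @return A list suitable for [repair_report()].
#' @export
cluster_report_entry <- function(cluster) {
  stopifnot(inherits(cluster, "oligo_cluster"), !is.null(cluster$status))
  edits <- if (!is.null(cluster$repair)) {
    lapply(seq_len(nrow(cluster$repair$edits)), function(i) {
      e <- cluster$repair$edits[i, ]
      list(op = e$op, pos = e$pos,
           from = if (is.na(e$from)) NULL else e$from,
           to = if (is.na(e$to)) NULL else e$to)
    })
  } else list()
  list(cluster_id = cluster$id,
       original_centroid = cluster$centroid$bases[1],
       chosen = if (is.null(cluster$chosen)) NULL else cluster$chosen$bases[1],
       edits = edits,
       n_changes = length(edits),
       category = cluster$status)
}
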