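#' Clustering parameters
#'
#' @param threshold similarity fraction in (0, 1]; a pooled sequence joins
#'   the current cluster when its similarity to the centroid is *strictly
#'   greater* than the threshold. Default 0.97.
#' @param order priority used to pick centroids: `"abundance"` (most
#'   common sequence first) or `"quality"` (highest mean PHRED first).
#'   Ties are broken by id, ascending.
#' @return A `cluster_params` object.
#' @export
cluster_params <- function(threshold = 0.97, order = c("abundance", "quality")) {
  stopifnot(threshold > 0, threshold <= 1)
  order <- match.arg(order)
  structure(list(threshold = threshold, order = order),
            class = "cluster_params")
}

#' Collapse identical sequences into abundance-annotated records
#'
#' Identical base strings are replaced by a single record whose abundance
#' is the sum of the member abundances. The representative's id and
#' qualities are taken from the member with the highest mean PHRED quality
#' (first occurrence on ties); for quality-less input, from the member with
#' the lexicographically smallest id.
#'
#' @param records a [seq_records()] data frame.
#' @return A dereplicated [seq_records()] data frame.
#' @export
dereplicate <- function(records) {
  if (nrow(records) == 0L) return(records)
  groups <- split(seq_len(nrow(records)), records$bases)
  rows <- lapply(groups, function(idx) {
    qs <- records$quals[idx]
    have_q <- !vapply(qs, is.null, logical(1))
    rep_i <- if (any(have_q)) {
      mq <- vapply(qs[have_q], mean, numeric(1))
      idx[have_q][which.max(mq)]
    } else {
      idx[order(records$id[idx])[1]]
    }
    rec <- as_record_row(records, rep_i)
    rec$abundance <- sum(records$abundance[idx])
    rec
  })
  out <- do.call(bind_records, rows)
  out[order(out$id), , drop = FALSE]
}

#' Pairwise sequence similarity
#'
#' `1 - d/max(len(a), len(b))` where `d` is the Levenshtein distance; two
#' empty strings have similarity 1. Monotone in edit distance, so a
#' similarity threshold maps directly onto a maximum edit distance at a
#' given length.
#'
#' @param a a single sequence string.
#' @param b a character vector of sequences.
#' @return A numeric vector of similarities in `[0, 1]`.
#' @examples
#' similarity("ACGT", c("ACGT", "ACGA", ""))
#' @export
similarity <- function(a, b) {
  d <- edit_distance(a, b)
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0L, 1, 1 - d / m)
}

#' Greedy centroid clustering by similarity
#'
#' The dereplicated pool is sorted by the chosen priority (abundance or
#' mean quality, descending; ties by id ascending). Repeatedly, the head
#' of the pool is removed and becomes a new cluster's centroid, and every
#' pooled sequence with similarity strictly above the threshold to that
#' centroid is moved into the cluster. Every input record ends up in
#' exactly one cluster.
#'
#' @param records a dereplicated [seq_records()] data frame.
#' @param params a [cluster_params()].
#' @return A list of `oligo_cluster` objects, each with fields `id`,
#'   `centroid` (one-row record set) and `members` (record set with
#'   `distance` and `similarity` columns, sorted by distance ascending,
#'   abundance descending, id ascending; the centroid is the first member).
#' @export
greedy_cluster <- function(records, params = cluster_params()) {
  if (nrow(records) == 0L) return(list())
  key <- if (params$order == "abundance") {
    records$abundance
  } else {
    if (!all(has_quals(records))) {
      stop("order = 'quality' requires per-base qualities on every record")
    }
    vapply(records$quals, mean, numeric(1))
  }
  pool <- records[order(-key, records$id), , drop = FALSE]
  clusters <- list()
  while (nrow(pool) > 0L) {
    centroid <- pool[1L, , drop = FALSE]
    pool <- pool[-1L, , drop = FALSE]
    sims <- if (nrow(pool)) similarity(centroid$bases, pool$bases) else numeric()
    hit <- sims > params$threshold
    members <- bind_records(centroid, pool[hit, , drop = FALSE])
    members$distance <- edit_distance(centroid$bases, members$bases)
    members$similarity <- c(1, sims[hit])
    members <- members[order(members$distance, -members$abundance, members$id), ,
                       drop = FALSE]
    pool <- pool[!hit, , drop = FALSE]
    clusters[[length(clusters) + 1L]] <-
      structure(list(id = sprintf("cluster_%d", length(clusters) + 1L),
                     centroid = centroid, members = members,
                     status = NULL, chosen = NULL, repair = NULL),
                class = "oligo_cluster")
  }
  clusters
}

#' @export
print.oligo_cluster <- function(x, ...) {
  cat("<oligo_cluster> ", x$id, ": centroid ", x$centroid$id[1], ", ",
      nrow(x$members), " member(s)",
      if (!is.null(x$status)) paste0(", status ", x$status) else "",
      "\n", sep = "")
  invisible(x)
}

#' Cluster membership table
#'
#' @param clusters a list of clusters from [greedy_cluster()].
#' @return A data frame with columns `member_id`, `centroid_id`,
#'   `similarity`, one row per member.
#' @export
cluster_membership <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(member_id = cl$members$id,
               centroid_id = cl$centroid$id[1],
               similarity = cl$members$similarity,
               stringsAsFactors = FALSE)
  }))
}
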