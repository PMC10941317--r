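#' Build a resolved pipeline configuration
#'
#' Takes a (possibly partial) nested configuration list, validates it
#' (unknown keys are rejected at every level, inconsistent stage
#' combinations are reported before any I/O) and materializes every
#' default. The resolved configuration is echoed to the output directory
#' by [run_pipeline()], so a run is reproducible from its outputs alone.
#'
#' Top-level keys: `input` (FASTQ/FASTA path or vector of paths),
#' `primer_table` (path or `NULL`), `output_dir`, `seed`, and the stage
#' blocks `demultiplex` (`enabled`), `filtering` (`min_mean_q`,
#' `mismatches`), `trim` (`enabled`), `constraint_stage` (`off`, `filter`
#' or `sort`), `constraints` (arguments of [constraint_set()]), `sort`
#' (`lambda`), `clustering` (`enabled`, `threshold`, `order`) and `repair`
#' (`enabled`, `max_changes`, `keep_original`, `exhaustive`). Repair
#' requires clustering: requesting `repair$enabled` with
#' `clustering$enabled = FALSE` is a configuration error.
#'
#' @param config a nested list, e.g. from [yaml::read_yaml()].
#' @return The resolved configuration list, classed `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    input = NULL,
    primer_table = NULL,
    output_dir = "oligorepair_out",
    seed = 1L,
    demultiplex = list(enabled = FALSE),
    filtering = list(min_mean_q = 10, mismatches = 0L),
    trim = list(enabled = FALSE),
    constraint_stage = "off",
    constraints = list(),
    sort = list(lambda = 1),
    clustering = list(enabled = FALSE, threshold = 0.97, order = "abundance"),
    repair = list(enabled = FALSE, max_changes = 8L, keep_original = FALSE,
                  exhaustive = TRUE)
  )
  merge_block <- function(def, got, path) {
    if (is.null(got)) return(def)
    unknown <- setdiff(names(got), names(def))
    if (length(unknown)) {
      stop("unknown configuration key(s) under '", path, "': ",
           paste(unknown, collapse = ", "))
    }
    def[names(got)] <- got
    def
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  out <- defaults
  for (k in c("input", "primer_table", "output_dir", "seed", "constraint_stage")) {
    if (!is.null(config[[k]])) out[[k]] <- config[[k]]
  }
  for (k in c("demultiplex", "filtering", "trim", "sort", "clustering", "repair")) {
    out[[k]] <- merge_block(defaults[[k]], config[[k]], k)
  }
  cs_args <- config$constraints
  if (!is.null(cs_args)) {
    bad <- setdiff(names(cs_args), names(formals(constraint_set)))
    if (length(bad)) stop("unknown constraint key(s): ", paste(bad, collapse = ", "))
    out$constraints <- cs_args
  }
  if (!out$constraint_stage %in% c("off", "filter", "sort")) {
    stop("constraint_stage must be one of off, filter, sort")
  }
  if (isTRUE(out$repair$enabled) && !isTRUE(out$clustering$enabled)) {
    stop("repair requires prior similarity clustering: enable clustering ",
         "or disable repair")
  }
  if (isTRUE(out$demultiplex$enabled) && is.null(out$primer_table)) {
    stop("demultiplexing requires a primer_table")
  }
  if (isTRUE(out$trim$enabled) && is.null(out$primer_table)) {
    stop("trimming requires a primer_table")
  }
  structure(out, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the processing pipeline
#'
#' Single-process driver over the package's stages, in fixed order:
#' demultiplex (optional) — mean-quality filter — barcode/primer trimming
#' (optional) — dereplication — constraint filter or sort (optional) —
#' greedy clustering (optional) — per-cluster repair (optional). Per
#' sample it writes `representatives.fasta` (abundance-annotated),
#' `report.json` (when repair ran) and appends to `counts.tsv`; the
#' resolved configuration is echoed to `resolved_config.yaml`. Read
#' counts are conserved at every filtering stage (`input = kept +
#' removed`), and the per-stage counts table records this.
#'
#' @param config a [pipeline_config()] (or a plain list, which is resolved
#'   first).
#' @param records optionally, an in-memory [seq_records()] set to process
#'   instead of reading `config$input`.
#' @return Invisibly, a list with per-sample results (`records`,
#'   `clusters`, `report`) plus `counts` and `output_dir`.
#' @export
run_pipeline <- function(config, records = NULL) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  set.seed(config$seed)
  if (is.null(records)) {
    if (is.null(config$input)) stop("no input configured")
    parts <- lapply(config$input, function(p) {
      if (grepl("\\.(fa|fasta)(\\.gz)?$", p, ignore.case = TRUE)) read_fasta(p)
      else read_fastq(p)
    })
    records <- do.call(bind_records, parts)
  }
  cs <- do.call(constraint_set, config$constraints)
  table <- if (!is.null(config$primer_table)) read_primer_table(config$primer_table)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(config$output_dir, "resolved_config.yaml"))

  samples <- if (isTRUE(config$demultiplex$enabled)) {
    demultiplex(records, table)
  } else {
    list(all = records)
  }
  samples <- samples[names(samples) != "undetermined" | vapply(samples, nrow, 0L) > 0]

  counts <- list()
  note <- function(sample, stage, n_in, n_kept) {
    counts[[length(counts) + 1L]] <<- data.frame(
      sample = sample, stage = stage, input = n_in, kept = n_kept,
      removed = n_in - n_kept, stringsAsFactors = FALSE)
  }
  results <- list()

  for (sample in names(samples)) {
    recs <- samples[[sample]]
    n0 <- nrow(recs)
    note(sample, "demultiplex", n0, n0)
    if (sample == "undetermined") next

    if (all(has_quals(recs)) && nrow(recs) > 0) {
      qf <- quality_filter(recs, config$filtering$min_mean_q)
      note(sample, "quality_filter", nrow(recs), nrow(qf$kept))
      recs <- qf$kept
    }
    if (isTRUE(config$trim$enabled)) {
      row <- table[table$sample == sample, , drop = FALSE]
      if (nrow(row) == 1L) {
        tr <- trim_extras(recs, row, config$filtering$mismatches)
        note(sample, "trim", nrow(recs), nrow(tr$kept))
        recs <- tr$kept
      }
    }
    n_in <- nrow(recs)
    recs <- dereplicate(recs)
    note(sample, "dereplicate", n_in, nrow(recs))

    if (config$constraint_stage == "filter") {
      cf <- constraint_filter(recs, cs)
      note(sample, "constraint_filter", nrow(recs), nrow(cf$kept))
      recs <- cf$kept
    } else if (config$constraint_stage == "sort") {
      recs <- constraint_sort(recs, cs, config$sort$lambda)
      note(sample, "constraint_sort", nrow(recs), nrow(recs))
    }

    clusters <- NULL
    report <- NULL
    if (isTRUE(config$clustering$enabled)) {
      clusters <- greedy_cluster(recs, cluster_params(config$clustering$threshold,
                                                      config$clustering$order))
      note(sample, "cluster", nrow(recs), length(clusters))
      if (isTRUE(config$repair$enabled)) {
        clusters <- lapply(clusters, repair_cluster, cs = cs,
                           max_changes = config$repair$max_changes,
                           exhaustive = config$repair$exhaustive)
        out_recs <- do.call(bind_records,
                            lapply(clusters, keep_original_option,
                                   keep_original = config$repair$keep_original))
        report <- repair_report(sample, lapply(clusters, cluster_report_entry))
        note(sample, "repair", length(clusters), nrow(out_recs))
        recs <- out_recs
      } else {
        recs <- do.call(bind_records, lapply(clusters, function(cl) cl$centroid))
        note(sample, "representatives", length(clusters), nrow(recs))
      }
    }

    prefix <- if (length(samples) > 1L) paste0(sample, "_") else ""
    write_fasta_derep(recs, file.path(config$output_dir,
                                      paste0(prefix, "representatives.fasta")))
    if (!is.null(report)) {
      write_report(report, file.path(config$output_dir,
                                     paste0(prefix, "report.json")))
    }
    results[[sample]] <- list(records = recs, clusters = clusters,
                              report = report)
  }
  counts <- do.call(rbind, counts)
  utils::write.table(counts, file.path(config$output_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(results, list(counts = counts, output_dir = config$output_dir)))
}
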