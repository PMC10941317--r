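#' Worked-example sequences
#'
#' Two small hand-constructed reads that exercise the repair algorithm
#' under the default storage-code constraint set (GC in \[0.40, 0.60\]
#' globally and per 15 nt window, homopolymer limit 3, fixed length 30).
#'
#' `example_homopolymer_read()` is 32 nt long with a single run of five
#' identical bases and no GC violation anywhere: the error metric flags
#' the run, and repair must both shorten the read to 30 nt and break the
#' run.
#'
#' `example_window_run_read()` is 30 nt long with a run of four `C`
#' crossing the boundary between the two GC windows, built so that the
#' first window sits exactly at the lower GC bound: substituting the
#' flagged run base with `A` or `T` would push that window (and the whole
#' sequence) below 40% GC, so the only valid single-base fix is a
#' substitution with `G`.
#'
#' @return A sequence string.
#' @examples
#' cs <- constraint_set(target_length = 30)
#' find_violations(example_homopolymer_read(), cs)
#' repair_sequence(example_window_run_read(), cs)
#' @export
example_homopolymer_read <- function() {
  # windows:     [0,15)           [15,30)          [30,32)
  paste0("CTGACAAAAATGCGT", "ACGTTAGCATGCTAA", "GT")
}

#' @rdname example_homopolymer_read
#' @export
example_window_run_read <- function() {
  # run of four C at 0-based positions 12..15, spanning the window border;
  # window 1 holds exactly 6 of 15 GC, the lower bound
  paste0("ATGATTCAGAAT", "CCCC", "ATGAGTATGCAGTA")
}
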