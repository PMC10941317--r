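#' PHRED score conversions
#'
#' A PHRED quality score encodes the probability `Pe` that a base call is
#' wrong as `Q = -10 * log10(Pe)`. FASTQ files store one score per base as
#' the ASCII character with code `Q + 33` (Sanger offset).
#'
#' @param pe per-base error probability, in (0, 1].
#' @return `phred_from_prob()` returns the (real-valued) quality score;
#'   `prob_from_phred()` inverts it.
#' @examples
#' phred_from_prob(0.1)    # 10
#' phred_from_prob(0.0001) # 40
#' prob_from_phred(20)     # 0.01
#' @export
phred_from_prob <- function(pe) {
  if (any(!is.finite(pe)) || any(pe <= 0) || any(pe > 1)) {
    stop("error probability must lie in (0, 1]")
  }
  -10 * log10(pe)
}

#' @rdname phred_from_prob
#' @param q PHRED quality score (>= 0).
#' @export
prob_from_phred <- function(q) {
  if (any(q < 0)) stop("PHRED scores must be >= 0")
  10^(-q / 10)
}

#' Decode / encode Sanger (+33) quality strings
#'
#' @param s a quality string as found on line 4 of a FASTQ record.
#' @return `decode_quals()` returns an integer vector of PHRED scores;
#'   `encode_quals()` returns the ASCII quality string.
#' @examples
#' decode_quals("IIII") # 40 40 40 40
#' encode_quals(c(0L, 40L, 93L))
#' @export
decode_quals <- function(s) {
  if (nchar(s) == 0L) return(integer())
  q <- utf8ToInt(s) - 33L
  if (any(q < 0L) || any(q > 93L)) {
    stop("quality string contains characters outside the Sanger +33 range")
  }
  q
}

#' @rdname decode_quals
#' @param q integer vector of PHRED scores in 0..93.
#' @export
encode_quals <- function(q) {
  q <- as.integer(q)
  if (length(q) == 0L) return("")
  if (any(q < 0L) || any(q > 93L)) stop("PHRED scores must be in [0, 93]")
  intToUtf8(q + 33L)
}
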