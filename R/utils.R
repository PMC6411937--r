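BASES <- c("A", "C", "G", "T")

#' GC fraction of nucleotide sequences
#'
#' @param x Character vector of sequences over \{A,C,G,T,N\}.
#' @return Numeric vector of GC fractions (N bases excluded from the
#'   denominator; all-N or empty sequences give `NaN`).
#' @export
#' @examples
#' gc_fraction(c("GGCC", "ATAT", "GCAT"))
gc_fraction <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(numeric(0))
  ss <- Biostrings::DNAStringSet(x)
  counts <- Biostrings::letterFrequency(ss, letters = c("GC", "AT"))
  as.numeric(counts[, "G|C"] / (counts[, "G|C"] + counts[, "A|T"]))
}

## Hamming distance between equal-length strings; `b` is a scalar.
hamming_to <- function(x, b) {
  br <- charToRaw(b)
  vapply(x, function(s) {
    sr <- charToRaw(s)
    if (length(sr) != length(br)) return(NA_integer_)
    sum(sr != br)
  }, integer(1), USE.NAMES = FALSE)
}

## n random sequences of width w with i.i.d. bases at given GC fraction
random_seq <- function(n, w, gc) {
  if (n == 0L) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(sample(BASES, n * w, replace = TRUE, prob = p), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## split an integer seed into k reproducible sub-seeds below 2^31
split_seed <- function(seed, k) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "riboqc_error")
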