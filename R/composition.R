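#' Per-position nucleotide composition of footprints
#'
#' For each 5'-end-anchored position `p` (1-based) the fraction of reads of
#' length at least `p` carrying each base at that position. Reads of
#' different lengths therefore contribute to different denominators; `N`
#' bases are excluded from the fractions and tracked in `n_other`.
#'
#' The input is typically restricted to CDS-mapped footprints before calling
#' (see [footprint_regions()]), matching how composition plots are drawn for
#' digestion diagnostics.
#'
#' @param footprints Footprint tibble carrying a `sequence` column (or a bare
#'   character vector of sequences).
#' @param max_position Last position to report (default: longest read).
#' @return Tibble of class `composition_matrix`: `position`, `A`, `C`, `G`,
#'   `T`, `n_reads`, `n_other`.
#' @export
#' @examples
#' nucleotide_composition(c("ACG", "AAG"))
nucleotide_composition <- function(footprints, max_position = NULL) {
  seqs <- if (is.character(footprints)) footprints else footprints$sequence
  if (length(seqs) == 0L) stop_bad_arg("no sequences to profile")
  lens <- nchar(seqs)
  P <- as.integer(max_position %||% max(lens))

  rows <- lapply(seq_len(P), function(p) {
    s <- seqs[lens >= p]
    ch <- substr(s, p, p)
    cnt <- c(A = sum(ch == "A"), C = sum(ch == "C"),
             G = sum(ch == "G"), T = sum(ch == "T"))
    tot <- sum(cnt)
    tibble(position = p,
           A = cnt[["A"]] / tot, C = cnt[["C"]] / tot,
           G = cnt[["G"]] / tot, T = cnt[["T"]] / tot,
           n_reads = length(s), n_other = length(s) - tot)
  })
  out <- bind_rows(rows)
  class(out) <- c("composition_matrix", class(out))
  out
}

#' Mean GC percentage within a position window
#'
#' Averages the per-position G+C fraction of a [nucleotide_composition()]
#' matrix over a 1-based inclusive window and reports a percentage. The
#' standard diagnostic windows are positions 10-20 for ribosome footprints
#' and 10-65 for mRNA-seq reads.
#'
#' @param composition A `composition_matrix` tibble.
#' @param window Integer pair, 1-based inclusive positions.
#' @return Mean GC content over the window, in percent.
#' @export
#' @examples
#' windowed_gc(nucleotide_composition(c("GGGGG", "GCGCG")), c(1, 5))
windowed_gc <- function(composition, window = c(10L, 20L)) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1] > window[2]) {
    stop_bad_arg("window must be an increasing position pair")
  }
  rows <- composition$position >= window[1] & composition$position <= window[2]
  if (sum(rows) != window[2] - window[1] + 1L || any(composition$n_reads[rows] == 0L)) {
    stop_bad_arg("window [%d, %d] exceeds the profiled read length", window[1], window[2])
  }
  mean(composition$G[rows] + composition$C[rows]) * 100
}

#' Modal footprint length
#'
#' The representative footprint length of a sample: the argmax of the length
#' histogram, with ties broken toward the smallest length.
#'
#' @param x A footprint tibble with a `length` column, a named count vector,
#'   or a tibble with `length` and `count`/`n` columns.
#' @return Integer modal length (nt).
#' @export
#' @examples
#' length_peak(c(`28` = 10, `29` = 3))
length_peak <- function(x) {
  h <- length_histogram(x)
  if (nrow(h) == 0L || sum(h$count) == 0) stop_bad_arg("empty length histogram")
  h <- h[h$count == max(h$count), ]
  min(h$length)
}

#' @rdname length_peak
#' @return `length_histogram()`: tibble with `length`, `count`.
#' @export
length_histogram <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("length", "count") %in% names(x))) {
      return(tibble(length = as.integer(x$length), count = as.numeric(x$count)))
    }
    if (all(c("length", "n") %in% names(x)) && !"read_id" %in% names(x)) {
      return(tibble(length = as.integer(x$length), count = as.numeric(x$n)))
    }
    x <- x$length
  }
  if (!is.null(names(x)) && !anyNA(suppressWarnings(as.integer(names(x))))) {
    return(tibble(length = as.integer(names(x)), count = as.numeric(x)))
  }
  tab <- table(x)
  tibble(length = as.integer(names(tab)), count = as.numeric(tab))
}
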