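#' Generate a synthetic transcriptome
#'
#' Builds transcript models (5'UTR / CDS / 3'UTR) with independently
#' controlled GC content per region. The CDS starts with `AUG`, ends with a
#' stop codon, and its length is a multiple of 3. Coordinates are 0-based
#' half-open: `[0, utr5_end)` is the 5'UTR, `[utr5_end, cds_end)` the CDS and
#' `[cds_end, length)` the 3'UTR.
#'
#' The default CDS GC target of 0.60 reflects the GC-richness of mammalian
#' coding sequence (roughly 60% in mouse), while UTRs are closer to neutral.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param cds_gc_target Target GC fraction of the CDS body, in (0, 1].
#' @param utr_gc_target Target GC fraction of the UTRs, in (0, 1).
#' @param length_range Integer pair: total transcript length is drawn
#'   uniformly from this range (minimum 90 nt).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble with columns `id`, `sequence`, `utr5_end`, `cds_end`,
#'   `length`.
#' @export
#' @examples
#' tx <- generate_transcriptome(5, seed = 1)
#' substr(tx$sequence[1], tx$utr5_end[1] + 1, tx$utr5_end[1] + 3) # "ATG"
generate_transcriptome <- function(n_transcripts,
                                   cds_gc_target = 0.60,
                                   utr_gc_target = 0.45,
                                   length_range = c(500L, 2000L),
                                   seed = NULL) {
  if (n_transcripts < 1) stop_bad_arg("n_transcripts must be >= 1")
  for (g in c(cds_gc_target, utr_gc_target)) {
    if (!is.finite(g) || g <= 0 || g > 1) {
      stop_bad_arg("GC target %s is infeasible for the {A,C,G,T} alphabet; need a fraction in (0, 1]", format(g))
    }
  }
  length_range <- as.integer(round(length_range))
  if (length(length_range) != 2L || any(length_range < 90L) ||
      length_range[1] > length_range[2]) {
    stop_bad_arg("length_range must be an increasing integer pair with minimum >= 90")
  }
  if (!is.null(seed)) set.seed(seed)

  len <- sample(seq(length_range[1], length_range[2]), n_transcripts, replace = TRUE)
  utr5 <- pmax(12L, as.integer(round(0.12 * len)))
  utr3_nom <- pmax(15L, as.integer(round(0.25 * len)))
  cds <- ((len - utr5 - utr3_nom) %/% 3L) * 3L
  cds <- pmax(cds, 6L)

  seqs <- vapply(seq_len(n_transcripts), function(i) {
    body_len <- cds[i] - 6L
    body <- if (body_len > 0) random_seq(1L, body_len, cds_gc_target) else ""
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    paste0(
      random_seq(1L, utr5[i], utr_gc_target),
      "ATG", body, stop_codon,
      random_seq(1L, len[i] - utr5[i] - cds[i], utr_gc_target)
    )
  }, character(1))

  tibble(
    id = sprintf("tx%04d", seq_len(n_transcripts)),
    sequence = seqs,
    utr5_end = utr5,
    cds_end = utr5 + cds,
    length = len
  )
}

## validate the transcript-model invariants; used by consumers of annotations
validate_transcripts <- function(tx) {
  stopifnot(all(c("id", "sequence", "utr5_end", "cds_end", "length") %in% names(tx)))
  ok <- tx$utr5_end >= 0 & tx$utr5_end < tx$cds_end & tx$cds_end <= tx$length &
    (tx$cds_end - tx$utr5_end) %% 3L == 0L &
    nchar(tx$sequence) == tx$length
  if (!all(ok)) {
    stop_bad_arg("invalid transcript model(s): %s",
                 paste(tx$id[!ok], collapse = ", "))
  }
  invisible(tx)
}

#' Serialise a transcript annotation
#'
#' Plain TSV round trip for the transcript model table (id, sequence, region
#' boundaries), so annotations can be shared with the command-line tools.
#'
#' @param transcripts Transcript tibble.
#' @param path TSV path.
#' @return `path` invisibly; `read_transcripts()` returns the tibble.
#' @export
write_transcripts <- function(transcripts, path) {
  validate_transcripts(transcripts)
  readr::write_tsv(transcripts, path)
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", sequence = "c", utr5_end = "i", cds_end = "i", length = "i"
  ))
  validate_transcripts(tx)
  tx
}
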