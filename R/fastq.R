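#' Describe the layout of a raw sequencing read
#'
#' A read layout is an ordered list of segments; exactly one segment (the
#' insert) has variable width. The default matches a 5 nt sample barcode
#' followed by an 8 nt UMI, the footprint insert, and the 3' adapter.
#'
#' @param barcode,umi Widths (nt) of the fixed-width segments; a width of 0
#'   removes the segment.
#' @param order Segment order from the 5' end; must contain `"insert"`
#'   exactly once and may contain `"barcode"`, `"umi"`, `"adapter"`.
#' @return A tibble of class `read_layout` with columns `segment`, `width`
#'   (`NA` for variable-width segments).
#' @export
#' @examples
#' read_layout()
#' read_layout(umi = 0)  # no UMI in this library
read_layout <- function(barcode = 5L, umi = 8L,
                        order = c("barcode", "umi", "insert", "adapter")) {
  widths <- c(barcode = as.integer(barcode), umi = as.integer(umi),
              insert = NA_integer_, adapter = NA_integer_)
  if (sum(order == "insert") != 1L) stop_bad_arg("layout needs exactly one insert segment")
  if (!all(order %in% names(widths))) stop_bad_arg("unknown layout segment")
  out <- tibble(segment = order, width = unname(widths[order]))
  out <- out[!(out$segment %in% c("barcode", "umi") & out$width == 0L), ]
  class(out) <- c("read_layout", class(out))
  out
}

## total width of fixed segments before `segment`, among those still present
layout_offset <- function(layout, segment, removed = character(0)) {
  pre <- layout$segment[seq_len(match(segment, layout$segment) - 1L)]
  pre <- setdiff(pre, c(removed, "insert", "adapter"))
  sum(layout$width[match(pre, layout$segment)], 0L)
}

layout_width <- function(layout, segment) {
  i <- match(segment, layout$segment)
  if (is.na(i)) 0L else layout$width[i]
}

#' Write simulated reads to FASTQ
#'
#' Assembles each record according to the read layout — by default
#' `[barcode][UMI][insert][adapter]` — and writes a 4-line Phred+33 FASTQ
#' file. Base qualities are constant (Q37) by default. When `read_length` is
#' given and the assembled read is longer, the adapter is truncated; the
#' insert never is.
#'
#' @param reads Tibble with `read_id`, `sequence` (the insert) and, as
#'   required by the layout, `barcode` and `umi` columns.
#' @param path Output FASTQ path.
#' @param layout A [read_layout()].
#' @param adapter 3' adapter sequence appended after the insert.
#' @param read_length Optional sequencing read-length budget (nt).
#' @param quality_char Single Phred+33 quality character (default `"F"`, Q37).
#' @return `path`, invisibly.
#' @export
#' @examples
#' tx <- generate_transcriptome(5, seed = 1)
#' sim <- simulate_footprints(tx, digestion_params(seed = 2), 20)
#' fq <- tempfile(fileext = ".fastq")
#' emit_fastq(sim$reads, fq)
emit_fastq <- function(reads, path, layout = read_layout(),
                       adapter = ribo_adapter(), read_length = NULL,
                       quality_char = "F") {
  pieces <- lapply(layout$segment, function(seg) {
    switch(seg,
      barcode = reads$barcode,
      umi = reads$umi,
      insert = reads$sequence,
      adapter = rep(adapter, nrow(reads))
    )
  })
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  for (i in seq_along(pieces)) {
    w <- layout$width[i]
    if (!is.na(w) && any(nchar(pieces[[i]]) != w)) {
      stop_bad_arg("segment '%s' does not match its layout width %d", layout$segment[i], w)
    }
  }
  seqs <- do.call(paste0, pieces)
  if (!is.null(read_length)) {
    min_keep <- nchar(do.call(paste0, pieces[layout$segment != "adapter"]))
    seqs <- substring(seqs, 1L, pmax(read_length, min_keep))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (4-line records, Phred+33).
#' @return Tibble with `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) {
    return(tibble(read_id = character(0), sequence = character(0),
                  qualities = character(0)))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    qualities = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write / read a simulation truth table
#'
#' Plain TSV serialisation of the per-read ground truth emitted by
#' [simulate_footprints()].
#'
#' @param truth Truth tibble.
#' @param path TSV path.
#' @return `path` invisibly; `read_truth()` returns the tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", transcript = "c", start = "i", length = "i",
    psite = "i", psite_offset = "i", region = "c", umi = "c",
    duplicate_of = "c", barcode = "c", sample = "c", sequence = "c"
  ))
}
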