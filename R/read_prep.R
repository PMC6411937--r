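#' Demultiplex pooled reads by sample barcode
#'
#' Assigns each read to the unique whitelist barcode within `max_mismatch`
#' Hamming distance of its barcode segment, strips the barcode segment from
#' sequence and qualities, and routes everything else to the unassigned pool.
#' The whitelist must have pairwise Hamming distance greater than
#' `2 * max_mismatch` so assignments are unambiguous.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `qualities`
#'   (e.g. from [read_fastq()]).
#' @param barcode_whitelist Character vector of barcodes (width per layout).
#' @param max_mismatch Maximum mismatches tolerated (default 1).
#' @param layout A [read_layout()] locating the barcode segment.
#' @return The input tibble with the barcode segment removed from
#'   `sequence`/`qualities`, plus columns `barcode_observed` and `barcode`
#'   (the assigned whitelist barcode, `NA` for unassigned reads).
#' @export
demultiplex <- function(reads, barcode_whitelist, max_mismatch = 1L,
                        layout = read_layout()) {
  width <- layout_width(layout, "barcode")
  if (width == 0L) stop_bad_arg("layout has no barcode segment")
  if (any(nchar(barcode_whitelist) != width)) {
    stop_bad_arg("whitelist barcodes must all have width %d", width)
  }
  if (length(barcode_whitelist) > 1L) {
    pairs <- utils::combn(barcode_whitelist, 2L)
    d <- mapply(function(a, b) hamming_to(a, b), pairs[1, ], pairs[2, ])
    if (any(d <= 2L * max_mismatch)) {
      stop_bad_arg(
        "ambiguous whitelist: barcode pairs within Hamming distance %d cannot be demultiplexed at %d mismatch(es)",
        2L * max_mismatch, max_mismatch)
    }
  }
  off <- layout_offset(layout, "barcode")
  observed <- substring(reads$sequence, off + 1L, off + width)

  dist <- vapply(barcode_whitelist, function(b) hamming_to(observed, b),
                 integer(length(observed)))
  dist <- matrix(dist, ncol = length(barcode_whitelist))
  best <- apply(dist, 1L, which.min)
  bestd <- dist[cbind(seq_along(best), best)]
  assigned <- ifelse(!is.na(bestd) & bestd <= max_mismatch,
                     barcode_whitelist[best], NA_character_)

  out <- reads
  out$sequence <- paste0(substring(reads$sequence, 1L, off),
                         substring(reads$sequence, off + width + 1L, nchar(reads$sequence)))
  if ("qualities" %in% names(out)) {
    out$qualities <- paste0(substring(reads$qualities, 1L, off),
                            substring(reads$qualities, off + width + 1L, nchar(reads$qualities)))
  }
  out$barcode_observed <- observed
  out$barcode <- assigned
  out
}

#' Trim the 3' adapter from reads
#'
#' Cutadapt-style 3'-anchored prefix matching without indels: every position
#' at which a prefix of the adapter could run to the read's 3' end is scored
#' (matches minus mismatches), matches need overlap of at least `min_overlap`
#' and a mismatch rate of at most `max_error_rate`, and among equal scores
#' the earliest start wins (trimming the most, which is conservative against
#' adapter read-through). Reads without an acceptable match are left
#' untouched and flagged.
#'
#' @param reads Tibble with `sequence` and optionally `qualities`.
#' @param adapter Adapter sequence (default [ribo_adapter()]).
#' @param min_overlap Minimum adapter prefix length considered (>= 3).
#' @param max_error_rate Maximum mismatch rate in `[0, 0.5)`.
#' @return The tibble with trimmed `sequence`/`qualities` and a logical
#'   `trimmed` column.
#' @export
trim_adapter <- function(reads, adapter = ribo_adapter(),
                         min_overlap = 5L, max_error_rate = 0.1) {
  if (min_overlap < 3L) stop_bad_arg("min_overlap must be >= 3")
  if (max_error_rate < 0 || max_error_rate >= 0.5) {
    stop_bad_arg("max_error_rate must lie in [0, 0.5)")
  }
  araw <- charToRaw(adapter)
  alen <- length(araw)

  cut_at <- vapply(reads$sequence, function(s) {
    rr <- charToRaw(s)
    L <- length(rr)
    if (L < min_overlap) return(NA_integer_)
    smin <- max(1L, L - alen + 1L) # adapter prefix must reach the read end
    starts <- seq.int(smin, L - min_overlap + 1L)
    if (length(starts) == 0L) return(NA_integer_)
    best_s <- NA_integer_
    best_score <- -Inf
    for (s0 in starts) {
      ov <- L - s0 + 1L
      mm <- sum(rr[s0:L] != araw[seq_len(ov)])
      if (mm > max_error_rate * ov) next
      score <- ov - 2L * mm
      if (score > best_score) { # ties keep the earlier (already stored) start
        best_score <- score
        best_s <- s0
      }
    }
    best_s
  }, integer(1), USE.NAMES = FALSE)

  out <- reads
  hit <- !is.na(cut_at)
  out$sequence[hit] <- substring(reads$sequence[hit], 1L, cut_at[hit] - 1L)
  if ("qualities" %in% names(out)) {
    out$qualities[hit] <- substring(reads$qualities[hit], 1L, cut_at[hit] - 1L)
  }
  out$trimmed <- hit
  out
}

#' Extract the UMI segment into read metadata
#'
#' Populates a `umi` column and removes the UMI segment from
#' `sequence`/`qualities`. Reads too short to contain all fixed-width
#' segments, or whose insert is empty after extraction, are flagged
#' `dropped`. Call after [demultiplex()] (the barcode segment is assumed
#' already stripped; see `removed`).
#'
#' @param reads Tibble with `sequence` and optionally `qualities`.
#' @param layout A [read_layout()].
#' @param removed Segments already stripped from the reads (default
#'   `"barcode"`).
#' @return The tibble with `umi` and logical `dropped` columns and the UMI
#'   removed from the sequence.
#' @export
extract_umi <- function(reads, layout = read_layout(), removed = "barcode") {
  width <- layout_width(layout, "umi")
  if (width == 0L) {
    out <- reads
    out$umi <- ""
    out$dropped <- FALSE
    return(out)
  }
  off <- layout_offset(layout, "umi", removed = removed)
  len <- nchar(reads$sequence)
  too_short <- len < off + width
  out <- reads
  out$umi <- ifelse(too_short, NA_character_,
                    substring(reads$sequence, off + 1L, off + width))
  out$sequence <- ifelse(too_short, reads$sequence,
                         paste0(substring(reads$sequence, 1L, off),
                                substring(reads$sequence, off + width + 1L, len)))
  if ("qualities" %in% names(out)) {
    out$qualities <- ifelse(too_short, reads$qualities,
                            paste0(substring(reads$qualities, 1L, off),
                                   substring(reads$qualities, off + width + 1L, len)))
  }
  out$dropped <- too_short | nchar(out$sequence) == 0L
  out
}

#' Run the full pre-mapping pipeline on a FASTQ file
#'
#' [read_fastq()] then [demultiplex()], [extract_umi()] and [trim_adapter()],
#' with an accounting attribute `counts` satisfying
#' `assigned + unassigned + dropped = input`.
#'
#' @inheritParams demultiplex
#' @inheritParams trim_adapter
#' @param path Input FASTQ.
#' @return Tibble of processed reads (unassigned and dropped reads retained,
#'   flagged); `attr(, "counts")` holds the partition counts.
#' @export
prep_reads <- function(path, barcode_whitelist, adapter = ribo_adapter(),
                       layout = read_layout(), max_mismatch = 1L,
                       min_overlap = 5L, max_error_rate = 0.1) {
  reads <- read_fastq(path)
  reads <- demultiplex(reads, barcode_whitelist, max_mismatch, layout)
  reads <- extract_umi(reads, layout)
  reads <- trim_adapter(reads, adapter, min_overlap, max_error_rate)
  counts <- c(
    input = nrow(reads),
    assigned = sum(!is.na(reads$barcode) & !reads$dropped),
    unassigned = sum(is.na(reads$barcode)),
    dropped = sum(!is.na(reads$barcode) & reads$dropped)
  )
  attr(reads, "counts") <- counts
  reads
}
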