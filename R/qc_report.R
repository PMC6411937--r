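#' Per-sample footprint QC report
#'
#' Bundles the digestion-diagnostic metrics for one sample: windowed GC of
#' CDS-mapped footprints, length histogram and modal length, region
#' fractions, P-site offsets, and frame preference at the best-resolving
#' length.
#'
#' P-site offsets are estimated from the data when a length class has enough
#' reads ([estimate_psite_offsets()]); otherwise the canonical offsets are
#' used with a message.
#'
#' @param footprints Footprint tibble for one sample (deduplicated unique
#'   reads).
#' @param transcripts Transcript tibble.
#' @param sample_id Sample label.
#' @param gc_window GC window, 1-based inclusive positions (default 10-20).
#' @param min_reads_offset Threshold passed to [estimate_psite_offsets()].
#' @return Object of class `qc_report`.
#' @export
#' @examples
#' tx <- generate_transcriptome(20, seed = 1)
#' sim <- simulate_footprints(tx, digestion_params(seed = 3), 2000)
#' fp <- load_sim_footprints(sim)
#' rep <- qc_report(fp, tx, "demo")
#' glance(rep)
qc_report <- function(footprints, transcripts, sample_id = "sample",
                      gc_window = c(10L, 20L), min_reads_offset = 200L) {
  validate_transcripts(transcripts)
  offsets <- tryCatch(
    estimate_psite_offsets(footprints, transcripts, min_reads = min_reads_offset),
    riboqc_error = function(e) {
      message("falling back to canonical P-site offsets: ", conditionMessage(e))
      NULL
    }
  )
  regions <- footprint_regions(footprints, transcripts, offsets)
  cds_fp <- footprints[!is.na(regions) & regions == "cds", ]
  comp <- nucleotide_composition(cds_fp)
  structure(list(
    sample = sample_id,
    n_reads = nrow(footprints),
    composition = comp,
    gc_window = gc_window,
    gc_window_mean = windowed_gc(comp, gc_window),
    length_histogram = length_histogram(footprints),
    length_peak = length_peak(footprints),
    region_fractions = assign_regions(footprints, transcripts, offsets),
    psite_offsets = offsets,
    frame = frame_preference(footprints, transcripts, offsets)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s (%d footprints)\n", x$sample, x$n_reads))
  cat(sprintf("  GC %.1f%% in window [%d, %d]; modal length %d nt\n",
              x$gc_window_mean, x$gc_window[1], x$gc_window[2], x$length_peak))
  rf <- setNames(x$region_fractions$fraction, x$region_fractions$region)
  cat(sprintf("  regions: 5'UTR %.3f / CDS %.3f / 3'UTR %.3f\n",
              rf["utr5"], rf["cds"], rf["utr3"]))
  cat(sprintf("  frame (length %d): f0 = %.3f\n",
              x$frame$best_length, x$frame$frame_fractions["f0"]))
  invisible(x)
}

#' @describeIn qc_report One-row tibble summary of a QC report.
#' @param x A `qc_report`.
#' @param ... Unused.
#' @export
glance.qc_report <- function(x, ...) {
  rf <- setNames(x$region_fractions$fraction, x$region_fractions$region)
  tibble(
    sample = x$sample,
    n_reads = x$n_reads,
    gc_window_mean = x$gc_window_mean,
    length_peak = x$length_peak,
    utr5_fraction = unname(rf["utr5"]),
    cds_fraction = unname(rf["cds"]),
    utr3_fraction = unname(rf["utr3"]),
    best_frame_length = x$frame$best_length,
    frame_f0 = unname(x$frame$frame_fractions["f0"])
  )
}

#' Serialise a QC report
#'
#' Writes `<prefix>.json` (the full report) and `<prefix>_summary.tsv` (the
#' [glance()] row).
#'
#' @param x A `qc_report`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_qc_report <- function(x, prefix) {
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, "_summary.tsv")
  payload <- list(
    sample = x$sample,
    n_reads = x$n_reads,
    gc_window = x$gc_window,
    gc_window_mean = x$gc_window_mean,
    length_peak = x$length_peak,
    length_histogram = x$length_histogram,
    region_fractions = x$region_fractions,
    psite_offsets = x$psite_offsets,
    frame_per_length = x$frame$per_length,
    best_frame_length = x$frame$best_length,
    frame_fractions = as.list(x$frame$frame_fractions)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  readr::write_tsv(glance(x), tsv_path)
  invisible(c(json_path, tsv_path))
}

#' Footprints from a simulation result
#'
#' Convenience bridge from [simulate_footprints()] truth to the footprint
#' tibble consumed by the QC functions (all reads start as category
#' `unique`; run [mark_duplicates()] to flag PCR duplicates).
#'
#' @param sim List returned by [simulate_footprints()].
#' @return Footprint tibble.
#' @export
load_sim_footprints <- function(sim) {
  tr <- sim$truth
  tibble(read_id = tr$read_id, reference = tr$transcript, start = tr$start,
         length = tr$length, strand = "+", sequence = tr$sequence,
         umi = tr$umi, category = "unique", sample = tr$sample)
}
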