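#' Load aligned footprints from disk
#'
#' Supported dialects:
#' * `"truth"` — the simulator truth TSV (see [write_truth()]);
#' * `"tsv"` — an 8-column SAM-like alignment table with header
#'   `read_id reference start length strand sequence umi align_count`
#'   (`start` 0-based; reads with `align_count > 1` are categorised
#'   `multimapped`);
#' * `"bed"` — BED6/BED12 (via rtracklayer), with the UMI carried in the read
#'   name after the last `_` delimiter.
#'
#' Coordinates are normalised to 0-based half-open throughout.
#'
#' @param path Input file.
#' @param format One of `"truth"`, `"tsv"`, `"bed"`.
#' @param transcripts Optional transcript tibble; when given, records whose
#'   reference is not annotated raise an error listing the offenders.
#' @return Footprint tibble with columns `read_id`, `reference`, `start`,
#'   `length`, `strand`, `sequence`, `umi`, `category`.
#' @export
load_alignments <- function(path, format = c("truth", "tsv", "bed"),
                            transcripts = NULL) {
  format <- match.arg(format)
  fp <- switch(format,
    truth = {
      tr <- read_truth(path)
      tibble(read_id = tr$read_id, reference = tr$transcript,
             start = tr$start, length = tr$length, strand = "+",
             sequence = tr$sequence, umi = tr$umi, category = "unique")
    },
    tsv = load_alignments_tsv(path),
    bed = load_alignments_bed(path)
  )
  if (any(fp$start < 0 | fp$length <= 0)) {
    bad <- which(fp$start < 0 | fp$length <= 0)[1]
    stop_bad_arg("malformed record at data line %d: start must be >= 0 and length > 0", bad)
  }
  if (!is.null(transcripts)) {
    unknown <- setdiff(unique(fp$reference), transcripts$id)
    if (length(unknown)) {
      stop_bad_arg("unknown reference id(s): %s",
                   paste(head(unknown, 10), collapse = ", "))
    }
  }
  fp
}

load_alignments_tsv <- function(path) {
  cols <- c("read_id", "reference", "start", "length", "strand",
            "sequence", "umi", "align_count")
  x <- tryCatch(
    readr::read_tsv(path, col_types = "cciiccci", show_col_types = FALSE),
    error = function(e) stop_bad_arg("malformed alignment TSV: %s", conditionMessage(e))
  )
  if (!all(cols %in% names(x))) {
    stop_bad_arg("alignment TSV must have columns: %s", paste(cols, collapse = ", "))
  }
  bad <- which(is.na(x$start) | is.na(x$length) | is.na(x$align_count))
  if (length(bad)) stop_bad_arg("malformed record at data line %d", bad[1])
  tibble(read_id = x$read_id, reference = x$reference,
         start = as.integer(x$start), length = as.integer(x$length),
         strand = x$strand, sequence = x$sequence, umi = x$umi,
         category = ifelse(x$align_count > 1L, "multimapped", "unique"))
}

load_alignments_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_bad_arg("BED input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name %||% as.character(seq_along(gr))
  umi <- sub(".*_", "", name)
  umi[!grepl("_", name)] <- NA_character_
  tab <- table(name)
  tibble(
    read_id = name,
    reference = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # GRanges is 1-based
    length = GenomicRanges::width(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    sequence = NA_character_,
    umi = umi,
    category = ifelse(as.integer(tab[name]) > 1L, "multimapped", "unique")
  )
}

#' Mark UMI-based PCR duplicates
#'
#' Within each key `(reference, start, strand, length, umi)` the
#' first-encountered unique footprint is retained and the rest are
#' re-categorised `duplicate`. Footprints already categorised as anything
#' other than `unique` pass through untouched.
#'
#' @param footprints Footprint tibble; unique-category rows must carry UMIs.
#' @return The tibble with updated `category`.
#' @export
#' @examples
#' fp <- tibble::tibble(read_id = c("a", "b"), reference = "tx1", start = 0L,
#'                      length = 28L, strand = "+", sequence = NA,
#'                      umi = "ACGTACGT", category = "unique")
#' table(mark_duplicates(fp)$category)
mark_duplicates <- function(footprints) {
  uniq <- footprints$category == "unique"
  missing_umi <- uniq & (is.na(footprints$umi) | footprints$umi == "")
  if (any(missing_umi)) {
    stop_bad_arg("missing UMI on unique footprint(s): %s",
                 paste(head(footprints$read_id[missing_umi], 5), collapse = ", "))
  }
  key <- paste(footprints$reference, footprints$start, footprints$strand,
               footprints$length, footprints$umi, sep = "\r")
  dup <- uniq & duplicated(ifelse(uniq, key, paste0("\n", seq_along(key))))
  out <- footprints
  out$category[dup] <- "duplicate"
  out
}

#' Summarise mapping categories
#'
#' The per-sample accounting of where reads went: unique / duplicate /
#' multimapped / unmapped / contaminant fractions, as in stacked mapping-rate
#' bar plots.
#'
#' @param footprints Footprint tibble with a `category` column.
#' @return Tibble with `category`, `n`, `fraction` (fractions sum to 1).
#' @export
summarize_mapping <- function(footprints) {
  out <- footprints %>%
    count(.data$category, name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n))
  out
}
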