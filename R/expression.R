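## tibble (gene + sample columns) <-> numeric matrix
mat_from_tbl <- function(x) {
  stopifnot("gene" %in% names(x))
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

tbl_from_mat <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(gene = rownames(m)), out)
  out
}

#' Count footprints on trimmed CDS
#'
#' Gene-level quantification for expression QC: counts deduplicated unique
#' footprints whose P-site lies in `[cds_start + trim, cds_end - trim)`,
#' excluding the first and last `trim` nt of each CDS to avoid the
#' translation initiation and termination peaks. Transcripts whose trimmed
#' CDS is empty are excluded (with a message). A `sample` column in the
#' footprints yields one count column per sample.
#'
#' @param footprints Footprint tibble; rows with `category != "unique"` are
#'   ignored.
#' @param transcripts Transcript tibble (one representative transcript per
#'   gene).
#' @param trim Nucleotides trimmed from each CDS end (default 30).
#' @param offsets Per-length P-site offsets (see [footprint_psites()]).
#' @return Count tibble: `gene` column plus one integer column per sample.
#' @export
count_cds <- function(footprints, transcripts, trim = 30L, offsets = NULL) {
  validate_transcripts(transcripts)
  if (trim < 0) stop_bad_arg("trim must be >= 0")
  keep_tx <- transcripts$cds_end - transcripts$utr5_end > 2L * trim
  if (!all(keep_tx)) {
    message(sum(!keep_tx), " transcript(s) excluded: trimmed CDS empty")
  }
  tx <- transcripts[keep_tx, ]
  if ("category" %in% names(footprints)) {
    footprints <- footprints[footprints$category == "unique", ]
  }
  if (!"sample" %in% names(footprints)) footprints$sample <- "sample1"

  psite <- footprint_psites(footprints, offsets)
  i <- match(footprints$reference, tx$id)
  in_window <- !is.na(i) &
    psite >= tx$utr5_end[i] + trim &
    psite < tx$cds_end[i] - trim

  counted <- tibble(gene = footprints$reference[in_window],
                    sample = footprints$sample[in_window]) %>%
    count(.data$gene, .data$sample) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "n", values_fill = 0L)
  out <- tibble(gene = tx$id) %>% left_join(counted, by = "gene")
  out[is.na(out)] <- 0L
  ## keep sample column order stable
  samp <- unique(footprints$sample)
  out[, c("gene", intersect(samp, names(out)))]
}

#' Filter genes by minimum mean count
#'
#' Retains genes with at least `min_mean` average reads across all samples
#' (default 5).
#'
#' @param counts Count tibble (`gene` + sample columns).
#' @param min_mean Minimum mean count.
#' @return Filtered count tibble.
#' @export
filter_low <- function(counts, min_mean = 5) {
  if (min_mean < 0) stop_bad_arg("min_mean must be >= 0")
  m <- mat_from_tbl(counts)
  counts[rowMeans(m) >= min_mean, ]
}

#' Size-factor normalisation and log2 transform
#'
#' Median-of-ratios size factors (the reference is the per-gene geometric
#' mean over genes with nonzero counts in every sample) followed by
#' `log2(count / size_factor + pseudocount)`. This is a simple variance-
#' unstabilised stand-in for the regularised log transform: absolute values
#' differ from rlog, but the correlation and PCA structure used for QC is
#' preserved. When no gene is nonzero in all samples, total-count size
#' factors are used with a warning.
#'
#' @param counts Count tibble (`gene` + sample columns).
#' @param pseudocount Added inside the log (default 1).
#' @return Transformed tibble; `attr(, "size_factors")` holds the factors.
#' @export
normalize_log <- function(counts, pseudocount = 1) {
  m <- mat_from_tbl(counts)
  if (ncol(m) < 1L || nrow(m) < 1L) stop_bad_arg("empty count matrix")
  common <- rowSums(m > 0) == ncol(m)
  if (any(common)) {
    logref <- rowMeans(log(m[common, , drop = FALSE]))
    ## median taken in log space (geometric interpolation at even counts)
    sf <- apply(m[common, , drop = FALSE], 2, function(col) {
      exp(median(log(col) - logref))
    })
  } else {
    warn("no gene has nonzero counts in every sample; using total-count size factors")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  trans <- log2(sweep(m, 2, sf, "/") + pseudocount)
  out <- tbl_from_mat(trans)
  attr(out, "size_factors") <- sf
  out
}

#' Pairwise sample correlation matrix
#'
#' Pearson correlation between samples on (typically log-transformed)
#' expression values — the reproducibility readout of scatter-plot panels.
#'
#' @param x Expression tibble (`gene` + sample columns).
#' @return Tibble: `sample` column plus one correlation column per sample;
#'   symmetric with unit diagonal.
#' @export
pairwise_correlation <- function(x) {
  m <- mat_from_tbl(x)
  if (ncol(m) < 2L) stop_bad_arg("need at least 2 samples")
  r <- cor(m)
  dplyr::bind_cols(tibble(sample = colnames(r)), as_tibble(r))
}
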