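#' Metagene coverage profile along a transcript
#'
#' Per-nucleotide P-site counts along one transcript, normalised either to
#' the library size (counts per million mapped reads of each sample) or to
#' the mean read density over the transcript's CDS, averaged across
#' replicate samples (the `sample` column), then smoothed with a centred
#' moving average. An even smoothing window is widened by 1 to stay centred;
#' windows are truncated at the transcript ends, so uniform coverage is a
#' fixed point of the smoother.
#'
#' @param footprints Footprint tibble; a `sample` column defines replicates
#'   (absent = one sample). Library size is the number of footprints per
#'   sample in this tibble.
#' @param transcript A single transcript id (character) present in
#'   `transcripts`.
#' @param transcripts Transcript tibble.
#' @param normalization `"library_size"` or `"cds_mean_density"`.
#' @param smooth_window Moving-average width in nt (default 30, used as 31);
#'   0 or 1 disables smoothing.
#' @param offsets Per-length P-site offsets (see [footprint_psites()]).
#' @return Tibble with `position` (0-based), `density` (smoothed) and
#'   `raw` (unsmoothed, replicate-averaged) columns.
#' @export
metagene_profile <- function(footprints, transcript, transcripts,
                             normalization = c("library_size", "cds_mean_density"),
                             smooth_window = 30L, offsets = NULL) {
  normalization <- match.arg(normalization)
  validate_transcripts(transcripts)
  ti <- match(transcript, transcripts$id)
  if (is.na(ti)) stop_bad_arg("transcript '%s' not in annotation", transcript)
  len <- transcripts$length[ti]
  u5 <- transcripts$utr5_end[ti]
  ce <- transcripts$cds_end[ti]

  if (!"sample" %in% names(footprints)) footprints$sample <- "sample1"
  samples <- unique(footprints$sample)

  profiles <- vapply(samples, function(s) {
    sub <- footprints[footprints$sample == s, ]
    lib_size <- nrow(sub)
    sub <- sub[sub$reference == transcript, ]
    psite <- footprint_psites(sub, offsets)
    psite <- psite[psite >= 0 & psite < len]
    counts <- tabulate(psite + 1L, nbins = len)
    norm <- switch(normalization,
      library_size = counts / max(lib_size, 1L) * 1e6,
      cds_mean_density = {
        dens <- mean(counts[(u5 + 1L):ce])
        if (dens == 0) counts else counts / dens
      }
    )
    norm
  }, numeric(len))
  avg <- rowMeans(profiles)

  tibble(position = seq_len(len) - 1L,
         density = smooth_centered(avg, smooth_window),
         raw = avg)
}

## centred moving average, window truncated at the ends
smooth_centered <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
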