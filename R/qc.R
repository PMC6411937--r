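#' P-site positions and region labels of footprints
#'
#' `footprint_psites()` returns each footprint's P-site position on its
#' reference (0-based), using per-length offsets. `footprint_regions()` maps
#' those P-sites to `utr5` / `cds` / `utr3` under the 0-based half-open
#' transcript model (`NA` when the P-site falls off the transcript).
#'
#' @param footprints Footprint tibble (`reference`, `start`, `length`).
#' @param transcripts Transcript tibble covering all references.
#' @param offsets Named offset vector (names = lengths) or the tibble
#'   returned by [estimate_psite_offsets()]; default
#'   [canonical_psite_offsets()].
#' @return Integer vector of P-sites / character vector of regions.
#' @export
footprint_psites <- function(footprints, offsets = NULL) {
  off <- resolve_offsets(offsets, footprints$length)
  footprints$start + off
}

#' @rdname footprint_psites
#' @export
footprint_regions <- function(footprints, transcripts, offsets = NULL) {
  validate_transcripts(transcripts)
  psite <- footprint_psites(footprints, offsets)
  i <- match(footprints$reference, transcripts$id)
  if (anyNA(i)) {
    stop_bad_arg("footprint references missing from annotation: %s",
                 paste(head(unique(footprints$reference[is.na(i)]), 5), collapse = ", "))
  }
  u5 <- transcripts$utr5_end[i]
  ce <- transcripts$cds_end[i]
  len <- transcripts$length[i]
  dplyr::case_when(
    psite < 0 | psite >= len ~ NA_character_,
    psite < u5 ~ "utr5",
    psite < ce ~ "cds",
    TRUE ~ "utr3"
  )
}

resolve_offsets <- function(offsets, lengths) {
  if (is.null(offsets)) return(unname(canonical_psite_offsets(lengths)))
  if (is.data.frame(offsets)) offsets <- setNames(offsets$offset, offsets$length)
  off <- offsets[as.character(lengths)]
  if (anyNA(off)) {
    ## lengths absent from the offset table fall back to the canonical rule
    miss <- is.na(off)
    off[miss] <- canonical_psite_offsets(lengths[miss])
  }
  as.integer(unname(off))
}

#' Region assignment fractions
#'
#' Fraction of footprints whose P-site falls in the 5'UTR, CDS and 3'UTR. In
#' `"psite"` mode (default) each read is assigned to exactly one region by
#' its P-site; `"overlap"` mode counts a read toward every region its span
#' overlaps (bedtools-intersect style, provided for comparability), so
#' fractions are over assignments rather than reads.
#'
#' @inheritParams footprint_psites
#' @param transcripts Transcript tibble.
#' @param mode `"psite"` or `"overlap"`.
#' @return Tibble with `region`, `n`, `fraction`; fractions sum to 1 over
#'   assignable reads.
#' @export
assign_regions <- function(footprints, transcripts, offsets = NULL,
                           mode = c("psite", "overlap")) {
  mode <- match.arg(mode)
  if (mode == "psite") {
    reg <- footprint_regions(footprints, transcripts, offsets)
    reg <- reg[!is.na(reg)]
  } else {
    validate_transcripts(transcripts)
    i <- match(footprints$reference, transcripts$id)
    if (anyNA(i)) stop_bad_arg("footprint references missing from annotation")
    s <- footprints$start
    e <- footprints$start + footprints$length
    reg <- c(
      rep("utr5", sum(s < transcripts$utr5_end[i])),
      rep("cds", sum(e > transcripts$utr5_end[i] & s < transcripts$cds_end[i])),
      rep("utr3", sum(e > transcripts$cds_end[i]))
    )
  }
  tab <- table(factor(reg, levels = c("utr5", "cds", "utr3")))
  tibble(region = names(tab), n = as.integer(tab),
         fraction = as.numeric(tab) / sum(tab))
}

#' Estimate P-site offsets from a start-codon metagene
#'
#' For each read length `L`, candidate offsets `o` in `[L/4, L/2]` are scored
#' by the aggregated 5'-end density at position `CDS start - o` across
#' transcripts; the initiation peak makes the true offset the argmax. Lengths
#' with fewer than `min_reads` reads inherit the read-weighted modal offset
#' of the estimated lengths. Offsets whose peak-to-mean density ratio falls
#' below 2 are flagged low-confidence.
#'
#' @inheritParams footprint_psites
#' @param transcripts Transcript tibble with annotated start codons.
#' @param min_reads Minimum reads per length class for direct estimation.
#' @return Tibble with `length`, `n_reads`, `offset`, `confidence`
#'   (peak/mean ratio), `estimated`, `low_confidence`.
#' @export
estimate_psite_offsets <- function(footprints, transcripts, min_reads = 200L) {
  validate_transcripts(transcripts)
  u5 <- setNames(transcripts$utr5_end, transcripts$id)
  rel5 <- footprints$start - u5[footprints$reference] # 5' end relative to CDS start

  per_len <- footprints %>%
    mutate(rel5 = unname(rel5)) %>%
    group_by(length = .data$length) %>%
    summarise(n_reads = n(), rel5 = list(.data$rel5), .groups = "drop")

  est <- purrr::pmap_dfr(per_len, function(length, n_reads, rel5) {
    if (n_reads < min_reads) {
      return(tibble(length = length, n_reads = n_reads, offset = NA_integer_,
                    confidence = NA_real_, estimated = FALSE))
    }
    cand <- seq.int(floor(length / 4), floor(length / 2))
    dens <- vapply(cand, function(o) sum(rel5 == -o), numeric(1))
    if (all(dens == 0)) {
      return(tibble(length = length, n_reads = n_reads, offset = NA_integer_,
                    confidence = NA_real_, estimated = FALSE))
    }
    best <- cand[which.max(dens)] # which.max ties -> smallest offset
    tibble(length = length, n_reads = n_reads, offset = as.integer(best),
           confidence = max(dens) / mean(dens), estimated = TRUE)
  })

  if (!any(est$estimated)) {
    stop_bad_arg("no read-length class reaches min_reads = %d; sequence more reads", min_reads)
  }
  ## read-weighted modal offset among estimated lengths
  w <- est %>% filter(.data$estimated) %>%
    group_by(.data$offset) %>% summarise(n = sum(.data$n_reads), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n), .data$offset)
  global_mode <- w$offset[1]
  est$offset[!est$estimated] <- global_mode
  est$low_confidence <- est$estimated & est$confidence < 2
  est
}

#' Reading-frame preference of footprints
#'
#' Computes the P-site frame `(psite - CDS start) mod 3` for CDS-mapped
#' reads, per read length, and reports the length with the best frame-0
#' resolution (ties toward the shortest length).
#'
#' @inheritParams footprint_psites
#' @param transcripts Transcript tibble.
#' @param min_reads Lengths with fewer CDS reads are reported but not
#'   eligible as best length.
#' @return List of class `frame_preference`: `per_length` tibble (`length`,
#'   `n`, `f0`, `f1`, `f2`), `best_length`, `frame_fractions` (at the best
#'   length), `overall` fractions.
#' @export
frame_preference <- function(footprints, transcripts, offsets = NULL,
                             min_reads = 100L) {
  validate_transcripts(transcripts)
  psite <- footprint_psites(footprints, offsets)
  i <- match(footprints$reference, transcripts$id)
  in_cds <- !is.na(i) & psite >= transcripts$utr5_end[i] & psite < transcripts$cds_end[i]
  if (!any(in_cds)) stop_bad_arg("no CDS-mapped footprints for frame analysis")
  frame <- (psite[in_cds] - transcripts$utr5_end[i][in_cds]) %% 3L

  per_length <- tibble(length = footprints$length[in_cds], frame = frame) %>%
    count(.data$length, .data$frame) %>%
    tidyr::pivot_wider(names_from = "frame", values_from = "n",
                       names_prefix = "f", values_fill = 0L)
  for (f in c("f0", "f1", "f2")) if (!f %in% names(per_length)) per_length[[f]] <- 0L
  per_length <- per_length %>%
    mutate(n = .data$f0 + .data$f1 + .data$f2,
           across(c("f0", "f1", "f2"), ~ .x / n)) %>%
    select("length", "n", "f0", "f1", "f2") %>%
    arrange(.data$length)

  eligible <- per_length %>% filter(.data$n >= min_reads)
  if (nrow(eligible) == 0L) eligible <- per_length
  best <- eligible %>% arrange(dplyr::desc(.data$f0), .data$length) %>% slice(1)

  overall <- as.numeric(table(factor(frame, levels = 0:2)) / length(frame))
  structure(list(
    per_length = per_length,
    best_length = best$length,
    frame_fractions = c(f0 = best$f0, f1 = best$f1, f2 = best$f2),
    overall = setNames(overall, c("f0", "f1", "f2"))
  ), class = "frame_preference")
}

#' @export
print.frame_preference <- function(x, ...) {
  cat(sprintf("<frame_preference> best length %d nt: f0 = %.3f, f1 = %.3f, f2 = %.3f\n",
              x$best_length, x$frame_fractions["f0"],
              x$frame_fractions["f1"], x$frame_fractions["f2"]))
  invisible(x)
}

#' @export
tidy.frame_preference <- function(x, ...) x$per_length
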