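#' Digestion-completeness parameters for the footprint simulator
#'
#' Bundles the knobs of the explicit digestion model used by
#' [simulate_footprints()]. `completeness` is the central quantity: 1 means
#' complete RNase digestion (modal footprint 28 nt, no GC selection, maximal
#' frame fidelity, no UTR contamination); values toward 0 reproduce the
#' signatures of incomplete digestion — longer, GC-richer, frame-degraded and
#' UTR-contaminated footprints.
#'
#' @param completeness Digestion completeness in (0, 1].
#' @param length_peak_complete Modal footprint length at complete digestion
#'   (nt; 28 for an 80S monosome footprint).
#' @param length_shift_max Maximal upward shift of the modal length at
#'   completeness 0 (nt).
#' @param gc_bias_strength Exponent `beta` of the GC acceptance tilt: a
#'   candidate fragment is kept with weight proportional to
#'   `exp(beta * (1 - completeness) * (GC - 0.5))`. The default of 12 makes a
#'   fully incomplete digestion raise the windowed GC of accepted footprints
#'   by roughly 8 percentage points, the scale seen in strongly affected
#'   library batches.
#' @param frame_fidelity_complete,frame_fidelity_floor Probability that a
#'   footprint's P-site falls in the annotated frame at completeness 1 and in
#'   the completeness-0 limit; the realised fidelity is
#'   `floor + (complete - floor) * completeness`.
#' @param utr_contamination_max Maximal fraction of footprints drawn from
#'   UTRs; the realised fraction is `utr_contamination_max * (1 - completeness)`.
#' @param end_bias List with named weight vectors `five_prime` and
#'   `three_prime` over A/C/G/T. Defaults encode the RNase A+T1 chemistry:
#'   RNase A cuts after pyrimidines (C/U) and T1 after G, so fragments rarely
#'   end in A, and observed footprint 5' ends are A-enriched.
#' @param pcr_dup_rate Expected fraction of emitted reads that are PCR
#'   duplicates, in `[0, 1)`; per-fragment extra copies are geometric.
#' @param init_peak_weight Relative P-site weight of the start codon versus
#'   any other codon (>= 1); models the initiation peak that anchors
#'   start-codon metagene offset estimation.
#' @param seed Integer seed for the per-sample generator.
#' @return An object of class `digestion_params` (a validated list).
#' @export
#' @examples
#' digestion_params(completeness = 0.4)
digestion_params <- function(completeness = 1,
                             length_peak_complete = 28L,
                             length_shift_max = 5L,
                             gc_bias_strength = 12,
                             frame_fidelity_complete = 0.9,
                             frame_fidelity_floor = 0.4,
                             utr_contamination_max = 0.3,
                             end_bias = list(
                               five_prime = c(A = 2.5, C = 1, G = 1, T = 1),
                               three_prime = c(A = 0.05, C = 1, G = 1, T = 1)
                             ),
                             pcr_dup_rate = 0.1,
                             init_peak_weight = 5,
                             seed = 1L) {
  p <- list(
    completeness = completeness,
    length_peak_complete = as.integer(length_peak_complete),
    length_shift_max = as.integer(length_shift_max),
    gc_bias_strength = gc_bias_strength,
    frame_fidelity_complete = frame_fidelity_complete,
    frame_fidelity_floor = frame_fidelity_floor,
    utr_contamination_max = utr_contamination_max,
    end_bias = end_bias,
    pcr_dup_rate = pcr_dup_rate,
    init_peak_weight = init_peak_weight,
    seed = as.integer(seed)
  )
  if (!is.finite(completeness) || completeness <= 0 || completeness > 1) {
    stop_bad_arg("completeness must lie in (0, 1]")
  }
  if (gc_bias_strength < 0) stop_bad_arg("gc_bias_strength must be >= 0")
  probs <- c(frame_fidelity_complete, frame_fidelity_floor)
  if (any(probs < 0 | probs > 1)) stop_bad_arg("frame fidelities must lie in [0, 1]")
  if (frame_fidelity_floor > frame_fidelity_complete) {
    stop_bad_arg("frame_fidelity_floor must not exceed frame_fidelity_complete")
  }
  if (utr_contamination_max < 0 || utr_contamination_max >= 1) {
    stop_bad_arg("utr_contamination_max must lie in [0, 1)")
  }
  if (pcr_dup_rate < 0 || pcr_dup_rate >= 1) stop_bad_arg("pcr_dup_rate must lie in [0, 1)")
  if (init_peak_weight < 1) stop_bad_arg("init_peak_weight must be >= 1")
  for (side in c("five_prime", "three_prime")) {
    w <- end_bias[[side]]
    if (is.null(w) || !all(BASES %in% names(w)) || any(w < 0) || all(w == 0)) {
      stop_bad_arg("end_bias$%s must be a non-negative weight vector named A,C,G,T", side)
    }
  }
  structure(p, class = "digestion_params")
}

#' @export
print.digestion_params <- function(x, ...) {
  cat("<digestion_params>\n")
  cat(sprintf("  completeness: %.2f  (modal length %d nt)\n", x$completeness,
              x$length_peak_complete +
                as.integer(round(x$length_shift_max * (1 - x$completeness)))))
  cat(sprintf("  gc_bias_strength: %.1f  frame fidelity: %.2f  UTR contamination: %.2f\n",
              x$gc_bias_strength,
              x$frame_fidelity_floor +
                (x$frame_fidelity_complete - x$frame_fidelity_floor) * x$completeness,
              x$utr_contamination_max * (1 - x$completeness)))
  cat(sprintf("  pcr_dup_rate: %.2f  seed: %d\n", x$pcr_dup_rate, x$seed))
  invisible(x)
}

#' Canonical P-site offsets by footprint length
#'
#' For a 28 nt monosome footprint the P-site sits 12 nt from the 5' end; in
#' this model extra length from incomplete digestion extends the 5' side, so
#' the truth offset is `12 + (length - 28)`.
#'
#' @param lengths Integer vector of footprint lengths.
#' @return Named integer vector of offsets (nt from the 5' end).
#' @export
#' @examples
#' canonical_psite_offsets(27:30)
canonical_psite_offsets <- function(lengths) {
  lengths <- as.integer(lengths)
  setNames(12L + (lengths - 28L), lengths)
}
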