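#' Simulate ribosome footprints under a digestion-completeness model
#'
#' Draws ribosome-protected fragments from a transcriptome according to a
#' [digestion_params()] model:
#'
#' * footprint length follows a unimodal discretised distribution (binomial
#'   shape over `mode - 4 .. mode + 6`, truncated to the gel size-selection
#'   window) whose mode is
#'   `length_peak_complete + round(length_shift_max * (1 - completeness))`;
#' * candidate fragments are accepted with weight proportional to
#'   `exp(gc_bias_strength * (1 - completeness) * (GC - 0.5))`, so incomplete
#'   digestion enriches GC-rich footprints;
#' * the P-site (at the canonical offset from the 5' end, see
#'   [canonical_psite_offsets()]) lands in the annotated frame with
#'   probability `frame_fidelity_floor + (frame_fidelity_complete -
#'   frame_fidelity_floor) * completeness`, otherwise it is shifted +/- 1 nt;
#' * a fraction `utr_contamination_max * (1 - completeness)` of fragments is
#'   drawn from UTRs instead of the CDS;
#' * fragment ends are filtered by the `end_bias` weights (5' A enrichment,
#'   3' C/T/G cut preference of the RNase A+T1 cocktail);
#' * each unique fragment receives a random 8 nt UMI and a geometric number
#'   of PCR duplicate copies at `pcr_dup_rate`.
#'
#' UMI assignment and PCR duplication use random streams separate from
#' fragment generation, so changing `pcr_dup_rate` does not perturb the
#' fragments themselves.
#'
#' @param transcripts Transcript tibble from [generate_transcriptome()].
#' @param params A [digestion_params()] object.
#' @param n_reads Number of unique fragments to draw (>= 1); PCR duplicates
#'   are emitted on top of these.
#' @param abundance Optional per-transcript sampling weights (default equal).
#' @param sample_id Sample label carried into the truth table.
#' @param barcode 5 nt sample barcode carried into the truth table.
#' @return A list with two tibbles: `reads` (`read_id`, `sequence` (the
#'   insert), `umi`, `barcode`, `sample`) ready for [emit_fastq()], and
#'   `truth` adding `transcript`, `start` (0-based), `length`, `psite`,
#'   `psite_offset`, `region` and `duplicate_of`.
#' @export
#' @examples
#' tx <- generate_transcriptome(10, seed = 1)
#' sim <- simulate_footprints(tx, digestion_params(seed = 7), n_reads = 100)
#' table(sim$truth$region)
simulate_footprints <- function(transcripts, params, n_reads,
                                abundance = NULL,
                                sample_id = "sample1",
                                barcode = "AATCG") {
  validate_transcripts(transcripts)
  if (nrow(transcripts) == 0L) stop_bad_arg("empty transcript list")
  if (!inherits(params, "digestion_params")) stop_bad_arg("params must come from digestion_params()")
  if (n_reads < 1) stop_bad_arg("n_reads must be >= 1")
  if (!is.null(abundance) && length(abundance) != nrow(transcripts)) {
    stop_bad_arg("abundance must have one weight per transcript")
  }

  seeds <- split_seed(params$seed, 3L)
  frag <- with_stream(seeds[1], draw_fragments(transcripts, params, n_reads, abundance))
  umi <- with_stream(seeds[2], random_seq(n_reads, 8L, gc = 0.5))
  extra <- with_stream(seeds[3], rgeom(n_reads, prob = 1 - params$pcr_dup_rate))

  base_id <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  idx <- rep(seq_len(n_reads), times = 1L + extra)
  rank <- sequence(1L + extra) - 1L

  truth <- tibble(
    read_id = ifelse(rank == 0L, base_id[idx], paste0(base_id[idx], ".dup", rank)),
    transcript = frag$transcript[idx],
    start = frag$start[idx],
    length = frag$length[idx],
    psite = frag$psite[idx],
    psite_offset = frag$offset[idx],
    region = frag$region[idx],
    umi = umi[idx],
    duplicate_of = ifelse(rank == 0L, NA_character_, base_id[idx]),
    barcode = barcode,
    sample = sample_id,
    sequence = frag$sequence[idx]
  )
  list(
    reads = truth[, c("read_id", "sequence", "umi", "barcode", "sample")],
    truth = truth
  )
}

## run `expr` under a dedicated RNG stream without disturbing the caller's
with_stream <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  res <- force(expr)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

## rejection-sample `n` fragments from the digestion model; region quotas are
## fixed up front (multinomial at the model's contamination fraction) and the
## GC/end-bias acceptance acts within each region, so the realised UTR
## fraction tracks utr_contamination_max * (1 - completeness) rather than
## being distorted by the GC tilt
draw_fragments <- function(tx, p, n, abundance) {
  p_utr <- p$utr_contamination_max * (1 - p$completeness)
  prob_tx <- abundance %||% rep(1, nrow(tx))
  share5 <- sum(tx$utr5_end * prob_tx) /
    max(sum((tx$utr5_end + tx$length - tx$cds_end) * prob_tx), 1)
  quota <- as.vector(stats::rmultinom(1, n, c(
    cds = 1 - p_utr, utr5 = p_utr * share5, utr3 = p_utr * (1 - share5)
  )))
  names(quota) <- c("cds", "utr5", "utr3")
  parts <- lapply(c("cds", "utr5", "utr3"), function(reg) {
    if (quota[reg] == 0L) return(NULL)
    draw_fragments_region(tx, p, quota[reg], prob_tx, reg)
  })
  out <- bind_rows(parts)
  out[sample.int(nrow(out)), ] # interleave regions
}

draw_fragments_region <- function(tx, p, n, prob_tx, region_target) {
  cmpl <- p$completeness
  mode_len <- p$length_peak_complete +
    as.integer(round(p$length_shift_max * (1 - cmpl)))
  gel_lo <- 26L
  gel_hi <- 34L
  tilt <- p$gc_bias_strength * (1 - cmpl)
  fidelity <- p$frame_fidelity_floor +
    (p$frame_fidelity_complete - p$frame_fidelity_floor) * cmpl
  w5 <- p$end_bias$five_prime[BASES] / max(p$end_bias$five_prime)
  w3 <- p$end_bias$three_prime[BASES] / max(p$end_bias$three_prime)

  u5 <- tx$utr5_end
  ce <- tx$cds_end
  txlen <- tx$length
  ncod <- (ce - u5) %/% 3L
  utr3_len <- txlen - ce
  ## restrict transcript sampling to those that can host the region
  prob_reg <- prob_tx
  if (region_target == "utr5") prob_reg <- prob_tx * (u5 > 0)
  if (region_target == "utr3") prob_reg <- prob_tx * (utr3_len > 0)

  if (sum(prob_reg) == 0) {
    stop_bad_arg("no transcript can host %s fragments", region_target)
  }

  out <- vector("list", 0L)
  got <- 0L
  dry_batches <- 0L
  while (got < n) {
    if (dry_batches >= 50L) {
      stop_bad_arg("cannot place %s fragments on this transcriptome (regions too short for the footprint window)", region_target)
    }
    m <- as.integer(min(5e5, 4L * (n - got) + 200L))
    ti <- sample.int(nrow(tx), m, replace = TRUE, prob = prob_reg)

    ## truncated binomial-shaped length draw
    len <- mode_len - 4L + rbinom(m, 10L, 0.4)
    bad <- len < gel_lo | len > gel_hi
    while (any(bad)) {
      len[bad] <- mode_len - 4L + rbinom(sum(bad), 10L, 0.4)
      bad <- len < gel_lo | len > gel_hi
    }
    off <- 12L + (len - 28L)

    region <- rep(region_target, m)
    psite <- integer(m)
    keep <- rep(TRUE, m)

    cds_i <- which(region == "cds")
    if (length(cds_i)) {
      t2 <- ti[cds_i]
      ## valid codon index range leaving 1 nt margin for frame jitter
      kmin <- pmax(0L, as.integer(ceiling((off[cds_i] + 1L - u5[t2]) / 3)))
      kmax <- pmin(ncod[t2] - 1L,
                   as.integer(floor((txlen[t2] - 1L - len[cds_i] + off[cds_i] - u5[t2]) / 3)))
      nk <- kmax - kmin + 1L
      has0 <- kmin == 0L
      others <- nk - as.integer(has0)
      wtot <- p$init_peak_weight * as.integer(has0) + pmax(others, 0L)
      ok <- nk > 0L
      pick0 <- ok & has0 & (runif(length(cds_i)) * wtot < p$init_peak_weight)
      kother <- ifelse(has0, 1L, kmin) +
        as.integer(floor(runif(length(cds_i)) * pmax(others, 1L)))
      k <- ifelse(pick0, 0L, kother)
      ok <- ok & (pick0 | others > 0L)
      ps <- u5[t2] + 3L * k
      ## frame infidelity: shift the P-site by +/- 1 nt
      jitter <- runif(length(cds_i)) >= fidelity
      ps <- ps + ifelse(jitter, sample(c(-1L, 1L), length(cds_i), replace = TRUE), 0L)
      psite[cds_i] <- ps
      keep[cds_i] <- ok
    }
    for (side in c("utr5", "utr3")) {
      ui <- which(region == side)
      if (!length(ui)) next
      t2 <- ti[ui]
      width <- if (side == "utr5") u5[t2] else utr3_len[t2]
      lo <- if (side == "utr5") 0L else ce[t2]
      psite[ui] <- lo + as.integer(floor(runif(length(ui)) * pmax(width, 1L)))
      keep[ui] <- width > 0L
    }

    start <- psite - off
    keep <- keep & start >= 0L & start + len <= txlen[ti]
    acc_u <- runif(m) # consumed for every candidate to keep streams aligned
    idx <- which(keep)
    if (!length(idx)) { dry_batches <- dry_batches + 1L; next }

    seqs <- substring(tx$sequence[ti[idx]], start[idx] + 1L, start[idx] + len[idx])
    gc <- gc_fraction(seqs)
    w_gc <- if (tilt > 0) exp(tilt * (gc - 0.5) - tilt * 0.5) else 1
    first <- substring(seqs, 1L, 1L)
    last <- substring(seqs, nchar(seqs), nchar(seqs))
    w <- w_gc * unname(w5[first]) * unname(w3[last])
    sel <- idx[acc_u[idx] < w]
    if (!length(sel)) { dry_batches <- dry_batches + 1L; next }
    dry_batches <- 0L

    sel_seq <- substring(tx$sequence[ti[sel]], start[sel] + 1L, start[sel] + len[sel])
    out[[length(out) + 1L]] <- tibble(
      transcript = tx$id[ti[sel]],
      start = start[sel],
      length = len[sel],
      psite = psite[sel],
      offset = off[sel],
      region = region[sel],
      sequence = sel_seq
    )
    got <- got + length(sel)
  }
  head(bind_rows(out), n)
}
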