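#' Simulate a 2-batch x 2-genotype ribosome profiling study
#'
#' Generates the count-level data of a factorial expression-QC experiment in
#' which technical batch effects arise from unequal RNase digestion
#' completeness and biological effects from genotype-dependent abundance
#' changes. Each batch digests at its own completeness, so the GC acceptance
#' tilt reshapes per-transcript counts batch-wide; a fraction of genes
#' changes abundance in the knockout. The transcriptome is drawn as two
#' equal pools at different CDS GC (default 0.55 / 0.65) to mimic the GC
#' heterogeneity of real coding sequence, which is what couples digestion
#' completeness to expression estimates.
#'
#' @param n_transcripts Total transcripts (split across the two GC pools).
#' @param n_reads Unique footprints per sample.
#' @param batch_completeness Named or unnamed length-2 numeric: digestion
#'   completeness of batch 1 and batch 2.
#' @param genotype_effect Fold-change applied to the abundance of affected
#'   genes in KO samples.
#' @param de_fraction Fraction of genes affected by genotype.
#' @param replicates Replicates per batch x genotype cell.
#' @param cds_gc Length-2 CDS GC targets of the two transcript pools.
#' @param trim CDS end trim for counting (nt).
#' @param seed Integer seed.
#' @return List: `counts` (gene x sample tibble), `metadata` (`sample`,
#'   `batch`, `genotype`), `transcripts`, `de_genes`.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_study_design(n_transcripts = 60, n_reads = 2000, seed = 1)
#' head(d$counts)
#' }
simulate_study_design <- function(n_transcripts = 200L,
                                  n_reads = 15000L,
                                  batch_completeness = c(1.0, 0.5),
                                  genotype_effect = 1.3,
                                  de_fraction = 0.1,
                                  replicates = 2L,
                                  cds_gc = c(0.55, 0.65),
                                  trim = 30L,
                                  seed = 1L) {
  stopifnot(length(batch_completeness) == 2L, length(cds_gc) == 2L)
  half <- n_transcripts %/% 2L
  tx1 <- generate_transcriptome(half, cds_gc_target = cds_gc[1], seed = seed)
  tx2 <- generate_transcriptome(n_transcripts - half, cds_gc_target = cds_gc[2],
                                seed = seed + 1L)
  tx2$id <- sprintf("tx%04d", half + seq_len(nrow(tx2)))
  tx <- bind_rows(tx1, tx2)

  set.seed(seed + 2L)
  base_abundance <- stats::rlnorm(nrow(tx), meanlog = 0, sdlog = 0.5)
  n_de <- max(1L, round(de_fraction * nrow(tx)))
  de_genes <- sample(tx$id, n_de)

  grid <- tidyr::expand_grid(batch = c("b1", "b2"), genotype = c("WT", "KO"),
                             rep = seq_len(replicates))
  fps <- purrr::pmap_dfr(grid, function(batch, genotype, rep) {
    ab <- base_abundance
    if (genotype == "KO") ab[tx$id %in% de_genes] <- ab[tx$id %in% de_genes] * genotype_effect
    cmpl <- batch_completeness[if (batch == "b1") 1L else 2L]
    samp <- sprintf("%s_%s_%d", batch, genotype, rep)
    sim <- simulate_footprints(
      tx,
      digestion_params(completeness = cmpl, pcr_dup_rate = 0,
                       seed = seed + 10L * rep + 100L * (genotype == "KO") +
                         1000L * (batch == "b2")),
      n_reads, abundance = ab, sample_id = samp)
    load_sim_footprints(sim)
  })

  counts <- count_cds(fps, tx, trim = trim)
  metadata <- grid %>%
    mutate(sample = sprintf("%s_%s_%d", .data$batch, .data$genotype, .data$rep)) %>%
    select("sample", "batch", "genotype")
  list(counts = counts, metadata = metadata, transcripts = tx,
       de_genes = sort(de_genes))
}
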