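test_that("nucleotide composition handles ragged lengths exactly", {
  one <- nucleotide_composition("ACG")
  expect_equal(one$A, c(1, 0, 0))
  expect_equal(one$C, c(0, 1, 0))
  expect_equal(one$G, c(0, 0, 1))

  two <- nucleotide_composition(c("AA", "AC"))
  expect_equal(two$A[2], 0.5)
  expect_equal(two$C[2], 0.5)
  expect_equal(rowSums(two[, c("A", "C", "G", "T")]), c(1, 1))
})

test_that("composition matches the brute-force oracle on simulated reads", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(completeness = 0.5, seed = 12), 800)
  comp <- nucleotide_composition(sim$truth$sequence)
  for (p in c(1, 10, 20, 26)) {
    oracle <- oracle_composition(sim$truth$sequence, p)
    expect_equal(unlist(comp[p, c("A", "C", "G", "T")]),
                 oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_true(all(abs(rowSums(comp[, c("A", "C", "G", "T")]) - 1) < 1e-9))
})

test_that("5' ends are A-enriched under the RNase A+T1 end bias", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 13), 4000)
  comp <- nucleotide_composition(sim$truth$sequence)
  expect_gt(comp$A[1], comp$A[5])
  ## 3' cut preference: terminal base rarely A
  last <- substring(sim$truth$sequence, nchar(sim$truth$sequence),
                    nchar(sim$truth$sequence))
  expect_lt(mean(last == "A"), 0.05)
})

test_that("windowed GC agrees with direct counting and is order-invariant", {
  expect_equal(windowed_gc(nucleotide_composition(rep(strrep("G", 25), 5))), 100)
  half <- c(rep(strrep("GC", 13), 10), rep(strrep("AT", 13), 10))
  expect_equal(windowed_gc(nucleotide_composition(half)), 50)

  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 14), 500)
  seqs <- sim$truth$sequence
  expect_equal(windowed_gc(nucleotide_composition(seqs)),
               oracle_windowed_gc(seqs, 10, 20), tolerance = 1e-12)
  expect_equal(windowed_gc(nucleotide_composition(sample(seqs))),
               windowed_gc(nucleotide_composition(seqs)))
  ## with equal-length reads spanning the window it equals per-read averaging
  eq <- seqs[nchar(seqs) == 28]
  win <- substring(eq, 10, 20)
  expect_equal(windowed_gc(nucleotide_composition(eq), c(10, 20)),
               100 * oracle_gc_by_counting(win), tolerance = 1e-9)

  expect_error(windowed_gc(nucleotide_composition("ACGT"), c(10, 20)), "window")
})

test_that("length peak takes the argmax with ties toward the smallest", {
  expect_equal(length_peak(c(`28` = 10, `29` = 3)), 28L)
  expect_equal(length_peak(c(`28` = 5, `31` = 5)), 28L)
  expect_error(length_peak(tibble::tibble(length = integer(0), count = numeric(0))),
               "empty")
})

test_that("region assignment is by P-site under half-open boundaries", {
  tx <- tibble::tibble(id = "t1", sequence = strrep("ACGT", 75),
                       utr5_end = 60L, cds_end = 240L, length = 300L)
  mk <- function(start) tibble::tibble(read_id = "r", reference = "t1",
                                       start = start, length = 28L)
  ## P-site = start + 12
  expect_equal(footprint_regions(mk(100L), tx), "cds")
  expect_equal(footprint_regions(mk(240L - 12L + 2L), tx), "utr3")
  expect_equal(footprint_regions(mk(240L - 12L - 1L), tx), "cds")
  expect_equal(footprint_regions(mk(60L - 12L), tx), "cds")
  expect_equal(footprint_regions(mk(60L - 13L), tx), "utr5")

  fr <- assign_regions(mk(100L), tx)
  expect_equal(sum(fr$fraction), 1)
})

test_that("region fractions recover the simulated contamination (closed form)", {
  tx <- tiny_tx()
  sim <- simulate_footprints(
    tx, digestion_params(completeness = 0.2, utr_contamination_max = 0.3,
                         pcr_dup_rate = 0, seed = 19), 20000)
  fp <- load_sim_footprints(sim)
  fr <- assign_regions(fp, tx)
  utr <- sum(fr$fraction[fr$region != "cds"])
  expect_lt(abs(utr - 0.3 * 0.8), 0.03)
})

test_that("P-site offsets are recovered from the start-codon metagene", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 22), 8000)
  fp <- load_sim_footprints(sim)
  off <- estimate_psite_offsets(fp, tx)
  est <- off[off$estimated, ]
  expect_equal(est$offset, unname(canonical_psite_offsets(est$length)))
  expect_true(all(!est$low_confidence))
  ## L = 28 -> 12 and L = 29 -> 13 specifically
  expect_equal(off$offset[off$length == 28], 12L)
  expect_equal(off$offset[off$length == 29], 13L)
})

test_that("uniform positions give low-confidence offsets; sparse data errors", {
  tx <- tiny_tx()
  set.seed(77)
  n <- 20000
  ti <- sample.int(nrow(tx), n, replace = TRUE)
  start <- as.integer(floor(runif(n) * (tx$length[ti] - 28L)))
  fp <- tibble::tibble(read_id = as.character(seq_len(n)),
                       reference = tx$id[ti], start = start, length = 28L)
  off <- estimate_psite_offsets(fp, tx)
  expect_true(all(off$low_confidence[off$estimated]))
  expect_error(estimate_psite_offsets(fp[1:50, ], tx), "min_reads")
})

test_that("frame preference separates fidelity levels and handles null cases", {
  tx <- tiny_tx()
  hi <- simulate_footprints(tx, digestion_params(frame_fidelity_complete = 0.9,
                                                 seed = 25), 6000)
  lo <- simulate_footprints(tx, digestion_params(frame_fidelity_complete = 0.4,
                                                 frame_fidelity_floor = 0.4,
                                                 seed = 25), 6000)
  f_hi <- frame_preference(load_sim_footprints(hi), tx)
  f_lo <- frame_preference(load_sim_footprints(lo), tx)
  expect_gt(f_hi$frame_fractions[["f0"]], f_lo$frame_fractions[["f0"]])
  expect_equal(sum(f_hi$frame_fractions), 1)

  ## perfectly in-frame reads
  fp <- tibble::tibble(read_id = as.character(1:10), reference = tx$id[1],
                       start = tx$utr5_end[1] + 3L * (3:12) - 12L, length = 28L)
  perfect <- frame_preference(fp, tx)
  expect_equal(perfect$frame_fractions[["f0"]], 1)

  ## uniform frames ~ 1/3 each
  set.seed(99)
  n <- 9999
  ti <- rep(1L, n)
  psite <- tx$utr5_end[1] + as.integer(floor(runif(n) * (tx$cds_end[1] - tx$utr5_end[1] - 3L)))
  fpu <- tibble::tibble(read_id = as.character(seq_len(n)), reference = tx$id[1],
                        start = psite - 12L, length = 28L)
  u <- frame_preference(fpu, tx)
  expect_lt(abs(u$overall[["f0"]] - 1 / 3), 0.02)
})

test_that("metagene profiles conserve counts and respect fixed points", {
  tx <- tibble::tibble(id = "t1", sequence = strrep("ACGT", 75),
                       utr5_end = 60L, cds_end = 240L, length = 300L)
  ## single read: delta at its P-site under library-size normalisation
  fp1 <- tibble::tibble(read_id = "r", reference = "t1", start = 100L,
                        length = 28L, sample = "s1")
  prof <- metagene_profile(fp1, "t1", tx, smooth_window = 0)
  expect_equal(which(prof$density > 0) - 1L, 112L)
  expect_equal(prof$density[113], 1e6) # 1 read / library of 1, per million

  ## uniform coverage is unchanged by smoothing
  fpu <- tibble::tibble(read_id = as.character(1:240),
                        reference = "t1", start = 0:239, length = 28L,
                        sample = "s1")
  fpu <- fpu[fpu$start + 12 < 300, ]
  raw <- metagene_profile(fpu, "t1", tx, smooth_window = 0)
  expect_true(all(raw$raw[13:252] == raw$raw[13]))
  sm <- metagene_profile(fpu, "t1", tx, smooth_window = 30)
  inner <- 40:220
  expect_equal(sm$density[inner], raw$raw[inner])

  ## two identical replicates average to each replicate
  fp2 <- dplyr::bind_rows(fp1, dplyr::mutate(fp1, sample = "s2"))
  prof2 <- metagene_profile(fp2, "t1", tx, smooth_window = 0)
  expect_equal(prof2$density, prof$density)

  ## conservation: raw counts sum to number of P-sites on the transcript
  prof3 <- metagene_profile(fpu, "t1", tx, normalization = "cds_mean_density",
                            smooth_window = 0)
  cds_mean <- mean(tabulate(fpu$start + 12 + 1, 300)[61:240])
  expect_equal(sum(prof3$raw) * cds_mean, nrow(fpu))
})

test_that("qc_report bundles consistent metrics and serialises", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 33), 5000)
  fp <- dplyr::filter(mark_duplicates(load_sim_footprints(sim)),
                      category == "unique")
  rep <- qc_report(fp, tx, sample_id = "s1")
  g <- glance(rep)
  expect_equal(g$length_peak, 28L)
  expect_equal(g$n_reads, nrow(fp))
  expect_equal(g$utr5_fraction + g$cds_fraction + g$utr3_fraction, 1,
               tolerance = 1e-9)
  prefix <- withr::local_tempfile()
  paths <- write_qc_report(rep, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$length_peak, 28L)
})
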