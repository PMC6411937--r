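test_that("emit_fastq writes layout-conformant records (string-scan oracle)", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 8), 1000)
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(sim$reads, path)
  fq <- read_fastq(path)
  expect_equal(nrow(fq), nrow(sim$reads))
  ## adapter prefix must sit immediately after barcode+umi+insert
  expected <- paste0(sim$reads$barcode, sim$reads$umi, sim$reads$sequence,
                     ribo_adapter())
  expect_true(all(fq$sequence == expected))
  expect_true(all(nchar(fq$qualities) == nchar(fq$sequence)))
})

test_that("an empty read list produces a valid empty FASTQ", {
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(tibble::tibble(read_id = character(0), sequence = character(0),
                            umi = character(0), barcode = character(0)), path)
  expect_true(file.exists(path))
  expect_equal(nrow(read_fastq(path)), 0)
})

test_that("a long insert preserves the insert and truncates the adapter", {
  reads <- tibble::tibble(read_id = "r1", sequence = strrep("ACGT", 10),
                          umi = "ACGTACGT", barcode = "AATCG")
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(reads, path, read_length = 55)
  fq <- read_fastq(path)
  expect_equal(nchar(fq$sequence), 55)
  expect_equal(substr(fq$sequence, 14, 53), strrep("ACGT", 10))
  expect_equal(substr(fq$sequence, 54, 55), substr(ribo_adapter(), 1, 2))
})

test_that("demultiplexing assigns by Hamming distance and strips the barcode", {
  wl <- c("AATCG", "GGCTA")
  mk <- function(bc) tibble::tibble(
    read_id = "r", sequence = paste0(bc, "ACGTACGTAAACCC"),
    qualities = strrep("F", 19))
  exact <- demultiplex(mk("AATCG"), wl, max_mismatch = 0)
  expect_equal(exact$barcode, "AATCG")
  expect_equal(exact$sequence, "ACGTACGTAAACCC")
  expect_equal(nchar(exact$qualities), 14)

  near <- demultiplex(mk("AATCC"), wl, max_mismatch = 1)
  expect_equal(near$barcode, "AATCG") # Hamming-distance oracle: d=1 vs d=5
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(hamming("AATCC", "AATCG"), 1)
  expect_equal(hamming("AATCC", "GGCTA"), 5)

  none <- demultiplex(mk("NNNNN"), wl, max_mismatch = 1)
  expect_true(is.na(none$barcode))
})

test_that("an ambiguous whitelist is a configuration error", {
  expect_error(
    demultiplex(tibble::tibble(read_id = "r", sequence = strrep("A", 20)),
                c("AATCG", "AATCC"), max_mismatch = 1),
    "ambiguous")
})

test_that("adapter trimming matches an exhaustive alignment oracle", {
  ad <- ribo_adapter()
  t1 <- trim_adapter(tibble::tibble(sequence = paste0("AAAA", ad)))
  expect_equal(t1$sequence, "AAAA")
  expect_true(t1$trimmed)

  ## partial adapter (10 bases) with 1 mismatch at rate 0.1
  ad10 <- substr(ad, 1, 10)
  substr(ad10, 4, 4) <- ifelse(substr(ad10, 4, 4) == "A", "C", "A")
  insert <- "ACGTACGTACGTACGTACGTACGTACGT"
  t2 <- trim_adapter(tibble::tibble(sequence = paste0(insert, ad10)),
                     max_error_rate = 0.1)
  expect_equal(t2$sequence, insert)

  t3 <- trim_adapter(tibble::tibble(sequence = "ACACACACACACACAC"))
  expect_equal(t3$sequence, "ACACACACACACACAC")
  expect_false(t3$trimmed)
})

test_that("trimming never lengthens a read and is idempotent", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 15), 300)
  reads <- tibble::tibble(sequence = paste0(sim$reads$sequence, ribo_adapter()))
  once <- trim_adapter(reads)
  expect_true(all(nchar(once$sequence) <= nchar(reads$sequence)))
  twice <- trim_adapter(once)
  expect_equal(twice$sequence, once$sequence)
})

test_that("UMI extraction handles boundary reads and zero-width layouts", {
  ## a 13 nt read is barcode + UMI only: zero-length insert, dropped
  r <- tibble::tibble(read_id = "r", sequence = paste0("AATCG", "ACGTACGT"))
  d <- demultiplex(r, "AATCG", max_mismatch = 0)
  u <- extract_umi(d)
  expect_equal(u$umi, "ACGTACGT")
  expect_equal(u$sequence, "")
  expect_true(u$dropped)

  no_umi <- extract_umi(tibble::tibble(sequence = "ACGTACGT"),
                        layout = read_layout(umi = 0))
  expect_equal(no_umi$umi, "")
  expect_equal(no_umi$sequence, "ACGTACGT")
})

test_that("the pipeline round-trips simulator reads exactly and partitions counts", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, digestion_params(seed = 21), 1000)
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(sim$reads, path)
  out <- prep_reads(path, barcode_whitelist = "AATCG")
  counts <- attr(out, "counts")
  expect_equal(counts[["assigned"]] + counts[["unassigned"]] + counts[["dropped"]],
               counts[["input"]])
  expect_equal(counts[["assigned"]], nrow(sim$reads))
  expect_identical(out$umi, sim$reads$umi)
  expect_identical(out$sequence, sim$reads$sequence)
  expect_identical(out$barcode, sim$reads$barcode)
})
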