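# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately written with different machinery (character matrices, explicit
# loops, enumeration) than the package implementations they check.

# small transcriptome shared across tests
tiny_tx <- function() generate_transcriptome(20, seed = 42)

# per-position base fractions by explicit looping over split characters
oracle_composition <- function(seqs, p) {
  chars <- strsplit(seqs, "")
  have <- Filter(function(x) length(x) >= p, chars)
  at <- vapply(have, `[[`, character(1), p)
  at <- at[at %in% c("A", "C", "G", "T")]
  c(A = mean(at == "A"), C = mean(at == "C"),
    G = mean(at == "G"), T = mean(at == "T"))
}

# windowed GC by averaging oracle_composition over positions
oracle_windowed_gc <- function(seqs, lo, hi) {
  per_pos <- vapply(lo:hi, function(p) {
    f <- oracle_composition(seqs, p)
    f[["G"]] + f[["C"]]
  }, numeric(1))
  mean(per_pos) * 100
}

# mean GC by direct base counting (used when all reads share a length)
oracle_gc_by_counting <- function(seqs) {
  chars <- unlist(strsplit(seqs, ""))
  sum(chars %in% c("G", "C")) / sum(chars %in% c("A", "C", "G", "T"))
}

# retained count after UMI dedup = number of distinct keys
oracle_dedup_count <- function(df) {
  length(unique(paste(df$reference, df$start, df$strand, df$length, df$umi)))
}

# upper-tail hypergeometric by exhaustive enumeration of draws (N <= 20)
oracle_hypergeom <- function(N, n1, n2, k) {
  draws <- utils::combn(N, n2)
  hits <- colSums(draws <= n1) # successes are items 1..n1
  mean(hits >= k)
}

# Pearson r from the raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# unbiased digestion parameters: every selection knob neutral
neutral_params <- function(seed, ...) {
  digestion_params(
    completeness = 1, gc_bias_strength = 0, utr_contamination_max = 0,
    pcr_dup_rate = 0, frame_fidelity_complete = 1, frame_fidelity_floor = 1,
    end_bias = list(five_prime = c(A = 1, C = 1, G = 1, T = 1),
                    three_prime = c(A = 1, C = 1, G = 1, T = 1)),
    init_peak_weight = 1, seed = seed, ...
  )
}

# CDS GC of one transcript, optionally excluding the start/stop codons
tx_cds_gc <- function(tx, exclude_fixed = FALSE) {
  from <- tx$utr5_end + if (exclude_fixed) 3L else 0L
  to <- tx$cds_end - if (exclude_fixed) 3L else 0L
  gc_fraction(substring(tx$sequence, from + 1L, to))
}

# count tibble -> plain matrix (gene rownames)
mat_from_counts <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  m
}
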