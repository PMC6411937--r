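test_that("CDS counting respects the trimmed half-open window", {
  tx <- tibble::tibble(id = "t1", sequence = strrep("ACGT", 100),
                       utr5_end = 60L, cds_end = 360L, length = 400L)
  mk <- function(psite) tibble::tibble(
    read_id = paste0("r", psite), reference = "t1",
    start = psite - 12L, length = 28L, category = "unique")
  ## P-site 29 nt into the CDS is excluded at trim 30; 30 nt is included
  expect_equal(sum(mat_from_counts(count_cds(mk(60L + 29L), tx, trim = 30))), 0)
  expect_equal(sum(mat_from_counts(count_cds(mk(60L + 30L), tx, trim = 30))), 1)
  ## upper boundary: cds_end - trim is excluded (half-open)
  expect_equal(sum(mat_from_counts(count_cds(mk(360L - 30L), tx, trim = 30))), 0)
  expect_equal(sum(mat_from_counts(count_cds(mk(360L - 31L), tx, trim = 30))), 1)
})

test_that("with no trimming or contamination counts equal the simulated truth", {
  tx <- tiny_tx()
  sim <- simulate_footprints(tx, neutral_params(seed = 41), 5000)
  fp <- load_sim_footprints(sim)
  counts <- count_cds(fp, tx, trim = 0)
  m <- mat_from_counts(counts)
  truth_tot <- table(factor(sim$truth$transcript, levels = counts$gene))
  expect_equal(as.integer(m[, 1]), as.integer(truth_tot))
  expect_equal(sum(m), nrow(fp))
})

test_that("low-count filtering uses the mean across samples", {
  counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
                           s1 = c(5L, 0L, 0L), s2 = c(5L, 9L, 0L))
  kept <- filter_low(counts, min_mean = 5)
  expect_equal(kept$gene, "g1") # mean(5,5) = 5 kept; mean(0,9) = 4.5 dropped
  expect_equal(filter_low(counts, min_mean = 0), counts)
})

test_that("size factors follow median-of-ratios (manual arithmetic oracle)", {
  counts <- tibble::tibble(gene = c("g1", "g2", "g3"),
                           a = c(10L, 20L, 40L), b = c(20L, 40L, 80L))
  x <- normalize_log(counts)
  sf <- attr(x, "size_factors")
  ## reference = geometric means; ratios are c(10,20,40)/ref and 2x that
  ref <- exp(rowMeans(log(cbind(c(10, 20, 40), c(20, 40, 80)))))
  expect_equal(unname(sf), unname(c(median(c(10, 20, 40) / ref),
                                    median(c(20, 40, 80) / ref))))
  expect_equal(unname(sf[["b"]] / sf[["a"]]), 2)
  ## scaling invariance: transformed values identical across the two samples
  expect_equal(x$a, x$b)

  same <- tibble::tibble(gene = c("g1", "g2"), a = c(3L, 7L), b = c(3L, 7L))
  expect_equal(unname(attr(normalize_log(same), "size_factors")), c(1, 1))
})

test_that("size factors agree with DESeq2's estimator", {
  skip_if_not_installed("DESeq2")
  tx <- tiny_tx()
  set.seed(51)
  m <- matrix(rnbinom(20 * 6, mu = rep(exp(rnorm(20, 4)), 6), size = 10),
              nrow = 20, dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
  counts <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                             tibble::as_tibble(m))
  sf <- attr(normalize_log(counts), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-9)
})

test_that("pairwise correlations behave under identity, affine maps and noise", {
  set.seed(61)
  base <- rnorm(5000)
  x <- tibble::tibble(gene = paste0("g", 1:5000),
                      s1 = base, s2 = 2 * base + 3, s3 = rnorm(5000))
  r <- pairwise_correlation(x)
  expect_equal(r$s1[r$sample == "s1"], 1)
  expect_equal(r$s2[r$sample == "s1"], 1) # affine invariance
  expect_lt(abs(r$s3[r$sample == "s1"]), 0.05) # independent noise
  ## symmetry
  expect_equal(r$s2[r$sample == "s1"], r$s1[r$sample == "s2"])
})

test_that("top-variable PCA recovers constructed structure exactly", {
  set.seed(71)
  n_gene <- 200
  x <- matrix(rnorm(n_gene * 6, sd = 0.05), nrow = n_gene,
              dimnames = list(paste0("g", 1:n_gene), paste0("s", 1:6)))
  x[1, ] <- c(0, 0, 0, 10, 10, 10) # one gene separates two clusters
  tbl <- dplyr::bind_cols(tibble::tibble(gene = rownames(x)), tibble::as_tibble(x))
  pca <- pca_top_variable(tbl, n_top = 50)
  expect_gt(pca$var_explained[1], 0.9)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-9)
  ## PC1 separates the clusters
  pc1 <- pca$scores$PC1
  expect_gt(min(abs(pc1[1:3] - pc1[4:6])), 5)
  ## scores reproduce pairwise distances of the centred top-gene matrix
  v <- apply(x, 1, var)
  top <- x[order(v, decreasing = TRUE)[1:50], ]
  centred <- scale(t(top), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(pca$scores[, -1])),
               as.matrix(dist(centred)), tolerance = 1e-9, ignore_attr = TRUE)

  flat <- dplyr::mutate(tbl, dplyr::across(-gene, ~ 0))
  expect_warning(pca_top_variable(flat, n_top = 10), "degenerate")
})

test_that("silhouette separates the factor that dominates the axis", {
  x <- c(0, 0.2, 0.1, 5, 5.2, 5.1)
  batch <- c("b1", "b1", "b1", "b2", "b2", "b2")
  geno <- c("wt", "ko", "wt", "ko", "wt", "ko")
  expect_gt(silhouette_score(x, batch), 0.8)
  expect_lt(silhouette_score(x, geno), silhouette_score(x, batch))
  expect_error(silhouette_score(x, rep("a", 6)), "2 groups")
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  r <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_equal(r$p_value, 1 / 252, tolerance = 1e-12) # 1/choose(10,5)
  expect_equal(r$k, 5)

  ## disjoint sets: k = 0 is the minimum, so P(X >= 0) = 1
  d <- hypergeom_overlap(u[1:3], u[4:6], u)
  expect_equal(d$p_value, 1)

  ## brute-force enumeration over all C(20, n2) draws
  u20 <- paste0("g", 1:20)
  cases <- list(c(8, 6, 4), c(8, 6, 1), c(10, 10, 7), c(5, 12, 3))
  for (cs in cases) {
    n1 <- cs[1]; n2 <- cs[2]; k <- cs[3]
    set_a <- u20[1:n1]
    set_b <- u20[c(1:k, (n1 + 1):(n1 + n2 - k))]
    r <- hypergeom_overlap(set_a, set_b, u20)
    expect_equal(r$k, k)
    expect_equal(r$p_value, oracle_hypergeom(20, n1, n2, k), tolerance = 1e-12)
  }

  expect_error(hypergeom_overlap(c("zz"), u[1:2], u), "universe")
})
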