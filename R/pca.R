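#' PCA on the most variable genes
#'
#' Selects the `n_top` genes with the highest variance of (transformed)
#' expression, centres them per gene (no unit-variance scaling, matching
#' `prcomp()`'s default) and performs PCA on samples. With 1000 top genes
#' this is the standard expression-QC projection for spotting batch and
#' genotype structure.
#'
#' @param x Expression tibble (`gene` + sample columns), typically from
#'   [normalize_log()].
#' @param n_top Number of top-variance genes (capped at the gene count).
#' @param metadata Optional tibble with a `sample` column plus grouping
#'   variables (batch, genotype, condition), joined onto the scores.
#' @param scale. Scale genes to unit variance before PCA (default `FALSE`).
#' @return Object of class `ribo_pca` with elements `scores` (tibble:
#'   `sample`, `PC1`, `PC2`, ..., metadata), `var_explained` (fractions
#'   summing to 1), `prcomp` (the underlying fit) and `n_top`.
#' @export
#' @examples
#' x <- tibble::tibble(gene = paste0("g", 1:50),
#'                     s1 = rnorm(50), s2 = rnorm(50), s3 = rnorm(50, 2))
#' pca <- pca_top_variable(x, n_top = 20)
#' glance(pca)
pca_top_variable <- function(x, n_top = 1000L, metadata = NULL, scale. = FALSE) {
  m <- mat_from_tbl(x)
  if (ncol(m) < 3L) stop_bad_arg("PCA needs at least 3 samples")
  if (n_top < 1L) stop_bad_arg("n_top must be >= 1")
  n_top <- min(as.integer(n_top), nrow(m))
  v <- apply(m, 1, var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top)]
  sub <- m[top, , drop = FALSE]
  if (all(apply(sub, 1, var) == 0)) {
    warn("all selected genes are constant across samples; PCA is degenerate")
  }
  fit <- prcomp(t(sub), center = TRUE, scale. = scale.)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- dplyr::bind_cols(tibble(sample = colnames(m)),
                             as_tibble(fit$x))
  if (!is.null(metadata)) scores <- left_join(scores, metadata, by = "sample")
  structure(list(scores = scores, var_explained = ve, prcomp = fit,
                 n_top = n_top), class = "ribo_pca")
}

#' @export
print.ribo_pca <- function(x, ...) {
  cat(sprintf("<ribo_pca> %d samples x %d top-variance genes\n",
              nrow(x$scores), x$n_top))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

#' @describeIn pca_top_variable Sample scores in long form (`sample`, `PC`,
#'   `score`).
#' @param ... Unused.
#' @export
tidy.ribo_pca <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(dplyr::starts_with("PC"), names_to = "PC",
                        values_to = "score")
}

#' @describeIn pca_top_variable One-row summary with leading variance
#'   fractions.
#' @export
glance.ribo_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_top = x$n_top,
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' @describeIn pca_top_variable Score plot of the first two components,
#'   optionally coloured/shaped by metadata columns.
#' @param object A `ribo_pca`.
#' @param colour,shape Names of metadata columns mapped to aesthetics.
#' @export
autoplot.ribo_pca <- function(object, colour = NULL, shape = NULL, ...) {
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(
    x = .data$PC1, y = .data$PC2,
    colour = if (is.null(colour)) NULL else .data[[colour]],
    shape = if (is.null(shape)) NULL else .data[[shape]]
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%% var.)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%% var.)", 100 * object$var_explained[2]),
      colour = colour, shape = shape
    ) +
    ggplot2::theme_minimal()
  p
}

#' Average silhouette width of a grouping
#'
#' Plain average silhouette width under Euclidean distance, used to quantify
#' which experimental factor (batch or genotype) dominates a principal
#' component: for each point, `a` is the mean distance to its own group and
#' `b` the smallest mean distance to another group, giving
#' `s = (b - a) / max(a, b)` (0 for singleton groups).
#'
#' @param x Numeric vector or matrix of coordinates (e.g. PC1 scores).
#' @param groups Grouping vector, one label per row of `x`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
#' @examples
#' silhouette_score(c(0, 0.1, 5, 5.1), c("a", "a", "b", "b"))
silhouette_score <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  stopifnot(nrow(x) == length(groups))
  if (length(unique(groups)) < 2L) stop_bad_arg("need at least 2 groups")
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_along(groups), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(d[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
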