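#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' the realised overlap between two gene sets drawn from a common universe —
#' the standard test for, e.g., overlap between differentially expressed
#' genes and an independently derived target-gene list. The tail is computed
#' in log space for numerical stability.
#'
#' The universe must be supplied explicitly (typically all expressed genes
#' after filtering); there is no safe default.
#'
#' @param set_a,set_b Character vectors of gene ids; must be subsets of
#'   `universe`. Duplicates are removed.
#' @param universe Character vector of all eligible gene ids.
#' @return One-row tibble: `k` (overlap), `n1`, `n2` (set sizes), `N`
#'   (universe size), `p_value`.
#' @export
#' @examples
#' hypergeom_overlap(letters[1:5], letters[3:7], letters)
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop_bad_arg("gene sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  n1 <- length(set_a)
  n2 <- length(set_b)
  N <- length(universe)
  log_p <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE, log.p = TRUE)
  tibble(k = k, n1 = n1, n2 = n2, N = N, p_value = exp(log_p))
}
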