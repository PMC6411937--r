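#' Design an RNase titration series
#'
#' A geometric escalation of RNase A + T1 amounts used to locate the optimal
#' digestion condition. Defaults reproduce the 5-step, 5-fold series starting
#' at 4.8 ng RNase A + 0.6 U RNase T1 per microgram of RNA, digesting 2 ug
#' RNA in 0.3 ml at 25 degrees C for 30 min.
#'
#' @param base_rnaseA Base RNase A amount (ng per ug RNA).
#' @param base_rnaseT1 Base RNase T1 amount (U per ug RNA).
#' @param fold Fold factor between consecutive steps (> 1).
#' @param steps Number of steps (>= 2).
#' @param rna_amount RNA input per reaction (ug).
#' @param volume Reaction volume (ml).
#' @param temperature Digestion temperature (degrees C).
#' @param minutes Digestion time (min).
#' @return Object of class `titration_design`.
#' @export
#' @examples
#' plan_titration(titration_design())
titration_design <- function(base_rnaseA = 4.8, base_rnaseT1 = 0.6,
                             fold = 5, steps = 5L, rna_amount = 2,
                             volume = 0.3, temperature = 25, minutes = 30L) {
  if (fold <= 1) stop_bad_arg("fold must exceed 1")
  if (steps < 2L) stop_bad_arg("steps must be >= 2")
  if (any(c(base_rnaseA, base_rnaseT1, rna_amount, volume) <= 0)) {
    stop_bad_arg("amounts must be positive")
  }
  structure(list(base_rnaseA = base_rnaseA, base_rnaseT1 = base_rnaseT1,
                 fold = fold, steps = as.integer(steps),
                 rna_amount = rna_amount, volume = volume,
                 temperature = temperature, minutes = as.integer(minutes)),
            class = "titration_design")
}

#' @describeIn titration_design Per-step RNase amounts: step `k` uses
#'   `base * fold^(k - 1)` of each enzyme per ug RNA, plus the absolute
#'   amounts in the reaction (`x rna_amount`).
#' @param design A `titration_design`.
#' @return `plan_titration()`: tibble with `step`, `rnaseA_per_ug` (ng/ug),
#'   `rnaseT1_per_ug` (U/ug), `rnaseA_total_ng`, `rnaseT1_total_U`.
#' @export
plan_titration <- function(design) {
  stopifnot(inherits(design, "titration_design"))
  k <- seq_len(design$steps)
  f <- design$fold^(k - 1)
  tibble(
    step = k,
    rnaseA_per_ug = design$base_rnaseA * f,
    rnaseT1_per_ug = design$base_rnaseT1 * f,
    rnaseA_total_ng = design$base_rnaseA * f * design$rna_amount,
    rnaseT1_total_U = design$base_rnaseT1 * f * design$rna_amount
  )
}

#' Correlate QC metrics with log RNase concentration
#'
#' Pearson correlation of windowed GC and of modal footprint length against
#' the log-`fold` concentration axis (step `k` maps to `log_fold(fold^(k-1))
#' = k - 1`; base 5 for the default 5-fold series). Complete digestion shows
#' strong negative correlations for both metrics.
#'
#' @param results Tibble with columns `step`, `gc_window_mean`,
#'   `length_peak` — e.g. `purrr::map_dfr(reports, glance)` with a `step`
#'   column added.
#' @param fold Fold factor of the series (log base).
#' @return One-row tibble with `r_gc`, `r_length` (`NA` with a warning when a
#'   metric has zero variance).
#' @export
correlate_metrics <- function(results, fold = 5) {
  stopifnot(all(c("step", "gc_window_mean", "length_peak") %in% names(results)))
  if (nrow(results) < 3L) stop_bad_arg("need at least 3 titration steps")
  x <- log(fold^(results$step - 1), base = fold)
  safe_cor <- function(y, label) {
    if (var(y) == 0 || var(x) == 0) {
      warn(sprintf("%s has zero variance across steps; correlation undefined", label))
      return(NA_real_)
    }
    cor(x, y)
  }
  tibble(r_gc = safe_cor(results$gc_window_mean, "GC"),
         r_length = safe_cor(as.numeric(results$length_peak), "length peak"))
}

#' Recommend an RNase digestion condition
#'
#' Picks the lowest titration step whose windowed GC is within `gc_tol`
#' percentage points of `gc_target`, whose modal length lies in
#' `[length_target, length_target + length_tol]`, and whose monosomes are
#' not disassembled (an operator-supplied judgement from sucrose-gradient
#' inspection). When no step qualifies, the highest non-disassembled step is
#' recommended with a warning.
#'
#' @inheritParams correlate_metrics
#' @param gc_target Target GC percent (default 50, the complete-digestion
#'   footprint GC).
#' @param length_target Target modal length in nt (default 28).
#' @param disassembly Logical vector, one flag per step (`TRUE` = monosome
#'   disassembly observed); default all `FALSE`.
#' @param gc_tol,length_tol Qualification tolerances (percentage points /
#'   nt).
#' @return One-row tibble with `step`, `qualified`, `rationale`.
#' @export
recommend_condition <- function(results, gc_target = 50, length_target = 28L,
                                disassembly = NULL, gc_tol = 2, length_tol = 1L) {
  n <- nrow(results)
  disassembly <- disassembly %||% rep(FALSE, n)
  stopifnot(length(disassembly) == n)
  ok <- abs(results$gc_window_mean - gc_target) <= gc_tol &
    results$length_peak >= length_target &
    results$length_peak <= length_target + length_tol &
    !disassembly
  if (any(ok)) {
    step <- min(results$step[ok])
    i <- match(step, results$step)
    return(tibble(
      step = step, qualified = TRUE,
      rationale = sprintf(
        "lowest step meeting GC %.1f%% (target %.0f +/- %.0f) and modal length %d nt (target %d-%d) without monosome disassembly",
        results$gc_window_mean[i], gc_target, gc_tol,
        results$length_peak[i], length_target, length_target + length_tol)
    ))
  }
  intact <- results$step[!disassembly]
  if (length(intact) == 0L) stop_bad_arg("all steps show monosome disassembly")
  step <- max(intact)
  warn("no titration step meets the GC/length targets; recommending the highest non-disassembled step")
  tibble(step = step, qualified = FALSE,
         rationale = "no step met the GC/length targets; highest non-disassembled step chosen as the most complete digestion available")
}
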