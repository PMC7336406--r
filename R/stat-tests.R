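#' Divergence shift test and multiple-testing adjustment
#'
#' Annotated orthogroups are tested for a shift in protein divergence
#' against the median divergence of orthogroups lacking an annotation from
#' the same source, with a one-sample Wilcoxon signed-rank test. The
#' median-reference design partially mitigates pseudoreplication from
#' treating orthogroups as independent samples.
#'
#' @name divergence_shift
NULL

#' One-sample signed-rank test of annotated divergences
#'
#' Tests whether the divergence values of orthogroups carrying a label are
#' shifted relative to the median divergence of the unannotated orthogroups
#' (two-sided). Differences of exactly zero are discarded before ranking;
#' the null is exact for 25 or fewer non-zero differences without ties and
#' a normal approximation with tie and continuity correction otherwise. If
#' every difference is zero the test is degenerate and reports p = 1.
#'
#' @param annotated Divergence values of orthogroups with the label.
#' @param unannotated Divergence values of orthogroups without any label
#'   from the same annotation source.
#' @param label Optional label name carried into the result.
#' @return List of class `divergence_shift` with `label`, `n` (annotated
#'   count), `n_nonzero` (differences entering the ranking),
#'   `reference_median`, `statistic` (signed-rank V), `p`, `degenerate`,
#'   and `p_adj` (`NA` until set by the caller via [bh_adjust()] across the
#'   test family).
#' @export
divergence_shift_test <- function(annotated, unannotated,
                                  label = NA_character_) {
  annotated <- as.numeric(annotated)
  unannotated <- as.numeric(unannotated)
  if (!length(annotated) || anyNA(annotated)) {
    stop("annotated divergences must be non-empty and free of NA",
         call. = FALSE)
  }
  if (!length(unannotated) || anyNA(unannotated)) {
    stop("unannotated divergences must be non-empty and free of NA",
         call. = FALSE)
  }
  ref <- stats::median(unannotated)
  diffs <- annotated - ref
  nz <- diffs[diffs != 0]
  if (!length(nz)) {
    out <- list(label = label, n = length(annotated), n_nonzero = 0L,
                reference_median = ref, statistic = NA_real_, p = 1,
                degenerate = TRUE, p_adj = NA_real_)
    return(structure(out, class = "divergence_shift"))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- length(nz) <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(annotated[diffs != 0], mu = ref,
                       alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(label = label, n = length(annotated),
                 n_nonzero = length(nz), reference_median = ref,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 degenerate = FALSE, p_adj = NA_real_),
            class = "divergence_shift")
}

#' @export
print.divergence_shift <- function(x, ...) {
  cat("One-sample Wilcoxon signed-rank divergence shift",
      if (!is.na(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  n = %d (non-zero: %d), reference median = %.4f\n",
              x$n, x$n_nonzero, x$reference_median))
  if (x$degenerate) {
    cat("  degenerate: all differences zero; p = 1\n")
  } else {
    cat(sprintf("  V = %.1f, p = %.4g", x$statistic, x$p))
    if (!is.na(x$p_adj)) cat(sprintf(", adjusted p = %.4g", x$p_adj))
    cat("\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values;
#' monotone, capped at one, order-preserving.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}
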