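#' Species-composition resampling test and signal-peptide enrichment
#'
#' Orthogroup species composition is tested against annotation by
#' resampling: from all orthogroups containing the reference species,
#' random samples the size of the annotated set are drawn repeatedly, and
#' the count of draws satisfying a composition predicate (e.g. "contains
#' all four species") is compared with the observed count. Signal-peptide
#' enrichment across positional annotation categories is tested with a
#' chi-square goodness of fit.
#'
#' @name composition_tests
NULL

#' Composition predicates
#'
#' @param kind `"complete"` (all configured species present), `"pair_only"`
#'   (exactly the two species in `species`, default the reference and
#'   `Mspi`), or `"custom"` (exactly the set `species`).
#' @param species Species codes for `pair_only`/`custom`.
#' @param config A [species_config()].
#' @return Object of class `composition_predicate`; applied to the logical
#'   presence matrix of [species_composition()] via [predicate_hits()].
#' @export
composition_predicate <- function(kind = c("complete", "pair_only", "custom"),
                                  species = NULL,
                                  config = species_config()) {
  kind <- match.arg(kind)
  target <- switch(kind,
    complete = config$codes,
    pair_only = {
      if (is.null(species)) species <- c(config$reference, "Mspi")
      species
    },
    custom = {
      if (is.null(species)) stop("custom predicate needs species",
                                 call. = FALSE)
      species
    })
  bad <- setdiff(target, config$codes)
  if (length(bad)) {
    stop("predicate references unknown species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  exact <- kind != "complete" || length(target) == length(config$codes)
  structure(list(kind = kind, target = sort(unique(target)), exact = exact),
            class = "composition_predicate")
}

#' Evaluate a composition predicate
#'
#' @param predicate A [composition_predicate()].
#' @param composition Logical presence matrix from [species_composition()].
#' @return Logical vector, one entry per orthogroup.
#' @export
predicate_hits <- function(predicate, composition) {
  in_target <- colnames(composition) %in% predicate$target
  all_target <- rowSums(composition[, in_target, drop = FALSE]) ==
    length(predicate$target)
  if (!predicate$exact) return(all_target)
  none_other <- rowSums(composition[, !in_target, drop = FALSE]) == 0L
  all_target & none_other
}

#' Resampling test of orthogroup species composition
#'
#' Each of `n_iter` draws samples `length(annotated_ids)` orthogroups
#' without replacement from the universe (all orthogroups containing the
#' reference species, annotated or not) and counts how many satisfy the
#' predicate. The two-tailed p-value doubles the smaller smoothed tail:
#' `p = min(1, 2 * min(#draws <= obs, #draws >= obs) + 1) / (n_iter + 1))`,
#' which avoids zero p-values. Because the predicate is fixed per
#' orthogroup, the exact reference distribution is hypergeometric — used as
#' an analytic cross-check, not as the implementation.
#'
#' @param universe An [orthogroup_set()] restricted to reference-containing
#'   orthogroups, or a logical vector of predicate hits named by OG ID.
#' @param annotated_ids OG IDs carrying the annotation (subset of the
#'   universe).
#' @param predicate A [composition_predicate()] (ignored when `universe` is
#'   already a logical hit vector).
#' @param n_iter Number of draws (default 100000, minimum 1000).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param label Optional annotation label carried into the result.
#' @return List of class `composition_resample`: `label`, `n_annotated`,
#'   `observed`, `expected` (mean over draws), `ci95`, `p`, `p_adj` (`NA`
#'   until adjusted across the family), `n_iter`, `seed`.
#' @export
resample_composition_test <- function(universe, annotated_ids,
                                      predicate = composition_predicate(),
                                      n_iter = 100000L, seed = NULL,
                                      label = NA_character_) {
  if (inherits(universe, "orthogroup_set")) {
    comp <- species_composition(universe)
    ref <- universe$config$reference
    in_univ <- comp[, ref]
    hits <- stats::setNames(predicate_hits(predicate, comp), rownames(comp))
    hits <- hits[in_univ]
  } else if (is.logical(universe)) {
    if (is.null(names(universe))) {
      stop("a logical universe must be named by OG ID", call. = FALSE)
    }
    hits <- universe
  } else {
    stop("universe must be an orthogroup_set or a named logical vector",
         call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1000L) stop("n_iter must be at least 1000", call. = FALSE)
  annotated_ids <- as.character(annotated_ids)
  if (!length(annotated_ids)) {
    stop("annotated set is empty", call. = FALSE)
  }
  if (anyDuplicated(annotated_ids)) {
    stop("annotated_ids contains duplicates", call. = FALSE)
  }
  outside <- setdiff(annotated_ids, names(hits))
  if (length(outside)) {
    stop("annotated OG(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  N <- length(hits)
  n_ann <- length(annotated_ids)
  if (n_ann > N) stop("annotated set larger than the universe", call. = FALSE)
  observed <- sum(hits[annotated_ids])

  if (!is.null(seed)) set.seed(as.integer(seed))
  hit_vec <- unname(hits)
  draws <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    draws[i] <- sum(hit_vec[sample.int(N, n_ann)])
  }
  lo_tail <- sum(draws <= observed)
  hi_tail <- sum(draws >= observed)
  p <- min(1, 2 * (min(lo_tail, hi_tail) + 1) / (n_iter + 1))
  structure(list(label = label, n_annotated = n_ann, observed = observed,
                 expected = mean(draws),
                 ci95 = unname(stats::quantile(draws, c(0.025, 0.975))),
                 p = p, p_adj = NA_real_, n_iter = n_iter,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "composition_resample")
}

#' @export
print.composition_resample <- function(x, ...) {
  cat("Species-composition resampling test",
      if (!is.na(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  n = %d, observed = %d, expected = %.2f [%.1f, %.1f] (%d draws)\n",
              x$n_annotated, x$observed, x$expected, x$ci95[1], x$ci95[2],
              x$n_iter))
  cat(sprintf("  two-tailed p = %.4g", x$p))
  if (!is.na(x$p_adj)) cat(sprintf(", adjusted p = %.4g", x$p_adj))
  cat("\n")
  invisible(x)
}

#' Chi-square goodness-of-fit test of signal-peptide counts
#'
#' Compares observed counts of signal-peptide-flagged orthogroups per
#' annotation category against expectations proportional to category sizes:
#' `E_i = sizes_i * sum(observed) / sum(sizes)`. In `printed_1dp` mode the
#' expected counts are rounded to one decimal before forming the statistic,
#' reproducing published tables whose statistic was computed from rounded
#' expectations; `full` precision is the default for new analyses.
#'
#' @param observed Non-negative flagged counts per category.
#' @param sizes Total orthogroup counts per category (`observed <= sizes`).
#' @param rounding `"full"` or `"printed_1dp"`.
#' @return List of class `gof_test`: `observed`, `sizes`, `expected`,
#'   `residuals` (observed - expected), `chi2`, `df`, `p`.
#' @export
#' @examples
#' signalp_gof_test(observed = c(8, 2), sizes = c(50, 50))
signalp_gof_test <- function(observed, sizes,
                             rounding = c("full", "printed_1dp")) {
  rounding <- match.arg(rounding)
  observed <- as.numeric(observed)
  sizes <- as.numeric(sizes)
  if (length(observed) != length(sizes) || length(observed) < 2L) {
    stop("observed and sizes must have equal length >= 2", call. = FALSE)
  }
  if (any(observed < 0) || any(sizes < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(observed > sizes)) {
    stop("observed flagged counts exceed category sizes", call. = FALSE)
  }
  expected <- sizes * sum(observed) / sum(sizes)
  if (any(expected == 0)) {
    stop("expected count of zero (empty category)", call. = FALSE)
  }
  if (rounding == "printed_1dp") expected <- round(expected, 1L)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, sizes = sizes, expected = expected,
                 residuals = observed - expected, chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 rounding = rounding),
            class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat("Chi-square goodness of fit (proportional allocation",
      if (x$rounding == "printed_1dp") ", expected rounded to 1 dp", ")\n",
      sep = "")
  cat(sprintf("  chi-squared = %.4g, df = %d, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}
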