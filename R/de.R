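#' Cross-species DE consistency
#'
#' DE calls are made from per-species result tables at a fixed adjusted-p
#' threshold, and orthogroups are then classified by whether their DE
#' transcripts agree in direction across all required species.
#'
#' @name de_consistency
NULL

#' Harmonise expression-filter thresholds across contrasts
#'
#' Independent filtering picks a mean-count threshold per contrast; to apply
#' identical criteria in every contrast, the minimum of these thresholds is
#' used throughout before multiple-test correction.
#'
#' @param thresholds Numeric vector of non-negative per-contrast thresholds.
#' @return The minimum threshold.
#' @export
#' @examples
#' min_filter_threshold(c(AvH = 10.5, AvR = 3.2, RvH = 7.1))
min_filter_threshold <- function(thresholds) {
  if (!length(thresholds)) {
    stop("no thresholds supplied", call. = FALSE)
  }
  thresholds <- as.numeric(thresholds)
  if (anyNA(thresholds) || any(thresholds < 0)) {
    stop("thresholds must be non-negative numbers", call. = FALSE)
  }
  min(thresholds)
}

#' Call differential expression from a result table
#'
#' A transcript is called DE when its adjusted p-value is present and below
#' `alpha`; the direction comes from the sign of the log2 fold change, where
#' a positive value means higher expression in the first condition of the
#' contrast (e.g. adults in AvH). A log2 fold change of exactly zero with a
#' significant adjusted p is degenerate and called `none`.
#'
#' @param table A [de_table()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @return Data frame of calls: `transcript`, `species`, `contrast`,
#'   `direction` (`up_first`, `up_second`, `none`), `log2FoldChange`,
#'   `padj`, with attribute `alpha`.
#' @export
call_de <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  }
  sig <- !is.na(table$padj) & table$padj < alpha
  direction <- rep("none", nrow(table))
  direction[sig & table$log2FoldChange > 0] <- "up_first"
  direction[sig & table$log2FoldChange < 0] <- "up_second"
  n_zero <- sum(sig & table$log2FoldChange == 0)
  out <- data.frame(transcript = table$transcript,
                    species = attr(table, "species"),
                    contrast = attr(table, "contrast"),
                    direction = direction,
                    log2FoldChange = table$log2FoldChange,
                    padj = table$padj,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "n_zero_lfc") <- n_zero
  out
}

#' Classify orthogroups by cross-species DE consistency
#'
#' An orthogroup is eligible when every required species contributes at
#' least one DE transcript in the contrast; eligible orthogroups are
#' `consistent_up_first` (every DE transcript across the required species up
#' in the first condition), `consistent_up_second` (all up in the second),
#' or `inconsistent` (mixed directions). Non-DE transcripts do not vote.
#'
#' @param ogs An [orthogroup_set()].
#' @param calls List of per-species DE call data frames from [call_de()],
#'   all for the same contrast.
#' @param required_species Species that must each contribute a DE
#'   transcript; defaults to the three non-reference species.
#' @return Data frame: `og_id`, `classification` (one of
#'   `consistent_up_first`, `consistent_up_second`, `inconsistent`,
#'   `not_eligible`), and per required species the counts of `up_first` and
#'   `up_second` transcripts (`n_up_first_<sp>`, `n_up_second_<sp>`).
#' @export
classify_consistent_ogs <- function(ogs, calls,
                                    required_species =
                                      setdiff(ogs$config$codes,
                                              ogs$config$reference)) {
  stopifnot(inherits(ogs, "orthogroup_set"), is.list(calls))
  all_calls <- do.call(rbind, lapply(calls, function(x)
    x[, c("transcript", "species", "direction")]))
  contrasts <- unique(vapply(calls, function(x)
    x$contrast[1] %||% NA_character_, character(1)))
  contrasts <- contrasts[!is.na(contrasts)]
  if (length(contrasts) > 1L) {
    stop("calls mix contrasts: ", paste(contrasts, collapse = ", "),
         call. = FALSE)
  }
  de <- all_calls[all_calls$direction != "none", , drop = FALSE]
  de <- de[de$species %in% required_species, , drop = FALSE]
  unknown <- !de$transcript %in% ogs$tab$transcript
  if (any(unknown)) {
    warning(sum(unknown), " DE call(s) reference transcripts absent from ",
            "every orthogroup", call. = FALSE)
    de <- de[!unknown, , drop = FALSE]
  }
  de$og_id <- ogs$tab$og_id[match(de$transcript, ogs$tab$transcript)]

  og_ids <- ogs$og_ids
  count <- function(dir, sp) {
    sub <- de[de$direction == dir & de$species == sp, , drop = FALSE]
    tab <- table(factor(sub$og_id, levels = og_ids))
    as.integer(tab)
  }
  out <- data.frame(og_id = og_ids, stringsAsFactors = FALSE)
  n_any <- matrix(0L, length(og_ids), length(required_species))
  up1 <- up2 <- 0L
  for (k in seq_along(required_species)) {
    sp <- required_species[[k]]
    c1 <- count("up_first", sp)
    c2 <- count("up_second", sp)
    out[[paste0("n_up_first_", sp)]] <- c1
    out[[paste0("n_up_second_", sp)]] <- c2
    n_any[, k] <- c1 + c2
    up1 <- up1 + c1
    up2 <- up2 + c2
  }
  eligible <- apply(n_any >= 1L, 1L, all)
  classification <- rep("not_eligible", length(og_ids))
  classification[eligible & up2 == 0L] <- "consistent_up_first"
  classification[eligible & up1 == 0L] <- "consistent_up_second"
  classification[eligible & up1 > 0L & up2 > 0L] <- "inconsistent"
  out$classification <- classification
  out[, c("og_id", "classification",
          setdiff(colnames(out), c("og_id", "classification")))]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
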