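#' Full-analysis pipeline
#'
#' Runs the stages in order — annotation transfer, mix resolution and
#' retention, DE consistency classification, per-orthogroup protein
#' divergence, divergence-shift tests, species-composition resampling
#' tests and the signal-peptide goodness-of-fit test — writing per-stage
#' TSVs and a machine-readable JSON report.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or the
#' corresponding in-memory objects.
#'
#' @param orthogroups Path to an orthogroup membership TSV, or an
#'   [orthogroup_set()].
#' @param alignments Path to a directory of per-orthogroup FASTA
#'   alignments, or a list of [protein_alignment()]s (possibly `NULL` to
#'   skip the divergence stage).
#' @param de_tables Named list (by species) of DE table paths or
#'   [de_table()]s, all for one contrast (possibly `NULL` to skip the DE
#'   stage).
#' @param annotations Path to an annotation TSV or an
#'   [annotation_table()].
#' @param out_dir Output directory for stage TSVs and the report.
#' @param config A [species_config()].
#' @param alpha DE significance threshold.
#' @param contrast Contrast ID of the DE tables.
#' @param cutoff Divergence exclusion cutoff (substitutions per site).
#' @param min_overlap Overlap-filter threshold.
#' @param t_max Upper bound for pairwise distance optimisation.
#' @param n_iter Resampling iterations.
#' @param seed Integer seed for the resampling stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(orthogroups, alignments = NULL,
                            de_tables = NULL, annotations = NULL,
                            out_dir = tempfile("orthodiv_run_"),
                            config = species_config(), alpha = 0.05,
                            contrast = "AvH", cutoff = 2.0,
                            min_overlap = 1, t_max = 10,
                            n_iter = 100000L, seed = 1L) {
  for (p in c(if (is.character(orthogroups)) orthogroups,
              if (is.character(alignments)) alignments,
              if (!is.null(de_tables))
                unlist(Filter(is.character, de_tables)),
              if (is.character(annotations)) annotations)) {
    if (!file.exists(p)) stop("input does not exist: ", p, call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  structure(list(orthogroups = orthogroups, alignments = alignments,
                 de_tables = de_tables, annotations = annotations,
                 out_dir = out_dir, config = config, alpha = alpha,
                 contrast = contrast, cutoff = cutoff,
                 min_overlap = min_overlap, t_max = t_max,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "pipeline_config")
}

read_stage_inputs <- function(pc) {
  ogs <- if (inherits(pc$orthogroups, "orthogroup_set")) pc$orthogroups
         else read_orthogroups(pc$orthogroups, pc$config)
  alns <- pc$alignments
  if (is.character(alns)) {
    files <- list.files(alns, pattern = "\\.(fa|fasta|faa)$",
                        full.names = TRUE)
    alns <- lapply(files, read_fasta_alignment)
  }
  de <- pc$de_tables
  if (!is.null(de)) {
    de <- lapply(stats::setNames(names(de), names(de)), function(s) {
      x <- de[[s]]
      if (is.character(x)) read_de_table(x, species = s,
                                         contrast = pc$contrast) else x
    })
  }
  ann <- pc$annotations
  if (is.character(ann)) ann <- read_annotation_table(ann)
  list(ogs = ogs, alignments = alns, de = de, annotations = ann)
}

#' Run the full analysis
#'
#' @param pc A [pipeline_config()].
#' @return List of class `pipeline_report` (also written to
#'   `out_dir/report.json`): input and parameter summary, annotation
#'   counts, DE classification counts, divergence summary, divergence-shift
#'   and composition test tables with BH-adjusted p-values, the
#'   signal-peptide goodness-of-fit result, and warning counts. Stages
#'   without inputs are skipped with a reason code.
#' @export
run_full_analysis <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  dir.create(pc$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  wcatch <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  inputs <- read_stage_inputs(pc)
  ogs <- inputs$ogs
  config <- pc$config
  report <- list(parameters = list(
    species = config$codes, reference = config$reference,
    alpha = pc$alpha, contrast = pc$contrast, cutoff = pc$cutoff,
    min_overlap = pc$min_overlap, t_max = pc$t_max,
    n_iter = pc$n_iter, seed = pc$seed),
    counts = list(n_orthogroups = length(ogs$og_ids),
                  n_transcripts = nrow(ogs$tab)))

  # --- annotation transfer ---------------------------------------------
  anns <- NULL
  if (!is.null(inputs$annotations)) {
    anns <- wcatch(transfer_annotations(ogs, inputs$annotations))
    anns <- retain_downstream(resolve_mixes(anns))
    write_og_annotations(anns, file.path(pc$out_dir, "og_annotations.tsv"))
    inter <- annotation_intersections(anns)
    utils::write.table(inter$combinations,
                       file.path(pc$out_dir, "annotation_intersections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$annotation <- list(
      n_with_reference = nrow(anns),
      n_annotated = sum(lengths(anns$resolved) > 0L),
      n_orphan_transcripts = length(attr(anns, "orphans")),
      label_totals = as.list(inter$totals))
  } else {
    report$annotation <- list(skipped = "no annotation table supplied")
  }

  # --- DE consistency --------------------------------------------------
  if (!is.null(inputs$de)) {
    calls <- lapply(inputs$de, call_de, alpha = pc$alpha)
    classes <- wcatch(classify_consistent_ogs(ogs, calls))
    utils::write.table(classes, file.path(pc$out_dir, "de_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$de <- as.list(table(classes$classification))
    report$de$n_eligible <- sum(classes$classification != "not_eligible")
  } else {
    classes <- NULL
    report$de <- list(skipped = "no DE tables supplied")
  }

  # --- divergence ------------------------------------------------------
  divs <- NULL
  if (!is.null(inputs$alignments) && length(inputs$alignments)) {
    model <- build_rate_matrix("JTT")
    divs <- og_divergence_table(inputs$alignments, ogs, model, config,
                                min_overlap = pc$min_overlap,
                                t_max = pc$t_max)
    divs <- exclude_saturated(divs, cutoff = pc$cutoff)
    utils::write.table(divs, file.path(pc$out_dir, "og_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$divergence <- list(
      n_alignments = length(inputs$alignments),
      n_usable = sum(divs$ok),
      n_excluded_saturated = attr(divs, "n_excluded"),
      median_divergence = stats::median(divs$divergence[divs$ok &
                                                        !divs$excluded]))
  } else {
    report$divergence <- list(skipped = "no alignments supplied")
  }

  # --- divergence-shift tests ------------------------------------------
  report$divergence_shift <- run_divergence_shift_stage(anns, divs)
  if (is.data.frame(report$divergence_shift)) {
    utils::write.table(report$divergence_shift,
                       file.path(pc$out_dir, "divergence_shift_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- composition resampling ------------------------------------------
  report$composition <- run_composition_stage(ogs, anns, config,
                                              n_iter = pc$n_iter,
                                              seed = pc$seed)
  if (is.data.frame(report$composition)) {
    utils::write.table(report$composition,
                       file.path(pc$out_dir, "composition_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- signal-peptide enrichment ---------------------------------------
  report$signalp_gof <- run_signalp_stage(ogs, anns, config,
                                          out_dir = pc$out_dir)

  report$warnings <- list(n = length(warnings_seen),
                          messages = warnings_seen)
  class(report) <- "pipeline_report"
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null", null = "null")
  writeLines(json, file.path(pc$out_dir, "report.json"))
  report
}

ANNOTATION_FAMILIES <- list(
  positional = list(source = c(POSITIONAL_LABELS, "positional_mix"),
                    tested = POSITIONAL_LABELS),
  neoblast = list(source = c(NEOBLAST_LABELS, "neoblast_mix"),
                  tested = c("neoblast_FACS", "neoblast_strict")),
  social = list(source = c(SOCIAL_LABELS, "social_mix"),
                tested = c("OvI", "BOTH")))

run_divergence_shift_stage <- function(anns, divs) {
  if (is.null(anns)) return(list(skipped = "no annotations"))
  if (is.null(divs)) return(list(skipped = "no divergence estimates"))
  usable <- divs[divs$ok & !divs$excluded, , drop = FALSE]
  div_of <- stats::setNames(usable$divergence, usable$og_id)
  in_div <- anns$og_id %in% names(div_of)
  rows <- list()
  for (fam in names(ANNOTATION_FAMILIES)) {
    spec <- ANNOTATION_FAMILIES[[fam]]
    has_src <- vapply(anns$resolved, function(x)
      any(x %in% spec$source), logical(1))
    unann <- anns$og_id[in_div & !has_src]
    if (length(unann) == 0L) next
    for (lab in spec$tested) {
      hit <- vapply(anns$retained, function(x) lab %in% x, logical(1))
      ids <- anns$og_id[in_div & hit]
      if (length(ids) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, label = lab, n = 0L, reference_median = NA_real_,
          statistic = NA_real_, p = NA_real_, degenerate = NA,
          stringsAsFactors = FALSE)
        next
      }
      res <- divergence_shift_test(div_of[ids], div_of[unann], label = lab)
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, label = lab, n = res$n,
        reference_median = res$reference_median,
        statistic = if (is.null(res$statistic) || is.na(res$statistic))
          NA_real_ else res$statistic,
        p = res$p, degenerate = res$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(list(skipped = "no testable labels"))
  out <- do.call(rbind, rows)
  tested <- !is.na(out$p)
  out$p_adj <- NA_real_
  out$p_adj[tested] <- bh_adjust(out$p[tested])
  out
}

run_composition_stage <- function(ogs, anns, config, n_iter, seed) {
  if (is.null(anns)) return(list(skipped = "no annotations"))
  comp <- species_composition(ogs)
  in_univ <- comp[, config$reference]
  predicates <- list(
    complete = composition_predicate("complete", config = config),
    pair_only = composition_predicate(
      "pair_only",
      species = c(config$reference,
                  setdiff(config$codes, config$reference)[[2L]]),
      config = config))
  labels <- sort(unique(unlist(anns$retained)))
  if (!length(labels)) return(list(skipped = "no retained labels"))
  rows <- list()
  for (pname in names(predicates)) {
    hits <- stats::setNames(predicate_hits(predicates[[pname]], comp),
                            rownames(comp))[in_univ]
    fam_rows <- list()
    for (k in seq_along(labels)) {
      lab <- labels[[k]]
      ids <- anns$og_id[vapply(anns$retained, function(x) lab %in% x,
                               logical(1))]
      ids <- intersect(ids, names(hits))
      if (!length(ids)) next
      res <- resample_composition_test(hits, ids, n_iter = n_iter,
                                       seed = seed + k, label = lab)
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        predicate = pname, label = lab, n_annotated = res$n_annotated,
        observed = res$observed, expected = res$expected,
        ci_lo = res$ci95[1], ci_hi = res$ci95[2], p = res$p,
        n_iter = res$n_iter, seed = res$seed, stringsAsFactors = FALSE)
    }
    if (length(fam_rows)) {
      fam <- do.call(rbind, fam_rows)
      fam$p_adj <- bh_adjust(fam$p)   # one BH family per predicate
      rows[[pname]] <- fam
    }
  }
  if (!length(rows)) return(list(skipped = "no testable labels"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_signalp_stage <- function(ogs, anns, config, out_dir = NULL) {
  if (is.null(anns)) return(list(skipped = "no annotations"))
  comp <- species_composition(ogs)
  complete <- rownames(comp)[rowSums(comp) == ncol(comp)]
  sub <- anns[anns$og_id %in% complete, , drop = FALSE]
  if (!nrow(sub)) return(list(skipped = "no complete annotated orthogroups"))
  pos_cat <- vapply(sub$resolved, function(x) {
    pos <- intersect(x, c(POSITIONAL_LABELS, "positional_mix"))
    if (length(pos)) pos[[1L]] else "no_annotation"
  }, character(1))
  cats <- c(POSITIONAL_LABELS, "positional_mix", "no_annotation")
  sizes <- as.integer(table(factor(pos_cat, levels = cats)))
  observed <- as.integer(tapply(sub$signalp,
                                factor(pos_cat, levels = cats), sum,
                                default = 0L))
  keep <- sizes > 0L
  if (sum(keep) < 2L || sum(observed) == 0L) {
    return(list(skipped = "fewer than two non-empty categories or no flags"))
  }
  res <- signalp_gof_test(observed[keep], sizes[keep])
  tab <- data.frame(category = cats[keep], size = sizes[keep],
                    observed = observed[keep], expected = res$expected,
                    residual = res$residuals, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    utils::write.table(tab, file.path(out_dir, "signalp_gof.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, chi2 = res$chi2, df = res$df, p = res$p)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("orthodiv pipeline report\n")
  cat("  orthogroups:", x$counts$n_orthogroups,
      "| transcripts:", x$counts$n_transcripts, "\n")
  if (!is.null(x$annotation$n_annotated)) {
    cat("  annotated OGs:", x$annotation$n_annotated, "\n")
  }
  if (!is.null(x$de$n_eligible)) {
    cat("  DE-eligible OGs:", x$de$n_eligible, "\n")
  }
  if (!is.null(x$divergence$n_usable)) {
    cat("  divergence estimates:", x$divergence$n_usable,
        sprintf("(median %.3f)", x$divergence$median_divergence), "\n")
  }
  invisible(x)
}
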