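#' Annotation transfer and mix resolution
#'
#' Reference-species transcript annotations are lifted to orthogroups on the
#' assumption that genes sharing an orthogroup share function: the raw label
#' set of an OG is the union of its reference members' labels. Conflicting
#' labels within an annotation family are then collapsed to a `*_mix`
#' category, and a fixed retention rule selects the labels carried into the
#' downstream tests.
#'
#' @name annotation_transfer
NULL

POSITIONAL_LABELS <- c("testis_region", "ovary_region", "tail_region")
NEOBLAST_LABELS <- c("germline_FACS", "neoblast_FACS", "neoblast_strict")
SOCIAL_LABELS <- c("OvI", "OvP", "BOTH")
MIX_LABELS <- c("positional_mix", "neoblast_mix", "social_mix")
RETAINED_LABELS <- c("testis_region", "ovary_region", "tail_region",
                     "neoblast_FACS", "neoblast_strict", "OvI", "BOTH")

#' Transfer transcript annotations to orthogroups
#'
#' For every orthogroup with at least one reference-species member, collects
#' the union of its reference members' labels. Orthogroups without reference
#' members yield no record. Labels attached to transcripts absent from every
#' orthogroup are counted and reported with a warning (they cannot be
#' transferred), never an error.
#'
#' @param ogs An [orthogroup_set()].
#' @param annotations An [annotation_table()] for the reference species.
#' @param reference Reference species code (default from the OG set's
#'   configuration).
#' @return An `og_annotation` data frame: columns `og_id`, `raw` (list of
#'   character vectors), `signalp` (logical), plus `resolved`/`retained`
#'   filled by [resolve_mixes()] / [retain_downstream()].
#' @export
transfer_annotations <- function(ogs, annotations,
                                 reference = ogs$config$reference) {
  stopifnot(inherits(ogs, "orthogroup_set"))
  ref_tab <- ogs$tab[ogs$tab$species == reference, , drop = FALSE]
  orphan <- setdiff(unique(annotations$transcript), ogs$tab$transcript)
  if (length(orphan)) {
    warning(length(orphan), " annotated transcript(s) absent from every ",
            "orthogroup; their labels were not transferred", call. = FALSE)
  }
  ann_og <- merge(ref_tab[, c("og_id", "transcript")], annotations,
                  by = "transcript")
  og_ids <- ogs$og_ids[ogs$og_ids %in% ref_tab$og_id]
  raw <- split(ann_og$label, factor(ann_og$og_id, levels = og_ids))
  raw <- lapply(raw, function(x) sort(unique(x)))
  out <- data.frame(og_id = og_ids, stringsAsFactors = FALSE)
  out$raw <- unname(raw)
  out$signalp <- vapply(raw, function(x) "signalp" %in% x, logical(1),
                        USE.NAMES = FALSE)
  out$resolved <- vector("list", nrow(out))
  out$retained <- vector("list", nrow(out))
  attr(out, "orphans") <- orphan
  class(out) <- c("og_annotation", "data.frame")
  out
}

resolve_one <- function(raw) {
  raw <- setdiff(raw, "signalp")
  out <- character()
  pos <- intersect(raw, POSITIONAL_LABELS)
  out <- c(out, if (length(pos) >= 2L) "positional_mix" else pos)
  neo <- intersect(raw, NEOBLAST_LABELS)
  neo_mix <- "germline_FACS" %in% neo &&
    any(c("neoblast_FACS", "neoblast_strict") %in% neo)
  out <- c(out, if (neo_mix) "neoblast_mix" else neo)
  soc <- intersect(raw, SOCIAL_LABELS)
  soc_mix <- all(c("OvI", "OvP") %in% soc) && !"BOTH" %in% soc
  out <- c(out, if (soc_mix) "social_mix" else soc)
  sort(unique(c(out, intersect(raw, MIX_LABELS))))
}

#' Resolve conflicting labels to mix categories
#'
#' Per annotation family, independently:
#' * positional: two or more distinct labels among `testis_region`,
#'   `ovary_region`, `tail_region` collapse to `positional_mix`; a single
#'   label carries over.
#' * neoblast: `germline_FACS` together with a neoblast label
#'   (`neoblast_FACS` or `neoblast_strict`) collapses all neoblast-source
#'   labels to `neoblast_mix`; otherwise labels carry over.
#' * social: `OvI` and `OvP` both present with no member carrying `BOTH`
#'   collapse to `social_mix`; when `BOTH` is present it carries over along
#'   with any `OvI`/`OvP` (the retention step then drops `OvP`).
#'
#' The `signalp` flag is unaffected. The operation is idempotent.
#'
#' @param anns An `og_annotation` from [transfer_annotations()] (or one
#'   already resolved; re-resolving is a no-op).
#' @return The same object with the `resolved` list-column filled.
#' @export
resolve_mixes <- function(anns) {
  src <- if (all(lengths(anns$resolved) == 0L) &&
             any(lengths(anns$raw) > 0L)) anns$raw else anns$resolved
  anns$resolved <- lapply(src, resolve_one)
  anns
}

#' Retain the labels used for downstream testing
#'
#' Keeps `testis_region`, `ovary_region`, `tail_region`, `neoblast_FACS`,
#' `neoblast_strict`, `OvI` and `BOTH`; drops `germline_FACS` (redundant with
#' the neoblast labels), `OvP` (small sample) and every `*_mix` category.
#' Mix categories stay visible in `resolved` for reporting, and
#' `positional_mix` additionally forms its own category in the
#' signal-peptide enrichment table.
#'
#' @param anns A resolved `og_annotation`.
#' @return The same object with the `retained` list-column filled.
#' @export
retain_downstream <- function(anns) {
  if (nrow(anns) && any(lengths(anns$raw) > 0L) &&
      all(lengths(anns$resolved) == 0L)) {
    stop("call resolve_mixes() before retain_downstream()", call. = FALSE)
  }
  anns$retained <- lapply(anns$resolved, intersect, RETAINED_LABELS)
  anns
}

#' @export
print.og_annotation <- function(x, ...) {
  cat("OG annotations:", nrow(x), "orthogroups with reference members;",
      sum(lengths(x$resolved) > 0L), "resolved,",
      sum(lengths(x$retained) > 0L), "retained for testing\n")
  invisible(x)
}

#' Count exact annotation-label intersections
#'
#' Tabulates orthogroups by their exact resolved label combination (the
#' quantity behind UpSet-style intersection plots) and, separately, the
#' total count per single label. The `signalp` flag is not part of the
#' combinations. Orthogroups with an empty resolved set are ignored.
#'
#' @param anns A resolved `og_annotation`.
#' @param min_count Suppress combinations with `count <= min_count` from the
#'   combination table (`0` keeps all; intersection plots often use 20).
#' @return List with `combinations` (data frame: `labels` (`+`-joined),
#'   `count`) sorted by decreasing count, and `totals` (named integer vector
#'   per label).
#' @export
annotation_intersections <- function(anns, min_count = 0) {
  lab_sets <- anns$resolved[lengths(anns$resolved) > 0L]
  if (!length(lab_sets)) {
    return(list(combinations = data.frame(labels = character(),
                                          count = integer()),
                totals = integer()))
  }
  key <- vapply(lab_sets, paste, character(1), collapse = "+")
  counts <- sort(table(key), decreasing = TRUE)
  comb <- data.frame(labels = names(counts),
                     count = as.integer(counts),
                     stringsAsFactors = FALSE)
  totals <- sort(table(unlist(lab_sets, use.names = FALSE)),
                 decreasing = TRUE)
  comb <- comb[comb$count > min_count, , drop = FALSE]
  rownames(comb) <- NULL
  list(combinations = comb,
       totals = stats::setNames(as.integer(totals), names(totals)))
}

#' Write per-orthogroup annotations to TSV
#'
#' @param anns An `og_annotation`.
#' @param path Output path; label sets are `+`-joined, empty sets written as
#'   `"."`.
#' @return `path`, invisibly.
#' @export
write_og_annotations <- function(anns, path) {
  join <- function(x) {
    out <- vapply(x, paste, character(1), collapse = "+")
    ifelse(nzchar(out), out, ".")
  }
  out <- data.frame(og_id = anns$og_id,
                    raw = join(anns$raw),
                    resolved = join(anns$resolved),
                    retained = join(anns$retained),
                    signalp = anns$signalp,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
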