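#' Differential-expression and annotation tables
#'
#' DE result tables are consumed as input (one per species and contrast):
#' per transcript a mean expression (`baseMean`), a signed log2 fold change
#' and a multiplicity-adjusted p-value; a missing (`NA`) adjusted p means the
#' transcript was removed by expression filtering before testing.
#' Annotation tables list (transcript, label) pairs for the reference
#' species; repeated pairs collapse to one (set semantics).
#'
#' @name tables
NULL

#' Annotation label vocabulary
#'
#' The transcript-level labels that can be attached to reference-species
#' transcripts: positional body-region labels (`testis_region`,
#' `ovary_region`, `tail_region`), stem-cell labels (`germline_FACS`,
#' `neoblast_FACS`, `neoblast_strict`), social-environment labels (`OvI`,
#' `OvP`, `BOTH`) and the secretory-signal flag `signalp`.
#'
#' @return Character vector of valid transcript-level labels.
#' @export
annotation_labels <- function() {
  c("testis_region", "ovary_region", "tail_region",
    "germline_FACS", "neoblast_FACS", "neoblast_strict",
    "OvI", "OvP", "BOTH", "signalp")
}

#' Read a per-species DE result table
#'
#' @param path TSV with header columns `transcript`, `baseMean`,
#'   `log2FoldChange`, `padj` (literal `"NA"` in `padj` means
#'   filtered-before-testing).
#' @param species Species code the table belongs to.
#' @param contrast Contrast ID, one of `"AvH"`, `"AvR"`, `"RvH"` (or any
#'   configured label).
#' @return A `de_table`: data frame with the four columns and attributes
#'   `species` and `contrast`.
#' @export
read_de_table <- function(path, species, contrast) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  need <- c("transcript", "baseMean", "log2FoldChange", "padj")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) {
    stop("DE table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & x != "NA")
    if (length(bad)) {
      stop("non-numeric value '", x[bad[1L]], "' in column ", col,
           " at data row ", bad[1L], call. = FALSE)
    }
    out
  }
  tab <- data.frame(transcript = raw$transcript,
                    baseMean = num("baseMean"),
                    log2FoldChange = num("log2FoldChange"),
                    padj = num("padj"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$transcript)) {
    stop("duplicate transcript IDs in DE table ", path, call. = FALSE)
  }
  if (any(tab$baseMean < 0, na.rm = TRUE)) {
    stop("negative baseMean in DE table ", path, call. = FALSE)
  }
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE)) {
    stop("padj outside [0, 1] in DE table ", path, call. = FALSE)
  }
  de_table(tab, species, contrast)
}

#' Construct a DE table from a data frame
#'
#' @param df Data frame with columns `transcript`, `baseMean`,
#'   `log2FoldChange`, `padj`.
#' @param species,contrast See [read_de_table()].
#' @return A `de_table`.
#' @export
de_table <- function(df, species, contrast) {
  stopifnot(all(c("transcript", "baseMean", "log2FoldChange", "padj")
                %in% colnames(df)))
  attr(df, "species") <- as.character(species)
  attr(df, "contrast") <- as.character(contrast)
  class(df) <- c("de_table", "data.frame")
  df
}

#' Write a DE table
#'
#' @param tab A `de_table`.
#' @param path Output path; `NA` padj values are written as literal `"NA"`.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation table
#'
#' @param path TSV with header columns `transcript` and `label`; labels must
#'   come from [annotation_labels()]. Duplicate (transcript, label) pairs are
#'   collapsed.
#' @return An `annotation_table`: data frame with columns `transcript`,
#'   `label`.
#' @export
read_annotation_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  miss <- setdiff(c("transcript", "label"), colnames(raw))
  if (length(miss)) {
    stop("annotation table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  annotation_table(raw$transcript, raw$label)
}

#' Construct an annotation table
#'
#' @param transcript,label Parallel character vectors of (transcript, label)
#'   pairs.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(transcript, label) {
  bad <- setdiff(unique(label), annotation_labels())
  if (length(bad)) {
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df <- unique(data.frame(transcript = as.character(transcript),
                          label = as.character(label),
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write an annotation table
#'
#' @param tab An `annotation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
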