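#' Orthogroup collections
#'
#' An `orthogroup_set` holds the membership of every orthogroup (OG): for each
#' OG, the transcript IDs it contains per species. Internally the memberships
#' are stored in long format (one row per transcript) together with the ordered
#' OG IDs and the species configuration, which keeps all per-OG summaries
#' vectorised.
#'
#' @name orthogroup_set
NULL

new_orthogroup_set <- function(og_ids, tab, config) {
  stopifnot(is.character(og_ids), is.data.frame(tab))
  structure(list(og_ids = og_ids, tab = tab, config = config),
            class = "orthogroup_set")
}

#' Build an orthogroup set from a long table
#'
#' @param og_id,species,transcript Parallel vectors: one entry per transcript.
#' @param config A [species_config()].
#' @param og_ids Optional full set of OG IDs (to keep OGs that would otherwise
#'   appear empty; an OG must still have at least one member).
#' @return An `orthogroup_set`.
#' @export
orthogroup_set <- function(og_id, species, transcript,
                           config = species_config(), og_ids = NULL) {
  tab <- data.frame(og_id = as.character(og_id),
                    species = as.character(species),
                    transcript = as.character(transcript),
                    stringsAsFactors = FALSE)
  if (is.null(og_ids)) og_ids <- unique(tab$og_id)
  validate_orthogroup_set(new_orthogroup_set(og_ids, tab, config))
}

validate_orthogroup_set <- function(x) {
  tab <- x$tab
  if (anyDuplicated(x$og_ids)) {
    dup <- unique(x$og_ids[duplicated(x$og_ids)])
    stop("duplicate orthogroup ID(s): ", paste(utils::head(dup, 5L),
         collapse = ", "), call. = FALSE)
  }
  bad_sp <- setdiff(unique(tab$species), x$config$codes)
  if (length(bad_sp)) {
    stop("unknown species code(s) in memberships: ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$transcript)) {
    dup <- tab$transcript[duplicated(tab$transcript)]
    first <- tab[tab$transcript %in% dup, , drop = FALSE]
    stop("transcript(s) assigned to more than one orthogroup or listed twice: ",
         paste(utils::head(unique(dup), 5L), collapse = ", "), call. = FALSE)
  }
  empty <- setdiff(x$og_ids, unique(tab$og_id))
  if (length(empty)) {
    stop("orthogroup(s) with no members in any species: ",
         paste(utils::head(empty, 5L), collapse = ", "), call. = FALSE)
  }
  if (!all(tab$og_id %in% x$og_ids)) {
    stop("membership rows reference unknown orthogroup IDs", call. = FALSE)
  }
  x
}

#' @export
print.orthogroup_set <- function(x, ...) {
  cat("Orthogroup set:", length(x$og_ids), "orthogroups,",
      nrow(x$tab), "transcripts,",
      length(x$config$codes), "species (",
      paste(x$config$codes, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
length.orthogroup_set <- function(x) length(x$og_ids)

#' Members of one orthogroup
#'
#' @param ogs An `orthogroup_set`.
#' @param og_id Single OG ID.
#' @return Named list, one character vector of transcript IDs per species
#'   (empty vector where the species is absent).
#' @export
og_members <- function(ogs, og_id) {
  if (!og_id %in% ogs$og_ids) stop("unknown orthogroup: ", og_id, call. = FALSE)
  sub <- ogs$tab[ogs$tab$og_id == og_id, , drop = FALSE]
  out <- lapply(ogs$config$codes, function(s) sub$transcript[sub$species == s])
  names(out) <- ogs$config$codes
  out
}

#' Species composition of orthogroups
#'
#' The set of species with at least one member, reported as a logical
#' presence/absence matrix over the configured species.
#'
#' @param ogs An `orthogroup_set`.
#' @return Logical matrix, one row per OG (rownames = OG IDs), one column per
#'   species code.
#' @export
#' @examples
#' ogs <- orthogroup_set(og_id = c("OG1", "OG1", "OG2"),
#'                       species = c("Mlig", "Mspi", "Mhys"),
#'                       transcript = c("a", "b", "c"))
#' species_composition(ogs)
species_composition <- function(ogs) {
  codes <- ogs$config$codes
  m <- matrix(FALSE, length(ogs$og_ids), length(codes),
              dimnames = list(ogs$og_ids, codes))
  i <- match(ogs$tab$og_id, ogs$og_ids)
  j <- match(ogs$tab$species, codes)
  m[cbind(i, j)] <- TRUE
  m
}

#' Read an orthogroup membership table
#'
#' Reads the tab-separated dialect emitted by orthology inference tools: a
#' header row naming the orthogroup column first and then one column per
#' species; each cell lists the transcript IDs of that species, separated by
#' commas (`", "` or `","` are both accepted); an empty cell means the species
#' is absent from the orthogroup.
#'
#' @param path Path to the TSV file.
#' @param config A [species_config()]; its codes must match the header's
#'   species columns (order taken from the file).
#' @return An `orthogroup_set`.
#' @export
read_orthogroups <- function(path, config = species_config()) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", na.strings = NULL)
  if (ncol(raw) < 2L) stop("orthogroup table needs an ID column and at least ",
                           "one species column", call. = FALSE)
  sp_cols <- colnames(raw)[-1L]
  missing_sp <- setdiff(config$codes, sp_cols)
  extra_sp <- setdiff(sp_cols, config$codes)
  if (length(missing_sp) || length(extra_sp)) {
    stop("species columns do not match the configured set; missing: [",
         paste(missing_sp, collapse = ", "), "], unexpected: [",
         paste(extra_sp, collapse = ", "), "]", call. = FALSE)
  }
  og_ids <- raw[[1L]]
  parts <- lapply(sp_cols, function(s) {
    cell <- trimws(raw[[s]])
    ids <- strsplit(cell, ",", fixed = TRUE)
    ids[!nzchar(cell)] <- list(character())
    n <- lengths(ids)
    data.frame(og_id = rep(og_ids, n),
               species = rep(s, sum(n)),
               transcript = trimws(unlist(ids, use.names = FALSE)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, parts)
  validate_orthogroup_set(new_orthogroup_set(og_ids, long, config))
}

#' Write an orthogroup membership table
#'
#' Inverse of [read_orthogroups()]; cells are joined with `", "`.
#'
#' @param ogs An `orthogroup_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(ogs, path) {
  codes <- ogs$config$codes
  cells <- matrix("", length(ogs$og_ids), length(codes),
                  dimnames = list(NULL, codes))
  sp_split <- split(ogs$tab, ogs$tab$species)
  for (s in names(sp_split)) {
    sub <- sp_split[[s]]
    joined <- vapply(split(sub$transcript, factor(sub$og_id, ogs$og_ids)),
                     paste, character(1), collapse = ", ")
    cells[, s] <- joined
  }
  out <- data.frame(Orthogroup = ogs$og_ids, cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
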