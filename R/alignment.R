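#' Protein alignments
#'
#' A `protein_alignment` is a per-orthogroup amino-acid multiple alignment:
#' equal-length rows over the 20 amino-acid letters plus the gap symbol `-`
#' and the ambiguity symbol `X`. `X` is treated as missing data downstream
#' (excluded from likelihood columns), never as an error.
#'
#' @name protein_alignment
NULL

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
ALN_ALPHABET <- c(AA_LETTERS, "-", "X")

#' Construct a protein alignment
#'
#' @param ids Character vector of sequence (transcript) IDs.
#' @param seqs Character vector of aligned sequences, same length as `ids`.
#' @param og_id Optional orthogroup ID the alignment belongs to.
#' @param species Optional character vector giving the species of each row
#'   (resolved later via [resolve_species()] when `NULL`).
#' @param validate Check the residue vocabulary character by character
#'   (default). Internal callers constructing rows from already validated
#'   material may disable it.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(ids, seqs, og_id = NA_character_,
                              species = NULL, validate = TRUE) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs differ in length", call. = FALSE)
  }
  if (length(seqs) < 2L) {
    stop("an alignment needs at least two sequences", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  }
  if (validate) {
    ok_codes <- utf8ToInt(paste(ALN_ALPHABET, collapse = ""))
    for (i in seq_along(seqs)) {
      codes <- utf8ToInt(seqs[[i]])
      bad <- which(!codes %in% ok_codes)
      if (length(bad)) {
        stop("illegal symbol '", intToUtf8(codes[bad[1L]]),
             "' in sequence '", ids[[i]], "' at column ", bad[1L],
             call. = FALSE)
      }
    }
  }
  if (!is.null(species)) {
    stopifnot(length(species) == length(ids))
    species <- as.character(species)
  }
  structure(list(og_id = og_id, ids = ids, species = species, seqs = seqs,
                 length = widths[[1L]]),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Protein alignment", if (!is.na(x$og_id)) paste0("[", x$og_id, "]"),
      ":", length(x$ids), "sequences x", x$length, "columns\n")
  invisible(x)
}

#' @export
length.protein_alignment <- function(x) length(x$ids)

#' Read a FASTA protein alignment
#'
#' Parses FASTA via Biostrings, normalises lower-case residues to upper case,
#' and validates that all rows have equal length and use only the 20
#' amino-acid letters, `-` and `X`.
#'
#' @param path FASTA file path.
#' @param og_id Optional orthogroup ID (defaults to the file name without
#'   extension).
#' @return A `protein_alignment` with rows in file order.
#' @export
read_fasta_alignment <- function(path, og_id = NULL) {
  if (is.null(og_id)) {
    og_id <- sub("\\.[^.]*$", "", basename(path))
  }
  set <- Biostrings::readBStringSet(path)
  protein_alignment(ids = names(set), seqs = as.character(set), og_id = og_id)
}

#' Write a protein alignment to FASTA
#'
#' @param aln A `protein_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Integer encoding used by the distance kernels: 1..20 = amino acids in the
# fixed ARNDCQEGHILKMFPSTWYV order, 0 = gap or X (missing). Rows x columns.
encode_alignment <- function(aln) {
  lut <- integer(256)
  lut[utf8ToInt(paste(AA_LETTERS, collapse = ""))] <- seq_len(20L)
  m <- matrix(0L, length(aln$ids), aln$length)
  for (i in seq_along(aln$seqs)) {
    m[i, ] <- lut[utf8ToInt(aln$seqs[[i]])]
  }
  rownames(m) <- aln$ids
  m
}
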