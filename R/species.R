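#' Species configuration
#'
#' Defines the set of species codes an analysis operates on, which one is the
#' annotated reference species, and an optional map from transcript-ID prefixes
#' to species codes (used to resolve the species of alignment rows when no
#' orthogroup table is at hand).
#'
#' The default set is the four *Macrostomum* species of the study system:
#' `Mlig` (*M. lignano*, the annotated reference), `Mhys` (*M. hystrix*),
#' `Mspi` (*M. spirale*) and `Mpus` (*M. pusillum*).
#'
#' @param codes Character vector of unique species codes.
#' @param reference Single code naming the reference species; must be one of
#'   `codes`.
#' @param prefix_map Named character vector mapping transcript-ID prefixes to
#'   species codes (values must be in `codes`), e.g.
#'   `c(Mlig = "Mlig", Machtx = "Mhys")`.
#' @return An object of class `species_config`.
#' @export
#' @examples
#' species_config()
#' species_config(codes = c("A", "B"), reference = "A")
species_config <- function(codes = c("Mlig", "Mhys", "Mspi", "Mpus"),
                           reference = codes[[1L]],
                           prefix_map = stats::setNames(codes, codes)) {
  codes <- as.character(codes)
  if (length(codes) < 2L) {
    stop("need at least two species codes", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("species codes must be unique", call. = FALSE)
  }
  if (length(reference) != 1L || !reference %in% codes) {
    stop("reference species '", reference,
         "' is not in the configured species set", call. = FALSE)
  }
  if (length(prefix_map)) {
    if (is.null(names(prefix_map)) || any(!nzchar(names(prefix_map)))) {
      stop("prefix_map must be a named character vector", call. = FALSE)
    }
    bad <- setdiff(unique(prefix_map), codes)
    if (length(bad)) {
      stop("prefix_map targets unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(codes = codes, reference = reference,
                 prefix_map = prefix_map),
            class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species configuration:", paste(x$codes, collapse = ", "),
      "\n  reference:", x$reference, "\n")
  invisible(x)
}

#' Default species tree
#'
#' The fixed four-taxon topology used throughout, with branch lengths in
#' expected amino-acid substitutions per site. The defaults place
#' *M. lignano* and *M. hystrix* as closest relatives, *M. spirale* next and
#' *M. pusillum* on the deepest branch, and are calibrated so the mean
#' pairwise path length (the expected background orthogroup divergence) is
#' about 0.5 substitutions per site.
#'
#' @param newick Optional newick string overriding the default.
#' @return An [ape::phylo] tree.
#' @export
#' @examples
#' tr <- default_species_tree()
#' tr$tip.label
default_species_tree <- function(newick = NULL) {
  if (is.null(newick)) {
    newick <- "(((Mlig:0.08,Mhys:0.08):0.07,Mspi:0.15):0.10,Mpus:0.45);"
  }
  ape::read.tree(text = newick)
}

# Resolve species for transcript IDs: first via the orthogroup table, then via
# the prefix map (longest matching prefix wins). Unresolvable IDs come back NA.
resolve_species <- function(ids, ogs = NULL, config = species_config()) {
  out <- rep(NA_character_, length(ids))
  if (!is.null(ogs)) {
    tab <- ogs$tab
    m <- match(ids, tab$transcript)
    out[!is.na(m)] <- tab$species[m[!is.na(m)]]
  }
  todo <- which(is.na(out))
  if (length(todo) && length(config$prefix_map)) {
    pref <- names(config$prefix_map)
    pref <- pref[order(nchar(pref), decreasing = TRUE)]
    for (p in pref) {
      hit <- todo[startsWith(ids[todo], p)]
      if (length(hit)) {
        out[hit] <- config$prefix_map[[p]]
        todo <- setdiff(todo, hit)
      }
    }
  }
  out
}
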