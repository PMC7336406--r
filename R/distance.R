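#' Pairwise ML distances and per-orthogroup divergence
#'
#' Protein divergence is summarised per orthogroup from maximum-likelihood
#' pairwise distances between its aligned member sequences: gap/ambiguity
#' columns are removed pairwise, within-species pairs are discarded, each
#' species pair is summarised as the mean of all between-species sequence
#' pairs, and the orthogroup divergence is the mean of the six species-pair
#' means.
#'
#' @name jtt_divergence
NULL

#' Maximum-likelihood distance between two aligned sequences
#'
#' Maximises the likelihood `prod(pi[a] * P[a, b](t))` over the comparable
#' columns (both residues; gap and `X` columns dropped pairwise), by Brent
#' optimisation of `t` on `[1e-6, t_max]` with convergence tolerance `1e-6`.
#' Identical comparable columns clamp the distance to zero.
#'
#' @param a,b Aligned sequences: character strings of equal length, or
#'   integer-encoded vectors (1-20 residues, 0 missing).
#' @param model A [build_rate_matrix()] model.
#' @param t_max Upper optimisation bound (expected substitutions per site).
#' @return List of class `pairwise_distance`: `t_hat`, `n_sites`
#'   (comparable columns), `saturated` (`t_hat >= t_max - 1e-3`).
#' @export
#' @examples
#' m <- build_rate_matrix("JTT")
#' pairwise_ml_distance("ARNDC", "ARNDW", m)
pairwise_ml_distance <- function(a, b, model, t_max = 10) {
  if (is.character(a)) a <- encode_sequence(a)
  if (is.character(b)) b <- encode_sequence(b)
  if (length(a) != length(b)) {
    stop("sequences differ in length", call. = FALSE)
  }
  fit <- .cpp_pair_distance(a, b, model$U, model$W, model$eigenvalues,
                            log(model$pi), 1e-6, t_max, 1e-6)
  if (fit$n_sites == 0) {
    stop("no comparable columns between the two sequences", call. = FALSE)
  }
  structure(list(t_hat = fit$t_hat, n_sites = fit$n_sites,
                 saturated = fit$t_hat >= t_max - 1e-3),
            class = "pairwise_distance")
}

#' @export
print.pairwise_distance <- function(x, ...) {
  cat(sprintf("ML distance: %.6f substitutions/site (%d comparable sites%s)\n",
              x$t_hat, as.integer(x$n_sites),
              if (x$saturated) ", saturated" else ""))
  invisible(x)
}

encode_sequence <- function(s) {
  stopifnot(length(s) == 1L)
  lut <- integer(256)
  lut[utf8ToInt(paste(AA_LETTERS, collapse = ""))] <- seq_len(20L)
  lut[utf8ToInt(toupper(s))]
}

# comparable-column counts for every row pair (residue = 1..20)
overlap_matrix <- function(enc) {
  M <- (enc > 0L) + 0
  M %*% t(M)
}

#' Filter alignment rows to a mutually overlapping set
#'
#' Guarantees that every retained pair of rows shares at least `min_overlap`
#' comparable columns (columns where both rows carry a residue). Rows are
#' dropped greedily: repeatedly remove the row with the most
#' under-overlapping partners, breaking ties by fewest non-gap residues and
#' then by lexicographically smallest ID, until the condition holds.
#'
#' @param aln A [protein_alignment()].
#' @param min_overlap Minimum comparable columns per retained pair
#'   (default 1).
#' @return List: `alignment` (the filtered `protein_alignment`, or `NULL`
#'   when fewer than two rows survive), `dropped` (IDs removed), `usable`
#'   (logical; `FALSE` when fewer than two rows remain).
#' @export
overlap_filter <- function(aln, min_overlap = 1) {
  enc <- encode_alignment(aln)
  keep <- seq_along(aln$ids)
  dropped <- character()
  repeat {
    ov <- overlap_matrix(enc[keep, , drop = FALSE])
    diag(ov) <- Inf
    bad_deg <- rowSums(ov < min_overlap)
    if (all(bad_deg == 0)) break
    nres <- rowSums(enc[keep, , drop = FALSE] > 0L)
    ids <- aln$ids[keep]
    ord <- order(-bad_deg, nres, ids)
    victim <- ord[[1L]]
    dropped <- c(dropped, ids[[victim]])
    keep <- keep[-victim]
    if (length(keep) < 2L) break
  }
  if (length(keep) < 2L) {
    return(list(alignment = NULL, dropped = aln$ids[-keep], usable = FALSE))
  }
  out <- protein_alignment(ids = aln$ids[keep], seqs = aln$seqs[keep],
                           og_id = aln$og_id,
                           species = if (!is.null(aln$species))
                             aln$species[keep],
                           validate = FALSE)
  list(alignment = out, dropped = dropped, usable = TRUE)
}

#' All pairwise ML distances within an alignment
#'
#' @param aln A [protein_alignment()].
#' @param model A [build_rate_matrix()] model.
#' @param t_max Upper optimisation bound.
#' @return Data frame: `id_a`, `id_b`, `t_hat`, `n_sites`, `saturated`
#'   (one row per unordered pair; `t_hat` is `NA` for pairs with no
#'   comparable columns).
#' @export
all_pairwise_distances <- function(aln, model, t_max = 10) {
  enc <- encode_alignment(aln)
  fit <- .cpp_all_pair_distances(enc, model$U, model$W, model$eigenvalues,
                                 log(model$pi), 1e-6, t_max, 1e-6)
  data.frame(id_a = aln$ids[fit$i], id_b = aln$ids[fit$j],
             t_hat = fit$t_hat, n_sites = fit$n_sites,
             saturated = !is.na(fit$t_hat) & fit$t_hat >= t_max - 1e-3,
             stringsAsFactors = FALSE)
}

#' Per-orthogroup mean protein divergence
#'
#' Computes all between-species pairwise ML distances in the (already
#' overlap-filtered) alignment, averages them within each species pair, and
#' averages the species-pair means into one divergence estimate for the
#' orthogroup. Within-species pairs are excluded throughout. The divergence
#' is defined only when every species pair retains at least one comparable
#' sequence pair and all configured species are present.
#'
#' @param aln A [protein_alignment()] whose rows cover the orthogroup's
#'   members; species are resolved from `og` (fallback: the configuration's
#'   prefix map).
#' @param og An [orthogroup_set()] used to resolve row species (may be
#'   `NULL` when `aln$species` is already set).
#' @param model A [build_rate_matrix()] model.
#' @param config A [species_config()].
#' @param t_max Upper optimisation bound per pair.
#' @return List of class `og_divergence`: `og_id`, `pair_means` (named by
#'   `"spA|spB"`), `divergence`, `n_saturated_pairs`, `ok` (logical) and
#'   `reason` (`NA` or why the orthogroup is unusable: `missing_species`,
#'   `no_comparable_pair`, `unresolved_species`).
#' @export
og_mean_divergence <- function(aln, og = NULL, model,
                               config = species_config(), t_max = 10) {
  species <- aln$species
  if (is.null(species)) {
    species <- resolve_species(aln$ids, og, config)
  }
  fail <- function(reason) {
    structure(list(og_id = aln$og_id, pair_means = NULL, divergence = NA_real_,
                   n_saturated_pairs = NA_integer_, ok = FALSE,
                   reason = reason),
              class = "og_divergence")
  }
  if (anyNA(species)) return(fail("unresolved_species"))
  if (!all(config$codes %in% species)) return(fail("missing_species"))

  pair_key <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
  }
  d <- all_pairwise_distances(aln, model, t_max = t_max)
  sp_a <- species[match(d$id_a, aln$ids)]
  sp_b <- species[match(d$id_b, aln$ids)]
  use <- sp_a != sp_b & !is.na(d$t_hat)
  d <- d[use, , drop = FALSE]
  keys <- pair_key(sp_a[use], sp_b[use])
  codes <- config$codes
  want <- outer(codes, codes, pair_key)
  want <- unique(want[lower.tri(want)])
  means <- tapply(d$t_hat, factor(keys, levels = want), mean)
  if (anyNA(means)) return(fail("no_comparable_pair"))
  structure(list(og_id = aln$og_id,
                 pair_means = stats::setNames(as.numeric(means), want),
                 divergence = mean(means),
                 n_saturated_pairs = sum(d$saturated),
                 ok = TRUE, reason = NA_character_),
            class = "og_divergence")
}

#' @export
print.og_divergence <- function(x, ...) {
  if (!x$ok) {
    cat("OG divergence [", x$og_id, "]: unusable (", x$reason, ")\n",
        sep = "")
  } else {
    cat(sprintf("OG divergence [%s]: %.4f substitutions/site (%d saturated pairs)\n",
                x$og_id, x$divergence, x$n_saturated_pairs))
  }
  invisible(x)
}

#' Divergence for a collection of alignments
#'
#' @param alignments List of [protein_alignment()]s (or a directory of FASTA
#'   files, read via [read_fasta_alignment()]).
#' @param ogs An [orthogroup_set()] for species resolution.
#' @param model A [build_rate_matrix()] model.
#' @param config A [species_config()].
#' @param min_overlap Overlap filter threshold (see [overlap_filter()]).
#' @param t_max Upper optimisation bound per pair.
#' @return Data frame: `og_id`, one column per species pair, `divergence`,
#'   `n_saturated_pairs`, `ok`, `reason`.
#' @export
og_divergence_table <- function(alignments, ogs = NULL, model,
                                config = species_config(),
                                min_overlap = 1, t_max = 10) {
  if (is.character(alignments) && length(alignments) == 1L &&
      dir.exists(alignments)) {
    files <- list.files(alignments, pattern = "\\.(fa|fasta|faa)$",
                        full.names = TRUE)
    alignments <- lapply(files, read_fasta_alignment)
  }
  codes <- config$codes
  keys <- outer(codes, codes, function(a, b)
    paste(pmin(a, b), pmax(a, b), sep = "|"))
  keys <- unique(keys[lower.tri(keys)])
  n <- length(alignments)
  pm <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
  og_id <- character(n)
  divergence <- rep(NA_real_, n)
  n_sat <- rep(NA_integer_, n)
  ok <- logical(n)
  reason <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    aln <- alignments[[k]]
    filt <- overlap_filter(aln, min_overlap = min_overlap)
    if (!filt$usable) {
      og_id[k] <- aln$og_id
      reason[k] <- "overlap_filter_left_below_two"
      next
    }
    div <- og_mean_divergence(filt$alignment, ogs, model, config,
                              t_max = t_max)
    og_id[k] <- div$og_id
    reason[k] <- div$reason
    ok[k] <- div$ok
    if (div$ok) {
      pm[k, names(div$pair_means)] <- div$pair_means
      divergence[k] <- div$divergence
      n_sat[k] <- div$n_saturated_pairs
    }
  }
  out <- data.frame(og_id = og_id, pm, divergence = divergence,
                    n_saturated_pairs = n_sat, ok = ok, reason = reason,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclude near-saturated orthogroups
#'
#' Orthogroups whose mean divergence exceeds the cutoff (strictly greater
#' than; default two substitutions per site) are close to saturation or
#' reflect misalignment and are removed from downstream comparison.
#'
#' @param divs Data frame from [og_divergence_table()].
#' @param cutoff Exclusion threshold (default 2.0).
#' @return `divs` with a logical `excluded` column added (usable rows only
#'   can be excluded) and attribute `n_excluded`.
#' @export
exclude_saturated <- function(divs, cutoff = 2.0) {
  divs$excluded <- !is.na(divs$divergence) & divs$divergence > cutoff
  attr(divs, "n_excluded") <- sum(divs$excluded)
  divs
}
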