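#' Synthetic orthogroup data
#'
#' Generates inputs with the statistical structure the analysis assumes: an
#' orthogroup universe whose species completeness, divergence scale,
#' signal-peptide probability and DE behaviour depend on a planted
#' annotation class; per-orthogroup amino-acid alignments simulated under
#' the JTT model on the fixed species tree; per-species DE result tables
#' with planted consistent/inconsistent signals; and reference-species
#' annotation and signal-peptide flags. All generators are reproducible
#' under a fixed seed and emit (or can write) the exact formats the readers
#' consume.
#'
#' @name synthetic_data
NULL

#' Per-class simulation settings
#'
#' @param label Annotation class label from [annotation_labels()], or `NA`
#'   for the unannotated background.
#' @param prevalence Fraction of orthogroups in this class.
#' @param completeness Probability that each non-reference species is
#'   present in an orthogroup of this class (the reference species is
#'   always present for annotated classes).
#' @param divergence_scale Multiplier on the species-tree branch lengths
#'   for alignments of this class.
#' @param signalp_prob Probability that a reference transcript of this
#'   class carries the signal-peptide flag.
#' @param de_probs Probabilities of the planted DE classes
#'   `consistent_up_first`, `consistent_up_second`, `inconsistent`, `none`
#'   (must sum to one).
#' @return List of class `sim_class`.
#' @export
sim_class <- function(label, prevalence, completeness = 0.8,
                      divergence_scale = 1.0, signalp_prob = 0.1,
                      de_probs = c(consistent_up_first = 0,
                                   consistent_up_second = 0,
                                   inconsistent = 0, none = 1)) {
  stopifnot(is.na(prevalence) || (prevalence >= 0 && prevalence <= 1),
            completeness >= 0, completeness <= 1,
            divergence_scale >= 0,
            signalp_prob >= 0, signalp_prob <= 1)
  de_probs <- de_probs[c("consistent_up_first", "consistent_up_second",
                         "inconsistent", "none")]
  if (anyNA(de_probs) || abs(sum(de_probs) - 1) > 1e-9) {
    stop("de_probs must cover the four DE classes and sum to 1",
         call. = FALSE)
  }
  structure(list(label = label, prevalence = prevalence,
                 completeness = completeness,
                 divergence_scale = divergence_scale,
                 signalp_prob = signalp_prob, de_probs = de_probs),
            class = "sim_class")
}

#' Simulation configuration
#'
#' The defaults emulate the study conditions at desk scale: a four-taxon
#' universe on the fixed species tree with background divergence centred
#' near 0.5 substitutions per site, a rapidly evolving reproduction-like
#' class (`testis_region`: lower completeness, higher divergence, elevated
#' signal-peptide probability, adult-biased DE) and a conserved
#' stem-cell-like class (`neoblast_FACS`: high completeness, lower
#' divergence).
#'
#' @param n_ogs Number of orthogroups.
#' @param tree Species tree with branch lengths ([default_species_tree()]).
#' @param config A [species_config()].
#' @param classes List of [sim_class()] specifications; prevalences must
#'   sum to at most one, the remainder is unannotated background.
#' @param background A [sim_class()] for the unannotated remainder.
#' @param duplication_rate Mean number of extra transcripts per present
#'   species (Poisson).
#' @param stub_length Terminal branch length for within-species duplicate
#'   transcripts (near-copies).
#' @param alignment_length Alignment columns.
#' @param alpha DE significance threshold the planted signals straddle.
#' @param contrast Contrast ID for the generated DE tables.
#' @param seed Integer RNG seed.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_ogs = 1000L,
                              tree = default_species_tree(),
                              config = species_config(),
                              classes = list(
                                sim_class("testis_region", prevalence = 0.02,
                                          completeness = 0.5,
                                          divergence_scale = 1.5,
                                          signalp_prob = 0.3,
                                          de_probs = c(consistent_up_first = 0.8,
                                                       consistent_up_second = 0,
                                                       inconsistent = 0.1,
                                                       none = 0.1)),
                                sim_class("neoblast_FACS", prevalence = 0.02,
                                          completeness = 0.95,
                                          divergence_scale = 0.7,
                                          signalp_prob = 0.1,
                                          de_probs = c(consistent_up_first = 0.1,
                                                       consistent_up_second = 0.3,
                                                       inconsistent = 0.1,
                                                       none = 0.5))),
                              background = sim_class(NA_character_,
                                                     prevalence = NA_real_,
                                                     completeness = 0.8),
                              duplication_rate = 0.2,
                              stub_length = 0.01,
                              alignment_length = 200L,
                              alpha = 0.05,
                              contrast = "AvH",
                              seed = 1L) {
  prev <- vapply(classes, `[[`, numeric(1), "prevalence")
  if (sum(prev) > 1) stop("class prevalences exceed 1", call. = FALSE)
  if (!setequal(tree$tip.label, config$codes)) {
    stop("tree tips must match the configured species", call. = FALSE)
  }
  background$prevalence <- 1 - sum(prev)
  structure(list(n_ogs = as.integer(n_ogs), tree = tree, config = config,
                 classes = classes, background = background,
                 duplication_rate = duplication_rate,
                 stub_length = stub_length,
                 alignment_length = as.integer(alignment_length),
                 alpha = alpha, contrast = contrast,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample child states given parent states; cumP = row-wise cumulative
# transition matrix
evolve_states <- function(parent, cumP) {
  u <- stats::runif(length(parent))
  rowSums(cumP[parent, , drop = FALSE] < u) + 1L
}

# row-wise cumulative P(t), memoised on the (possibly scaled) branch length
cum_transition <- function(model, bl, cache = NULL) {
  key <- sprintf("%.12g", bl)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  P <- transition_probabilities(model, bl)
  cum <- P
  for (j in 2:ncol(P)) cum[, j] <- cum[, j - 1L] + P[, j]
  if (!is.null(cache)) cache[[key]] <- cum
  cum
}

#' Simulate one alignment along the species tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies and
#' evolved along each branch with transition matrices
#' `P(branch_length * scale)`; one sequence per species tip. Extra
#' transcripts per species (duplicates) are evolved from the species tip
#' sequence along short terminal stubs so that within-species distances are
#' small.
#'
#' @param tree Species tree ([ape::phylo]) with branch lengths.
#' @param scale Divergence multiplier applied to all branch lengths.
#' @param length Alignment columns.
#' @param model A [build_rate_matrix()] model.
#' @param n_copies Named integer vector: transcripts per species (default
#'   one per tip). Species with zero copies are omitted.
#' @param stub_length Branch length for duplicate transcripts.
#' @param ids Optional transcript IDs (default `<species>_g<og>` style
#'   names via `id_prefix`).
#' @param og_id Orthogroup ID recorded in the alignment.
#' @return A [protein_alignment()] with `species` set.
#' @export
simulate_alignment <- function(tree, scale = 1, length = 200L, model,
                               n_copies = NULL, stub_length = 0.01,
                               ids = NULL, og_id = "OG_sim",
                               .cache = NULL) {
  stopifnot(scale >= 0, length >= 1)
  tips <- tree$tip.label
  if (is.null(n_copies)) n_copies <- stats::setNames(rep(1L, length(tips)),
                                                     tips)
  n_nodes <- max(tree$edge)
  states <- vector("list", n_nodes)
  root <- length(tips) + 1L
  states[[root]] <- sample.int(20L, length, replace = TRUE, prob = model$pi)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    cumP <- cum_transition(model, ord$edge.length[e] * scale, .cache)
    states[[child]] <- evolve_states(states[[parent]], cumP)
  }
  aa_codes <- utf8ToInt(paste(AA_LETTERS, collapse = ""))
  seq_list <- list()
  sp_list <- character()
  for (k in seq_along(tips)) {
    sp <- tips[[k]]
    nc <- if (sp %in% names(n_copies)) n_copies[[sp]] else 0L
    if (nc < 1L) next
    base <- states[[k]]
    stub_cum <- if (nc > 1L)
      cum_transition(model, stub_length * scale, .cache)
    for (copy in seq_len(nc)) {
      s <- if (copy == 1L) base else evolve_states(base, stub_cum)
      seq_list[[length(seq_list) + 1L]] <- s
      sp_list <- c(sp_list, sp)
    }
  }
  seqs <- vapply(seq_list, function(s) intToUtf8(aa_codes[s]), character(1))
  if (is.null(ids)) {
    copy_idx <- unlist(lapply(rle(sp_list)$lengths, seq_len),
                       use.names = FALSE)
    ids <- paste0(sp_list, "_", og_id, "_t", copy_idx)
  }
  protein_alignment(ids = ids, seqs = seqs, og_id = og_id,
                    species = sp_list, validate = FALSE)
}

#' Generate an orthogroup universe with planted classes
#'
#' Per orthogroup: an annotation class is sampled by prevalence; species
#' membership by the class completeness probabilities (the reference
#' species is always present for annotated classes); member counts are
#' `1 + Poisson(duplication_rate)` per present species. The truth table
#' records the planted class, composition and divergence scale.
#'
#' @param sim A [simulation_config()].
#' @return List: `ogs` (an [orthogroup_set()]), `truth` (data frame:
#'   `og_id`, `class`, `divergence_scale`, `de_class`, one presence column
#'   per species, `n_<species>` member counts).
#' @export
generate_og_universe <- function(sim) {
  set.seed(sim$seed)
  codes <- sim$config$codes
  ref <- sim$config$reference
  all_classes <- c(sim$classes, list(sim$background))
  prev <- vapply(all_classes, `[[`, numeric(1), "prevalence")
  labels <- vapply(all_classes, `[[`, character(1), "label")
  cls_idx <- sample.int(length(all_classes), sim$n_ogs, replace = TRUE,
                        prob = prev)
  og_ids <- sprintf("OG%07d", seq_len(sim$n_ogs))

  present <- matrix(FALSE, sim$n_ogs, length(codes),
                    dimnames = list(og_ids, codes))
  for (ci in seq_along(all_classes)) {
    rows <- which(cls_idx == ci)
    if (!length(rows)) next
    comp <- all_classes[[ci]]$completeness
    for (s in codes) {
      if (s == ref && !is.na(labels[[ci]])) {
        present[rows, s] <- TRUE
      } else {
        present[rows, s] <- stats::runif(length(rows)) < comp
      }
    }
  }
  # an orthogroup needs at least one member; force the reference in
  # all-absent rows (rare)
  none <- rowSums(present) == 0L
  present[none, ref] <- TRUE

  counts <- matrix(0L, sim$n_ogs, length(codes),
                   dimnames = list(og_ids, codes))
  counts[present] <- 1L + stats::rpois(sum(present), sim$duplication_rate)

  long_n <- sum(counts)
  og_col <- rep(rep(og_ids, times = length(codes)), times = as.vector(counts))
  sp_col <- rep(rep(codes, each = sim$n_ogs), times = as.vector(counts))
  copy <- sequence(as.vector(counts))
  transcript <- paste0(sp_col, "_", og_col, "_t", copy)
  ogs <- orthogroup_set(og_id = og_col, species = sp_col,
                        transcript = transcript, config = sim$config,
                        og_ids = og_ids)
  de_class <- character(sim$n_ogs)
  for (ci in seq_along(all_classes)) {
    rows <- which(cls_idx == ci)
    if (!length(rows)) next
    pr <- all_classes[[ci]]$de_probs
    de_class[rows] <- sample(names(pr), length(rows), replace = TRUE,
                             prob = pr)
  }
  truth <- data.frame(og_id = og_ids, class = labels[cls_idx],
                      divergence_scale = vapply(all_classes, `[[`,
                                                numeric(1),
                                                "divergence_scale")[cls_idx],
                      de_class = de_class,
                      stringsAsFactors = FALSE)
  for (s in codes) truth[[paste0("present_", s)]] <- present[, s]
  for (s in codes) truth[[paste0("n_", s)]] <- counts[, s]
  list(ogs = ogs, truth = truth)
}

#' Simulate alignments for a generated universe
#'
#' One alignment per orthogroup that contains at least two transcripts,
#' evolved at the orthogroup's planted divergence scale with the species
#' subtree pruned to its present species.
#'
#' @param universe Output of [generate_og_universe()].
#' @param sim The [simulation_config()] used to generate it.
#' @param model A [build_rate_matrix()] model.
#' @param og_ids Optional subset of OG IDs to simulate (default: all with
#'   two or more transcripts and two or more species).
#' @return Named list of [protein_alignment()]s.
#' @export
simulate_og_alignments <- function(universe, sim, model, og_ids = NULL) {
  set.seed(sim$seed + 1L)
  truth <- universe$truth
  codes <- sim$config$codes
  n_cols <- paste0("n_", codes)
  counts <- as.matrix(truth[, n_cols])
  colnames(counts) <- codes
  if (is.null(og_ids)) {
    og_ids <- truth$og_id[rowSums(counts) >= 2L &
                          rowSums(counts > 0L) >= 2L]
  }
  idx <- match(og_ids, truth$og_id)
  alns <- vector("list", length(og_ids))
  names(alns) <- og_ids
  cache <- new.env(parent = emptyenv())
  tree_cache <- new.env(parent = emptyenv())
  for (k in seq_along(og_ids)) {
    i <- idx[[k]]
    nc <- counts[i, ]
    tips_in <- codes[nc > 0L]
    tkey <- paste(tips_in, collapse = "|")
    tr <- tree_cache[[tkey]]
    if (is.null(tr)) {
      tr <- if (length(tips_in) < length(codes)) {
        ape::keep.tip(sim$tree, tips_in)
      } else sim$tree
      tree_cache[[tkey]] <- tr
    }
    alns[[k]] <- simulate_alignment(tr, scale = truth$divergence_scale[i],
                                    length = sim$alignment_length,
                                    model = model,
                                    n_copies = nc[nc > 0L],
                                    stub_length = sim$stub_length,
                                    og_id = og_ids[[k]],
                                    .cache = cache)
  }
  alns
}

#' Generate per-species DE result tables with planted signals
#'
#' For orthogroups planted as `consistent_up_first`, every required (non-
#' reference) species present in the orthogroup receives at least one
#' transcript with adjusted p below `alpha / 2` and a positive log2 fold
#' change (symmetric for `consistent_up_second`); `inconsistent`
#' orthogroups receive significant transcripts of mixed sign across
#' species; all other transcripts get adjusted p above `alpha` (or `NA`,
#' emulating expression filtering). Mean expression is log-normal.
#'
#' @param universe Output of [generate_og_universe()].
#' @param sim The [simulation_config()].
#' @return Named list of [de_table()]s, one per non-reference species.
#' @export
generate_de_tables <- function(universe, sim) {
  set.seed(sim$seed + 2L)
  codes <- setdiff(sim$config$codes, sim$config$reference)
  truth <- universe$truth
  tab <- universe$ogs$tab
  alpha <- sim$alpha
  out <- list()
  for (s in codes) {
    sub <- tab[tab$species == s, , drop = FALSE]
    n <- nrow(sub)
    de_class <- truth$de_class[match(sub$og_id, truth$og_id)]
    padj <- stats::runif(n, alpha, 1)
    filtered <- stats::runif(n) < 0.1
    padj[filtered] <- NA_real_
    lfc <- stats::rnorm(n, 0, 1)
    # plant one significant transcript per (OG, species); the first listed
    first <- !duplicated(sub$og_id)
    plant <- function(class, sign_fun) {
      rows <- which(first & de_class == class)
      padj[rows] <<- stats::runif(length(rows), 0, alpha / 2)
      lfc[rows] <<- sign_fun(length(rows))
    }
    plant("consistent_up_first", function(k) abs(stats::rnorm(k, 2, 0.5)))
    plant("consistent_up_second", function(k) -abs(stats::rnorm(k, 2, 0.5)))
    # inconsistent: the sign flips across species (first species up, the
    # others down), guaranteeing a conflict within the orthogroup
    plant("inconsistent", if (s == codes[[1L]])
      function(k) abs(stats::rnorm(k, 2, 0.5)) else
      function(k) -abs(stats::rnorm(k, 2, 0.5)))
    out[[s]] <- de_table(
      data.frame(transcript = sub$transcript,
                 baseMean = stats::rlnorm(n, meanlog = 4, sdlog = 1.5),
                 log2FoldChange = lfc, padj = padj,
                 stringsAsFactors = FALSE),
      species = s, contrast = sim$contrast)
  }
  out
}

#' Generate reference-species annotation and signal-peptide flags
#'
#' Reference transcripts of each planted class receive the class label;
#' signal-peptide flags are Bernoulli with the class probability. An
#' optional conflict-injection rate relabels a fraction of annotated
#' orthogroups with a second label from the same family, exercising the
#' mix-resolution rules.
#'
#' @param universe Output of [generate_og_universe()].
#' @param sim The [simulation_config()].
#' @param conflict_rate Probability that an annotated orthogroup gains a
#'   conflicting second label (default 0).
#' @return An [annotation_table()] for the reference species.
#' @export
generate_annotation_flags <- function(universe, sim, conflict_rate = 0) {
  set.seed(sim$seed + 3L)
  ref <- sim$config$reference
  truth <- universe$truth
  tab <- universe$ogs$tab
  sub <- tab[tab$species == ref, , drop = FALSE]
  cls <- truth$class[match(sub$og_id, truth$og_id)]
  all_classes <- c(sim$classes, list(sim$background))
  labels <- vapply(all_classes, `[[`, character(1), "label")
  sp_prob <- vapply(all_classes, `[[`, numeric(1), "signalp_prob")
  prob <- sp_prob[match(cls, labels)]
  prob[is.na(prob)] <- sim$background$signalp_prob
  transcripts <- character()
  out_labels <- character()
  has_label <- !is.na(cls)
  transcripts <- c(transcripts, sub$transcript[has_label])
  out_labels <- c(out_labels, cls[has_label])
  if (conflict_rate > 0) {
    conflict_of <- c(testis_region = "tail_region",
                     ovary_region = "testis_region",
                     tail_region = "ovary_region",
                     neoblast_FACS = "germline_FACS",
                     neoblast_strict = "germline_FACS",
                     OvI = "OvP")
    first_ref <- !duplicated(sub$og_id)
    rows <- which(has_label & first_ref & cls %in% names(conflict_of) &
                  stats::runif(nrow(sub)) < conflict_rate)
    transcripts <- c(transcripts, sub$transcript[rows])
    out_labels <- c(out_labels, unname(conflict_of[cls[rows]]))
  }
  flagged <- stats::runif(nrow(sub)) < prob
  transcripts <- c(transcripts, sub$transcript[flagged])
  out_labels <- c(out_labels, rep("signalp", sum(flagged)))
  annotation_table(transcripts, out_labels)
}

#' Write a full synthetic data set to disk
#'
#' Emits the formats the readers consume: an orthogroup membership TSV,
#' one FASTA alignment per orthogroup, per-species DE TSVs, an annotation
#' TSV and the truth table.
#'
#' @param sim A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param model A [build_rate_matrix()] model.
#' @param conflict_rate Passed to [generate_annotation_flags()].
#' @return Invisibly, a list of the generated in-memory objects.
#' @export
simulate_og_data <- function(sim, dir, model = build_rate_matrix("JTT"),
                             conflict_rate = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln_dir <- file.path(dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  universe <- generate_og_universe(sim)
  alns <- simulate_og_alignments(universe, sim, model)
  de <- generate_de_tables(universe, sim)
  ann <- generate_annotation_flags(universe, sim,
                                   conflict_rate = conflict_rate)
  write_orthogroups(universe$ogs, file.path(dir, "orthogroups.tsv"))
  for (a in alns) {
    write_fasta_alignment(a, file.path(aln_dir, paste0(a$og_id, ".fasta")))
  }
  for (s in names(de)) {
    write_de_table(de[[s]], file.path(dir, paste0("de_", s, "_",
                                                  sim$contrast, ".tsv")))
  }
  write_annotation_table(ann, file.path(dir, "annotations.tsv"))
  utils::write.table(universe$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(universe = universe, alignments = alns, de = de,
                 annotations = ann))
}
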