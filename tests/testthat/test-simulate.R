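test_that("zero divergence scale yields identical sequences", {
  m <- jtt()
  set.seed(1)
  aln <- simulate_alignment(default_species_tree(), scale = 0, length = 50,
                            model = m)
  expect_equal(length(unique(aln$seqs)), 1L)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  sim <- simulation_config(n_ogs = 100, seed = 33)
  m <- jtt()
  u1 <- generate_og_universe(sim)
  u2 <- generate_og_universe(sim)
  expect_identical(u1$truth, u2$truth)
  expect_identical(u1$ogs$tab, u2$ogs$tab)
  a1 <- simulate_og_alignments(u1, sim, m)
  a2 <- simulate_og_alignments(u2, sim, m)
  expect_identical(lapply(a1, `[[`, "seqs"), lapply(a2, `[[`, "seqs"))
  expect_identical(generate_de_tables(u1, sim), generate_de_tables(u2, sim))
  expect_identical(generate_annotation_flags(u1, sim),
                   generate_annotation_flags(u2, sim))
})

test_that("a two-leaf simulation recovers the path length", {
  m <- jtt()
  set.seed(17)
  est <- vapply(1:15, function(i) {
    aln <- simulate_pair(0.8, 3000)
    pairwise_ml_distance(aln$seqs[1], aln$seqs[2], m)$t_hat
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 3 * se + 1e-3)
})

test_that("class completeness probabilities shape species presence", {
  sim <- simulation_config(
    n_ogs = 4000, seed = 5,
    classes = list(sim_class("testis_region", prevalence = 0.5,
                             completeness = 0.5)),
    background = sim_class(NA_character_, prevalence = NA_real_,
                           completeness = 1))
  u <- generate_og_universe(sim)
  planted <- u$truth$class %in% "testis_region"
  frac <- mean(u$truth$present_Mpus[planted])
  n <- sum(planted)
  # binomial 99% interval around 0.5
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / n))
  # reference always present in annotated classes
  expect_true(all(u$truth$present_Mlig[planted]))
  # background completeness 1: everything complete
  expect_true(all(u$truth$present_Mpus[!planted]))
})

test_that("duplication adds near-copy transcripts within species", {
  sim <- simulation_config(n_ogs = 60, seed = 9, duplication_rate = 1)
  m <- jtt()
  u <- generate_og_universe(sim)
  alns <- simulate_og_alignments(u, sim, m)
  multi <- Filter(function(a) any(table(a$species) > 1), alns)
  expect_gt(length(multi), 0)
  a <- multi[[1]]
  sp <- names(which(table(a$species) > 1))[1]
  rows <- which(a$species == sp)[1:2]
  d_within <- pairwise_ml_distance(a$seqs[rows[1]], a$seqs[rows[2]], m)
  expect_lt(d_within$t_hat, 0.15)
})

test_that("planted DE signals straddle alpha as designed", {
  sim <- simulation_config(n_ogs = 300, seed = 13)
  u <- generate_og_universe(sim)
  de <- generate_de_tables(u, sim)
  for (tab in de) {
    truth_class <- u$truth$de_class[match(tab$transcript,
                                          paste0(attr(tab, "species"), "_",
                                                 u$truth$og_id, "_t1"))]
    planted <- !is.na(truth_class) & truth_class != "none"
    expect_true(all(is.na(tab$padj[!planted]) |
                    tab$padj[!planted] >= sim$alpha))
    expect_true(all(tab$padj[planted] < sim$alpha / 2))
  }
})

test_that("zero planted DE yields zero eligible orthogroups", {
  sim <- simulation_config(
    n_ogs = 200, seed = 3,
    classes = list(sim_class("testis_region", prevalence = 0.1,
                             de_probs = c(consistent_up_first = 0,
                                          consistent_up_second = 0,
                                          inconsistent = 0, none = 1))))
  u <- generate_og_universe(sim)
  de <- generate_de_tables(u, sim)
  out <- classify_consistent_ogs(u$ogs, lapply(de, call_de))
  expect_true(all(out$classification == "not_eligible"))
})

test_that("conflict injection controls mix orthogroups", {
  sim <- simulation_config(n_ogs = 400, seed = 19)
  u <- generate_og_universe(sim)
  ann0 <- generate_annotation_flags(u, sim, conflict_rate = 0)
  res0 <- resolve_mixes(transfer_annotations(u$ogs, ann0))
  mixes0 <- sum(vapply(res0$resolved, function(x)
    any(grepl("_mix$", x)), logical(1)))
  expect_equal(mixes0, 0L)
  ann1 <- generate_annotation_flags(u, sim, conflict_rate = 1)
  res1 <- resolve_mixes(transfer_annotations(u$ogs, ann1))
  mixes1 <- sum(vapply(res1$resolved, function(x)
    any(grepl("_mix$", x)), logical(1)))
  expect_gt(mixes1, 0L)
})

test_that("elevated signal-peptide probability is detected by the GOF test", {
  sim <- simulation_config(
    n_ogs = 4000, seed = 23,
    classes = list(sim_class("testis_region", prevalence = 0.1,
                             completeness = 1, signalp_prob = 0.3)),
    background = sim_class(NA_character_, prevalence = NA_real_,
                           completeness = 1, signalp_prob = 0.1))
  u <- generate_og_universe(sim)
  ann <- generate_annotation_flags(u, sim)
  anns <- retain_downstream(resolve_mixes(transfer_annotations(u$ogs, ann)))
  planted <- vapply(anns$resolved, function(x) "testis_region" %in% x,
                    logical(1))
  obs <- c(sum(anns$signalp[planted]), sum(anns$signalp[!planted]))
  sizes <- c(sum(planted), sum(!planted))
  res <- signalp_gof_test(obs, sizes)
  expect_lt(res$p, 0.01)
})

test_that("written synthetic data round-trips through the readers", {
  dir <- file.path(tempdir(), "simdata")
  sim <- simulation_config(n_ogs = 40, seed = 77)
  out <- simulate_og_data(sim, dir)
  ogs <- read_orthogroups(file.path(dir, "orthogroups.tsv"))
  expect_equal(ogs$og_ids, out$universe$ogs$og_ids)
  expect_equal(sort(ogs$tab$transcript),
               sort(out$universe$ogs$tab$transcript))
  files <- list.files(file.path(dir, "alignments"), full.names = TRUE)
  expect_equal(length(files), length(out$alignments))
  aln <- read_fasta_alignment(files[1])
  expect_identical(aln$seqs, out$alignments[[aln$og_id]]$seqs)
  de_files <- list.files(dir, pattern = "^de_", full.names = TRUE)
  expect_equal(length(de_files), 3L)
  tab <- read_de_table(de_files[1], "Mhys", sim$contrast)
  expect_equal(nrow(tab), nrow(out$de$Mhys))
  ann <- read_annotation_table(file.path(dir, "annotations.tsv"))
  expect_equal(as.data.frame(ann)[order(ann$transcript, ann$label), ],
               as.data.frame(out$annotations)[
                 order(out$annotations$transcript,
                       out$annotations$label), ],
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
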