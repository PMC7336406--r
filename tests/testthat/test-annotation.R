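make_anns <- function(labels_by_og) {
  # labels_by_og: named list og_id -> character vector of transcript labels
  ogs <- orthogroup_set(
    og_id = rep(names(labels_by_og), each = 2),
    species = rep(c("Mlig", "Mhys"), length(labels_by_og)),
    transcript = paste0(rep(names(labels_by_og), each = 2), "_",
                        rep(c("Mlig", "Mhys"), length(labels_by_og))))
  pairs <- do.call(rbind, lapply(names(labels_by_og), function(og) {
    labs <- labels_by_og[[og]]
    if (!length(labs)) return(NULL)
    data.frame(transcript = paste0(og, "_Mlig"), label = labs)
  }))
  anns <- if (is.null(pairs)) {
    transfer_annotations(ogs, annotation_table(character(), character()))
  } else {
    transfer_annotations(ogs, annotation_table(pairs$transcript, pairs$label))
  }
  list(ogs = ogs, anns = anns)
}

test_that("annotations transfer as the union over reference members", {
  ogs <- orthogroup_set(
    og_id = c("OG1", "OG1", "OG1", "OG2"),
    species = c("Mlig", "Mlig", "Mhys", "Mhys"),
    transcript = c("L1", "L2", "H1", "H2"))
  ann <- annotation_table(c("L1", "L1", "L2"),
                          c("testis_region", "signalp", "OvI"))
  out <- transfer_annotations(ogs, ann)
  expect_equal(out$og_id, "OG1")         # OG2 has no reference member
  expect_setequal(out$raw[[1L]], c("OvI", "signalp", "testis_region"))
  expect_true(out$signalp[1L])
})

test_that("orphan annotation labels warn and leave records unchanged", {
  ogs <- orthogroup_set(og_id = c("OG1", "OG1"),
                        species = c("Mlig", "Mhys"),
                        transcript = c("L1", "H1"))
  ann <- annotation_table(c("L1", "ghost"), c("OvI", "testis_region"))
  expect_warning(out <- transfer_annotations(ogs, ann), "1 annotated")
  expect_equal(out$raw[[1L]], "OvI")
  expect_equal(attr(out, "orphans"), "ghost")
})

test_that("mix resolution follows the per-family conflict rules", {
  cases <- list(
    list(raw = c("tail_region", "testis_region"),
         resolved = "positional_mix"),
    list(raw = c("testis_region", "ovary_region", "tail_region"),
         resolved = "positional_mix"),
    list(raw = "ovary_region", resolved = "ovary_region"),
    list(raw = c("germline_FACS", "neoblast_FACS"),
         resolved = "neoblast_mix"),
    list(raw = c("germline_FACS", "neoblast_strict", "neoblast_FACS"),
         resolved = "neoblast_mix"),
    list(raw = "germline_FACS", resolved = "germline_FACS"),
    list(raw = c("neoblast_FACS", "neoblast_strict"),
         resolved = c("neoblast_FACS", "neoblast_strict")),
    list(raw = c("OvI", "OvP"), resolved = "social_mix"),
    list(raw = c("OvI", "OvP", "BOTH"), resolved = c("BOTH", "OvI", "OvP")),
    list(raw = "OvI", resolved = "OvI"),
    # families resolve independently: an OG can carry two mixes
    list(raw = c("testis_region", "tail_region", "germline_FACS",
                 "neoblast_FACS", "OvI"),
         resolved = c("neoblast_mix", "OvI", "positional_mix")))
  fix <- make_anns(stats::setNames(lapply(cases, `[[`, "raw"),
                                   sprintf("OG%02d", seq_along(cases))))
  res <- resolve_mixes(fix$anns)
  for (k in seq_along(cases)) {
    expect_equal(res$resolved[[k]], sort(cases[[k]]$resolved),
                 label = paste("case", k))
  }
  # idempotence
  res2 <- resolve_mixes(res)
  expect_equal(res2$resolved, res$resolved)
})

test_that("signalp carries through resolution unchanged", {
  fix <- make_anns(list(OG1 = c("testis_region", "signalp"),
                        OG2 = "signalp"))
  res <- resolve_mixes(fix$anns)
  expect_equal(res$signalp, c(TRUE, TRUE))
  expect_equal(res$resolved[[1L]], "testis_region")
  expect_equal(res$resolved[[2L]], character())
})

test_that("retention keeps the seven downstream labels only", {
  fix <- make_anns(list(
    OG1 = c("tail_region", "testis_region"),   # positional_mix -> dropped
    OG2 = "OvP",                               # dropped, small sample
    OG3 = c("testis_region", "OvI"),           # both kept
    OG4 = "germline_FACS",                     # dropped at retention
    OG5 = c("OvI", "OvP", "BOTH")))            # BOTH and OvI kept, OvP not
  out <- retain_downstream(resolve_mixes(fix$anns))
  expect_equal(out$retained[[1L]], character())
  expect_equal(out$retained[[2L]], character())
  expect_setequal(out$retained[[3L]], c("testis_region", "OvI"))
  expect_equal(out$retained[[4L]], character())
  expect_setequal(out$retained[[5L]], c("BOTH", "OvI"))
  expect_error(retain_downstream(fix$anns), "resolve_mixes")
})

test_that("every OG gets at most one positional outcome", {
  set.seed(42)
  pos <- c("testis_region", "ovary_region", "tail_region")
  labels <- lapply(1:50, function(i) sample(pos, sample(0:3, 1)))
  fix <- make_anns(stats::setNames(labels, sprintf("OG%03d", 1:50)))
  res <- resolve_mixes(fix$anns)
  for (r in res$resolved) {
    n_pos <- sum(r %in% c(pos, "positional_mix"))
    expect_lte(n_pos, 1L)
  }
})

test_that("intersection counts match exhaustive enumeration", {
  simple <- make_anns(list(OG1 = "OvI", OG2 = "OvI",
                           OG3 = c("OvI", "testis_region")))
  res <- resolve_mixes(simple$anns)
  tab <- annotation_intersections(res)
  expect_equal(tab$combinations$count[tab$combinations$labels == "OvI"], 2L)
  expect_equal(tab$combinations$count[
    tab$combinations$labels == "OvI+testis_region"], 1L)
  expect_equal(tab$totals[["OvI"]], 3L)
  expect_equal(tab$totals[["testis_region"]], 1L)

  # random labels vs brute-force oracle
  set.seed(7)
  vocab <- c("testis_region", "ovary_region", "OvI", "BOTH",
             "neoblast_FACS")
  labels <- lapply(1:40, function(i)
    sample(vocab, rbinom(1, 3, 0.5), replace = FALSE))
  fix <- make_anns(stats::setNames(labels, sprintf("OG%03d", 1:40)))
  res <- resolve_mixes(fix$anns)
  got <- annotation_intersections(res)
  # oracle: count by comparing every pair of label sets directly
  sets <- Filter(length, res$resolved)
  for (r in seq_len(nrow(got$combinations))) {
    combo <- strsplit(got$combinations$labels[r], "+", fixed = TRUE)[[1L]]
    n <- sum(vapply(sets, function(s) setequal(s, combo), logical(1)))
    expect_equal(got$combinations$count[r], n)
  }
  expect_equal(sum(got$combinations$count), length(sets))
  for (lab in names(got$totals)) {
    expect_equal(got$totals[[lab]],
                 sum(vapply(sets, function(s) lab %in% s, logical(1))))
  }
  # threshold suppression
  expect_true(all(annotation_intersections(res, min_count = 2)$
                  combinations$count > 2))
})

test_that("empty annotation collections yield empty intersection tables", {
  fix <- make_anns(list(OG1 = character(), OG2 = character()))
  res <- resolve_mixes(fix$anns)
  tab <- annotation_intersections(res)
  expect_equal(nrow(tab$combinations), 0L)
  expect_length(tab$totals, 0L)
})
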