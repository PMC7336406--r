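test_that("composition predicates evaluate presence patterns", {
  ogs <- make_test_ogs()
  comp <- species_composition(ogs)
  cfg <- four_species()
  complete <- composition_predicate("complete", config = cfg)
  expect_equal(unname(predicate_hits(complete, comp)),
               c(TRUE, FALSE, FALSE, FALSE))
  lig_spi <- composition_predicate("pair_only",
                                   species = c("Mlig", "Mspi"),
                                   config = cfg)
  expect_equal(unname(predicate_hits(lig_spi, comp)),
               c(FALSE, TRUE, FALSE, FALSE))
  custom <- composition_predicate("custom", species = c("Mlig", "Mpus"),
                                  config = cfg)
  expect_equal(unname(predicate_hits(custom, comp)),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_error(composition_predicate("custom", species = "Zzz",
                                     config = cfg), "unknown species")
})

make_universe <- function(n, k, seed = 1) {
  # n OGs, k of which satisfy the predicate
  set.seed(seed)
  hits <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  names(hits) <- sprintf("OG%05d", seq_len(n))
  hits
}

test_that("sampling the whole universe collapses the draw distribution", {
  hits <- make_universe(50, 20)
  res <- resample_composition_test(hits, names(hits), n_iter = 1000,
                                   seed = 1)
  expect_equal(res$observed, 20)
  expect_equal(res$expected, 20)
  expect_equal(res$p, 1)
})

test_that("identical seeds give bit-identical results", {
  hits <- make_universe(200, 80)
  ann <- sample(names(hits), 30)
  r1 <- resample_composition_test(hits, ann, n_iter = 2000, seed = 99)
  r2 <- resample_composition_test(hits, ann, n_iter = 2000, seed = 99)
  expect_identical(r1, r2)
})

test_that("the resampling test matches the exact hypergeometric oracle", {
  # universe of 100 OGs, 40 satisfying the predicate, 10 annotated none of
  # which satisfy it
  hits <- make_universe(100, 40, seed = 5)
  ann <- names(hits)[!hits][1:10]
  res <- resample_composition_test(hits, ann, n_iter = 100000, seed = 12)
  expect_equal(res$observed, 0)
  # hypergeometric mean 10 * 40 / 100 = 4
  expect_lt(abs(res$expected - 4), 3 * sqrt(10 * 0.4 * 0.6 * 0.9 / 1e5) + 0.05)
  # exact doubled lower tail
  p_exact <- min(1, 2 * phyper(0, 40, 60, 10))
  expect_lt(abs(res$p - p_exact), 0.003)
  # ci95 bounds are attainable counts
  expect_gte(res$ci95[1], 0)
  expect_lte(res$ci95[2], 10)
})

test_that("input contracts are enforced", {
  hits <- make_universe(50, 10)
  expect_error(resample_composition_test(hits, character(), seed = 1),
               "empty")
  expect_error(resample_composition_test(hits, c(names(hits)[1],
                                                 names(hits)[1]),
                                         seed = 1), "duplicates")
  expect_error(resample_composition_test(hits, "NOPE", seed = 1),
               "outside the universe")
  expect_error(resample_composition_test(hits, names(hits)[1:5],
                                         n_iter = 10), "1000")
})

test_that("an orthogroup_set universe restricts to reference-containing OGs", {
  ogs <- make_test_ogs()   # OG3 lacks Mlig
  res <- resample_composition_test(ogs, c("OG1", "OG2"),
                                   composition_predicate("complete"),
                                   n_iter = 1000, seed = 2)
  expect_equal(res$n_annotated, 2L)
  expect_equal(res$observed, 1L)
  expect_error(
    resample_composition_test(ogs, "OG3", n_iter = 1000, seed = 2),
    "outside the universe")
})

test_that("the goodness-of-fit statistic follows proportional allocation", {
  res0 <- signalp_gof_test(observed = c(10, 20, 30), sizes = c(10, 20, 30))
  expect_equal(res0$chi2, 0)
  res <- signalp_gof_test(observed = c(8, 2), sizes = c(50, 50))
  expect_equal(res$expected, c(5, 5))
  expect_equal(res$chi2, 3.6)
  expect_equal(res$df, 1L)
  expect_equal(sum(res$residuals), 0)
  # cross-check against the base chi-square routine
  ref <- suppressWarnings(chisq.test(x = c(8, 2), p = c(0.5, 0.5)))
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("the statistic is invariant under category permutation", {
  obs <- c(130, 37, 53, 16, 1764)
  sizes <- c(728, 181, 173, 84, 10165)
  r1 <- signalp_gof_test(obs, sizes)
  i <- c(3, 5, 1, 2, 4)
  r2 <- signalp_gof_test(obs[i], sizes[i])
  expect_equal(r1$chi2, r2$chi2)
  expect_equal(r1$p, r2$p)
})

test_that("goodness-of-fit input contracts are enforced", {
  expect_error(signalp_gof_test(5, 10), "length >= 2")
  expect_error(signalp_gof_test(c(5, -1), c(10, 10)), "non-negative")
  expect_error(signalp_gof_test(c(5, 11), c(10, 10)), "exceed")
  expect_error(signalp_gof_test(c(5, 0), c(10, 0)), "zero")
})
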