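test_that("identical and symmetric inputs give exact distances", {
  m <- jtt()
  d0 <- pairwise_ml_distance("ARNDCQEGHI", "ARNDCQEGHI", m)
  expect_equal(d0$t_hat, 0)
  expect_equal(d0$n_sites, 10)
  expect_false(d0$saturated)
  # symmetry under reversibility
  a <- "ARNDCQEGHILKMFPSTWYV"
  b <- "ARNDCQEGHILKMFPSTWYW"
  expect_equal(pairwise_ml_distance(a, b, m)$t_hat,
               pairwise_ml_distance(b, a, m)$t_hat, tolerance = 1e-8)
  # gaps and X are dropped pairwise
  d <- pairwise_ml_distance("AR-DX", "ARNDC", m)
  expect_equal(d$n_sites, 3)
  expect_error(pairwise_ml_distance("---", "ARN", m), "comparable")
})

test_that("a long simulated pair at t = 0.5 is recovered and matches the grid oracle", {
  skip_if_not_installed("Matrix")
  set.seed(421)
  aln <- simulate_pair(0.5, 10000)
  d <- pairwise_ml_distance(aln$seqs[1], aln$seqs[2], jtt())
  expect_gt(d$t_hat, 0.47)
  expect_lt(d$t_hat, 0.53)
  oracle <- grid_search_distance(aln$seqs[1], aln$seqs[2])
  expect_lt(abs(d$t_hat - oracle), 1e-3)
})

test_that("estimates are consistent across replicates (parameter recovery)", {
  m <- jtt()
  for (t_true in c(0.1, 0.5, 1.0, 2.0)) {
    set.seed(round(1000 * t_true))
    est <- vapply(1:20, function(i) {
      aln <- simulate_pair(t_true, 2000)
      pairwise_ml_distance(aln$seqs[1], aln$seqs[2], m)$t_hat
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - t_true), 3 * se + 1e-3)
  }
})

test_that("distance of a concatenation lies between the parts' estimates", {
  m <- jtt()
  set.seed(99)
  a1 <- simulate_pair(0.6, 1500)
  a2 <- simulate_pair(0.6, 1500)
  t1 <- pairwise_ml_distance(a1$seqs[1], a1$seqs[2], m)$t_hat
  t2 <- pairwise_ml_distance(a2$seqs[1], a2$seqs[2], m)$t_hat
  tc <- pairwise_ml_distance(paste0(a1$seqs[1], a2$seqs[1]),
                             paste0(a1$seqs[2], a2$seqs[2]), m)$t_hat
  expect_gte(tc, min(t1, t2) - 1e-6)
  expect_lte(tc, max(t1, t2) + 1e-6)
})

test_that("saturated pairs hit the optimisation bound and are flagged", {
  m <- jtt()
  set.seed(5)
  # unrelated sequences drawn independently from the equilibrium
  s1 <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I"), 300,
                     TRUE), collapse = "")
  s2 <- paste(sample(c("L","K","M","F","P","S","T","W","Y","V"), 300,
                     TRUE), collapse = "")
  d <- pairwise_ml_distance(s1, s2, m, t_max = 10)
  expect_true(d$saturated)
  expect_gte(d$t_hat, 10 - 1e-3)
})

overlap_filter_oracle <- function(aln, min_overlap = 1) {
  # independent re-statement of the greedy rule with explicit loops
  comparable <- function(i, j) {
    ci <- strsplit(aln$seqs[i], "")[[1]]
    cj <- strsplit(aln$seqs[j], "")[[1]]
    ok <- function(x) !x %in% c("-", "X")
    sum(ok(ci) & ok(cj))
  }
  keep <- seq_along(aln$ids)
  repeat {
    if (length(keep) < 2) break
    bad <- sapply(keep, function(i)
      sum(sapply(keep, function(j)
        j != i && comparable(i, j) < min_overlap)))
    if (all(bad == 0)) break
    nres <- sapply(keep, function(i) {
      ch <- strsplit(aln$seqs[i], "")[[1]]
      sum(!ch %in% c("-", "X"))
    })
    ids <- aln$ids[keep]
    pick <- order(-bad, nres, ids)[1]
    keep <- keep[-pick]
  }
  sort(aln$ids[keep])
}

test_that("the overlap filter drops non-overlapping rows greedily", {
  pad <- function(left, mid, right) {
    paste0(strrep("-", left), strrep("A", mid), strrep("-", right))
  }
  aln <- protein_alignment(
    ids = c("A", "B", "C"),
    seqs = c(pad(0, 50, 50), pad(0, 50, 50), pad(59, 41, 0)))
  out <- overlap_filter(aln)
  expect_true(out$usable)
  expect_equal(out$dropped, "C")
  expect_equal(out$alignment$ids, c("A", "B"))

  # fully overlapping rows are untouched
  aln2 <- protein_alignment(c("x", "y"), c("AAAA", "AAAA"))
  out2 <- overlap_filter(aln2)
  expect_equal(out2$dropped, character())
  expect_equal(out2$alignment$ids, c("x", "y"))

  # a pair with zero overlap anywhere leaves fewer than two rows
  aln3 <- protein_alignment(c("x", "y"),
                            c("AA--", "--AA"))
  expect_false(overlap_filter(aln3)$usable)
})

test_that("the overlap filter matches the explicit-loop oracle on random masks", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    len <- 30
    seqs <- vapply(1:n, function(i) {
      mask <- runif(len) < runif(1, 0.2, 0.9)
      paste(ifelse(mask, "A", "-"), collapse = "")
    }, character(1))
    aln <- protein_alignment(paste0("s", 1:n), seqs)
    got <- overlap_filter(aln, min_overlap = 3)
    expected <- overlap_filter_oracle(aln, min_overlap = 3)
    if (length(expected) < 2) {
      expect_false(got$usable)
    } else {
      expect_equal(sort(got$alignment$ids), expected)
    }
  }
})

test_that("orthogroup divergence averages species-pair means of between-species distances", {
  m <- jtt()
  cfg <- species_config()
  set.seed(77)
  tr <- default_species_tree()
  aln <- simulate_alignment(tr, scale = 1, length = 400, model = m,
                            n_copies = c(Mlig = 2, Mhys = 1, Mspi = 1,
                                         Mpus = 1),
                            og_id = "OGe")
  div <- og_mean_divergence(aln, NULL, m, cfg)
  expect_true(div$ok)
  # enumeration oracle from the raw pairwise table
  d <- all_pairwise_distances(aln, m)
  sp <- aln$species
  key <- function(i, j) paste(sort(c(sp[match(i, aln$ids)],
                                     sp[match(j, aln$ids)])), collapse = "|")
  keys <- mapply(key, d$id_a, d$id_b)
  between <- vapply(seq_len(nrow(d)), function(r)
    sp[match(d$id_a[r], aln$ids)] != sp[match(d$id_b[r], aln$ids)],
    logical(1))
  oracle_means <- tapply(d$t_hat[between], keys[between], mean)
  expect_equal(sort(names(div$pair_means)), sort(names(oracle_means)))
  expect_equal(div$pair_means[names(oracle_means)],
               stats::setNames(as.numeric(oracle_means),
                               names(oracle_means)))
  expect_equal(div$divergence, mean(div$pair_means))
  # Mlig|Mhys mean covers the two Mlig copies
  expect_equal(sum(between & grepl("Mlig", keys) & grepl("Mhys", keys)), 2L)

  # invariance to row order
  i <- rev(seq_along(aln$ids))
  aln_rev <- protein_alignment(aln$ids[i], aln$seqs[i], og_id = aln$og_id,
                               species = aln$species[i])
  div_rev <- og_mean_divergence(aln_rev, NULL, m, cfg)
  expect_equal(div_rev$divergence, div$divergence, tolerance = 1e-9)
})

test_that("identical sequences across species give zero divergence", {
  cfg <- species_config()
  aln <- protein_alignment(
    ids = paste0(cfg$codes, "_t"),
    seqs = rep("ARNDCQEGHI", 4),
    species = cfg$codes)
  div <- og_mean_divergence(aln, NULL, jtt(), cfg)
  expect_equal(div$divergence, 0)
})

test_that("orthogroups missing a species are excluded with a reason", {
  cfg <- species_config()
  aln <- protein_alignment(
    ids = c("Mlig_t", "Mhys_t", "Mspi_t"),
    seqs = rep("ARNDCQEGHI", 3),
    species = c("Mlig", "Mhys", "Mspi"))
  div <- og_mean_divergence(aln, NULL, jtt(), cfg)
  expect_false(div$ok)
  expect_equal(div$reason, "missing_species")
})

test_that("the saturation cutoff is strict and counts exclusions", {
  divs <- data.frame(og_id = c("a", "b", "c", "d"),
                     divergence = c(2.5, 2.0, 0.3, NA),
                     ok = c(TRUE, TRUE, TRUE, FALSE))
  out <- exclude_saturated(divs, cutoff = 2.0)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "n_excluded"), 1L)
})
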