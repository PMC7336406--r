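# Shared fixtures: small, programmatically built inputs.

four_species <- function() species_config()

# A four-OG set exercising complete / partial compositions.
make_test_ogs <- function() {
  orthogroup_set(
    og_id = c("OG1", "OG1", "OG1", "OG1",
              "OG2", "OG2",
              "OG3",
              "OG4", "OG4", "OG4"),
    species = c("Mlig", "Mhys", "Mspi", "Mpus",
                "Mlig", "Mspi",
                "Mhys",
                "Mlig", "Mlig", "Mpus"),
    transcript = c("Mlig_a", "Mhys_a", "Mspi_a", "Mpus_a",
                   "Mlig_b", "Mspi_b",
                   "Mhys_c",
                   "Mlig_d1", "Mlig_d2", "Mpus_d"))
}

# Random orthogroup universe in long format for round-trip tests.
random_ogs <- function(n_og = 20, seed = 1) {
  set.seed(seed)
  cfg <- species_config()
  og_ids <- sprintf("OG%04d", seq_len(n_og))
  rows <- do.call(rbind, lapply(og_ids, function(og) {
    sp <- cfg$codes[runif(4) < 0.7]
    if (!length(sp)) sp <- sample(cfg$codes, 1)
    counts <- 1 + rpois(length(sp), 0.5)
    data.frame(og_id = og, species = rep(sp, counts),
               transcript = paste0(rep(sp, counts), "_", og, "_",
                                   sequence(counts)),
               stringsAsFactors = FALSE)
  }))
  orthogroup_set(rows$og_id, rows$species, rows$transcript, config = cfg,
                 og_ids = og_ids)
}

jtt <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- build_rate_matrix("JTT")
    model
  }
})

# Simulate a single pair of sequences at distance t (two-leaf tree).
simulate_pair <- function(t, length, model = jtt()) {
  tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", t / 2, t / 2))
  simulate_alignment(tr, scale = 1, length = length, model = model,
                     og_id = "pair")
}

# Independent grid-search oracle for the pairwise ML distance: likelihood
# evaluated with Matrix::expm (Pade approximation, a different code path
# than the cached eigensystem), coarse grid then 1e-4 refinement around the
# coarse argmax.
grid_search_distance <- function(a, b, model = jtt(), t_max = 10,
                                 coarse_step = 0.005) {
  enc <- function(s) {
    lut <- integer(256)
    lut[utf8ToInt("ARNDCQEGHILKMFPSTWYV")] <- 1:20
    lut[utf8ToInt(toupper(s))]
  }
  ea <- enc(a); eb <- enc(b)
  use <- ea > 0 & eb > 0
  ea <- ea[use]; eb <- eb[use]
  counts <- matrix(0, 20, 20)
  for (k in seq_along(ea)) counts[ea[k], eb[k]] <- counts[ea[k], eb[k]] + 1
  loglik <- function(t) {
    P <- as.matrix(Matrix::expm(model$Q * t))
    P[P < 1e-300] <- 1e-300
    sum(counts * (log(model$pi) + log(P)))
  }
  eval_grid <- function(ts) vapply(ts, loglik, numeric(1))
  coarse <- seq(1e-4, t_max, by = coarse_step)
  lc <- eval_grid(coarse)
  best <- coarse[which.max(lc)]
  fine <- seq(max(1e-4, best - coarse_step), min(t_max, best + coarse_step),
              by = 1e-4)
  fine[which.max(eval_grid(fine))]
}
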