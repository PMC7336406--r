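# orthodiv

Comparative analysis of orthogroups across a small set of related species,
built around the question of whether reproduction-related gene families
evolve faster than the rest of the genome. The motivating system is the
flatworm genus *Macrostomum* — the annotated reference *M. lignano*
(`Mlig`) plus *M. hystrix* (`Mhys`), *M. spirale* (`Mspi`) and
*M. pusillum* (`Mpus`) — but species codes, the reference species and the
species tree are all configurable.

The package consumes the plain-text outputs of upstream tools (orthogroup
membership tables, per-orthogroup amino-acid alignments in FASTA,
per-species differential-expression result tables, transcript annotation
flags) and implements everything downstream:

* **Annotation transfer** — reference-species transcript labels
  (positional: testis/ovary/tail region; neoblast; social) are lifted to
  orthogroups as the union over reference members, conflicting labels
  within a family collapse to `positional_mix` / `neoblast_mix` /
  `social_mix`, and a fixed retention rule selects the seven labels used
  in testing.
* **DE consistency** — transcripts are called DE at adjusted *p* < α with
  direction from the sign of the log2 fold change; an orthogroup with at
  least one DE transcript in every required species is classified as
  consistently up, consistently down, or inconsistent.
* **Protein divergence** — pairwise maximum-likelihood distances under
  the Jones–Taylor–Thornton model. The reversible rate matrix is
  Q<sub>ij</sub> = S<sub>ij</sub>π<sub>j</sub>, scaled to one expected
  substitution per site per unit time, and the pairwise distance
  maximises ℓ(t) = Σ<sub>s</sub> log(π<sub>a<sub>s</sub></sub>
  P<sub>a<sub>s</sub>b<sub>s</sub></sub>(t)) over comparable columns
  (gaps and `X` dropped pairwise). Per orthogroup, within-species pairs
  are excluded, each species pair is averaged, and the orthogroup
  divergence is the mean of the six species-pair means; orthogroups above
  2 substitutions/site are excluded as near-saturated. Annotated
  orthogroups are tested against the median divergence of unannotated
  ones with a one-sample Wilcoxon signed-rank test, BH-corrected.
* **Species composition** — a resampling test (default 100,000 draws
  without replacement from the reference-containing universe) compares
  how often annotated orthogroups are complete (all four species) or
  restricted to a species pair against random expectation, with a
  doubled-tail smoothed p-value and BH correction per predicate.
* **Signal-peptide enrichment** — a chi-square goodness of fit of flagged
  orthogroup counts across positional categories with expected counts
  proportional to category sizes.
* **Synthetic data** — a generator that plants annotation classes with
  controllable completeness, divergence scale, signal-peptide probability
  and DE behaviour, emitting exactly the formats the readers consume, so
  the full pipeline runs and is testable with no external data.

## A worked example

```r
library(orthodiv)

sim <- simulation_config(n_ogs = 1000, seed = 1)
dir <- tempfile("demo_")
simulate_og_data(sim, dir)                 # writes TSV/FASTA inputs

pc <- pipeline_config(
  orthogroups = file.path(dir, "orthogroups.tsv"),
  alignments  = file.path(dir, "alignments"),
  de_tables   = list(Mhys = file.path(dir, "de_Mhys_AvH.tsv"),
                     Mspi = file.path(dir, "de_Mspi_AvH.tsv"),
                     Mpus = file.path(dir, "de_Mpus_AvH.tsv")),
  annotations = file.path(dir, "annotations.tsv"),
  out_dir = file.path(dir, "results"),
  n_iter = 10000, seed = 1)
report <- run_full_analysis(pc)
report
#> orthodiv pipeline report
#>   orthogroups: 1000 | transcripts: 3801
#>   annotated OGs: 42
#>   DE-eligible OGs: 13
#>   divergence estimates: 383 (median 0.475)
```

The default synthetic configuration plants a rapidly evolving
`testis_region`-like class (species completeness 0.5 vs 0.8 in the
background, divergence scale 1.5) and a conserved `neoblast_FACS`-like
class (completeness 0.95, scale 0.7). The report recovers both patterns.
Composition (complete = all four species present):

```r
subset(report$composition, predicate == "complete")
#>   predicate         label n_annotated observed expected ci_lo ci_hi          p n_iter seed      p_adj
#> 1  complete neoblast_FACS          19       19   9.0530     5    13 0.00019998  10000    2 0.00039996
#> 2  complete testis_region          23        2  10.9819     6    16 0.00039996  10000    3 0.00039996
```

The planted testis-like class is complete far less often than random
orthogroups (2 observed vs ~11 expected), the neoblast-like class far
more often (19 vs ~9). The divergence-shift table shows the conserved
class sitting significantly below the unannotated median (V = 0,
adjusted p ≈ 8e-06 with n = 19), while only two testis-like orthogroups
were complete enough to test here — at this desk scale the divergence
signal for a rare, incomplete class needs the larger simulated universes
used in the test suite.

Single components work standalone, e.g. the enrichment test with the
expected counts rounded to one decimal as in published tables:

```r
signalp_gof_test(observed = c(130, 37, 53, 16, 1764),
                 sizes    = c(728, 181, 173, 84, 10165),
                 rounding = "printed_1dp")
#> Chi-square goodness of fit (proportional allocation, expected rounded to 1 dp)
#>   chi-squared = 18.04, df = 4, p = 0.001214
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/orthodiv-pipeline.R` (subcommands `run` and `simulate`).

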