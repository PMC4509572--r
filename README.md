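# barcodeval

Evaluation of multi-locus DNA barcode reference libraries for tree species
identification.

A plot-based barcode library pairs each collected tree with aligned
sequences at a few barcode loci (typically rbcL, matK, trnH–psbA and ITS)
and a field identification (species, genus, family, plot). `barcodeval`
measures what such a library is worth, for the people who build them
(ecologists running plot inventories) and the people who query them:

* **Supermatrix construction** — per-locus alignments concatenated with an
  explicit partition map; loci that only align within families (trnH–psbA)
  are folded in block-diagonally, and missing data stays missing (pairwise
  deletion everywhere, never silent zeros).
* **Tree-based resolution** — Neighbor-Joining on p or K2P distances
  (K2P: *d* = −½ ln(1−2P−Q) − ¼ ln(1−2Q)), nonparametric bootstrap
  resampled within partitions, and the supported-monophyly criterion: a
  species with ≥ 2 sampled individuals is resolved iff its leaves form a
  bipartition of the unrooted tree with bootstrap support ≥ 50 %.
* **Similarity-based identification** — each query is assigned to the best
  matching species iff it shows ≥ 95 % identical sites to a conspecific
  reference *and* every sequence of that species strictly out-scores every
  sequence of any other species; evaluated leave-one-out (every sequence is
  both database and query) and in a regional design (one plot is the
  database, the other plots' shared taxa are queries).
* **Misidentification audit** — the algorithmic half of reciprocal
  illumination: specimens whose placement on the core-barcode (rbcL+matK)
  tree conflicts with their recorded taxonomy are flagged, with the
  conflict classified at family, genus or species level and gated on
  bootstrap support.
* **Synthetic data generator** — nested taxonomy (families ⊃ genera ⊃
  species ⊃ 1–6 specimens), a shared height-banded pure-birth genealogy,
  JC69 sequences, per-locus Bernoulli sequence recovery, optional
  between-plot intraspecific divergence, and injectable field
  misidentifications with ground truth — so the whole pipeline is testable
  without any field collection.

## Worked example

Simulate a small two-locus flora with an 8 % misidentification rate, then
run the three evaluations:

```r
library(barcodeval)

cfg <- sim_config(n_families = 3, genera_per_family = 2, species_per_genus = 2,
                  samples_per_species = 2:3, misid_rate = 0.08,
                  loci = list(
                    list(name = "rbcL", length = 550, inter = 0.05, intra = 0.001,
                         recovery = 0.95, per_family = FALSE),
                    list(name = "matK", length = 800, inter = 0.05, intra = 0.001,
                         recovery = 0.85, per_family = FALSE)))
sim <- simulate_dataset(cfg, seed = 1)

recovery_stats(sim$dataset)$per_locus
#>   locus  n  fraction   pct
#> 1  rbcL 31 1.0000000 100.0
#> 2  matK 29 0.9354839  93.5

tree <- combination_tree(sim$dataset, c("rbcL", "matK"), replicates = 200, seed = 2)
resolution_report(tree, sim$dataset$specimens, label = "rbcL+matK")
#>       label    rank eligible supported rate
#> 1 rbcL+matK species       11         8 72.7
#> 2 rbcL+matK   genus        6         2 33.3
#> 3 rbcL+matK  family        3         0  0.0

evaluate_leave_one_out(sim$dataset, c("rbcL", "matK"))$report
#>            mode     label query_plot    rank n_queries correct incorrect no_assignment unscorable rate
#> 1 leave_one_out rbcL+matK       <NA> species        31      21         7             3          0 75.0
#> 2 leave_one_out rbcL+matK       <NA>   genus        31      21         8             2          0 72.4

flag_conflicts(tree, sim$dataset$specimens)[, c("sample_id", "level", "support")]
#>   sample_id  level support
#> 3    XB0018 family     100
#> 4    XB0019 family     100
#> 1    XB0021 family      87
#> 2    XB0022 family     100
```

Reading the output: species-level resolution is 8 of 11 multi-sampled
species (72.7 %) — the injected label errors break several recorded-species
clades, and genus/family monophyly suffers more because a single misfiled
specimen breaks a whole higher clade. The leave-one-out rate is computed
over queries with a defined outcome (21 correct / 28 defined = 75.0 %);
queries whose best conspecific match falls below 95 % identity are counted
separately as `no_assignment`. The audit flags exactly the two injected
family-level errors in this run (`XB0018`, `XB0022` — compare
`sim$errors`) plus their swap partners `XB0019` and `XB0021`: when a
mislabeled specimen invades another species' clade, both sides of the
conflict are queued for review, and deciding which label is wrong is the
human half of reciprocal illumination.

The numbered scripts under `analysis/` run the same stages at a larger
scale (simulate → recovery → audit → resolution → assignment → report) and
write their tables under `results/`.

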