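test_that("taxonomy generation matches configured counts and is seed-deterministic", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2, species_per_genus = 3,
                    samples_per_species = 2, loci = sim_loci("rbcL", 50))
  tx <- generate_taxonomy(cfg, seed = 3)
  expect_equal(nrow(tx), 2 * 2 * 3 * 2)
  expect_equal(length(unique(tx$species)), 12)
  expect_equal(length(unique(tx$genus)), 4)
  expect_equal(length(unique(tx$family)), 2)
  # binomials start with the genus
  expect_true(all(startsWith(tx$species, paste0(tx$genus, " "))))
  expect_identical(tx, generate_taxonomy(cfg, seed = 3))
  expect_false(identical(tx, generate_taxonomy(cfg, seed = 4)))
})

test_that("clade-richness regimes are reproduced by configuration", {
  # 25 species spread over 10 genera is the S/G = 2.5 regime
  expect_equal(richness_ratios(25, 25, 10)$sg, 2.5)
  cfg <- sim_config(n_families = 1, genera_per_family = 10,
                    species_per_genus = 2:3, samples_per_species = 1,
                    loci = sim_loci("rbcL", 50))
  sg <- vapply(1:10, function(s) {
    tx <- generate_taxonomy(cfg, seed = s)
    length(unique(tx$species)) / length(unique(tx$genus))
  }, 0)
  expect_true(all(sg >= 2 & sg <= 3))
  expect_equal(mean(sg), 2.5, tolerance = 0.15)
})

test_that("the generator refuses inverted barcode-gap configurations", {
  expect_error(
    sim_config(loci = sim_loci("rbcL", 100, inter = 0.001, intra = 0.05)),
    "inverted")
  expect_silent(
    sim_config(loci = sim_loci("rbcL", 100, inter = 0.001, intra = 0.05),
               allow_inverted_gap = TRUE))
})

test_that("zero intraspecific height makes conspecific sequences identical; full recovery keeps all specimens", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2, species_per_genus = 2,
                    samples_per_species = 3,
                    loci = sim_loci("rbcL", 300, intra = 0))
  sim <- simulate_dataset(cfg, seed = 9)
  aln <- sim$dataset$alignments$rbcL
  expect_setequal(aln$members, sim$truth$sample_id)  # recovery = 1
  for (sp in unique(sim$truth$species)) {
    ids <- sim$truth$sample_id[sim$truth$species == sp]
    expect_length(unique(aln$seqs[ids]), 1)
  }
})

test_that("mean intraspecific p-distance matches the JC69 expectation", {
  # two conspecifics sit 2*intra apart; JC69 expected p-distance is
  # (3/4) * (1 - exp(-8*intra/3))
  intra <- 0.001
  expected <- 0.75 * (1 - exp(-8 * intra / 3))
  cfg <- sim_config(n_families = 1, genera_per_family = 2, species_per_genus = 5,
                    samples_per_species = 4,
                    loci = sim_loci("rbcL", 2000, intra = intra))
  obs <- vapply(1:20, function(s) {
    sim <- simulate_dataset(cfg, seed = 100 + s)
    D <- p_distance(sim$dataset$alignments$rbcL)
    sp_of <- setNames(sim$truth$species, sim$truth$sample_id)
    vals <- c()
    for (sp in unique(sp_of)) {
      ids <- names(sp_of)[sp_of == sp]
      sub <- D$values[ids, ids]
      vals <- c(vals, sub[upper.tri(sub)])
    }
    mean(vals)
  }, 0)
  expect_equal(mean(obs), expected, tolerance = 0.05)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg(misid_rate = 0.1)
  s1 <- simulate_dataset(cfg, seed = 17)
  s2 <- simulate_dataset(cfg, seed = 17)
  expect_identical(s1$dataset$specimens, s2$dataset$specimens)
  expect_identical(s1$dataset$alignments$rbcL$seqs, s2$dataset$alignments$rbcL$seqs)
  expect_identical(s1$errors, s2$errors)
})

test_that("misidentification injection respects rate, level mix and bookkeeping", {
  cfg <- sim_config(n_families = 6, genera_per_family = 3, species_per_genus = 3,
                    samples_per_species = 3, loci = sim_loci("rbcL", 50))
  tx <- generate_taxonomy(cfg, seed = 21)

  none <- inject_misidentifications(tx, rate = 0)
  expect_identical(none$specimens, tx)
  expect_equal(nrow(none$errors), 0)

  inj <- inject_misidentifications(tx, rate = 0.2, seed = 22)
  n_err <- round(0.2 * nrow(tx))
  expect_equal(nrow(inj$errors), n_err)
  # every listed error differs between true and recorded labels
  expect_true(all(inj$errors$true_species != inj$errors$recorded_species))
  # level semantics
  fam <- inj$errors[inj$errors$level == "family", ]
  expect_true(all(fam$true_family != fam$recorded_family))
  gen <- inj$errors[inj$errors$level == "genus", ]
  expect_true(all(gen$true_family == gen$recorded_family &
                    gen$true_genus != gen$recorded_genus))
  spe <- inj$errors[inj$errors$level == "species", ]
  expect_true(all(spe$true_genus == spe$recorded_genus &
                    spe$true_species != spe$recorded_species))
  # corrupted records differ from truth exactly at the listed ids
  changed <- tx$sample_id[tx$species != inj$specimens$species]
  expect_setequal(changed, inj$errors$sample_id)
})

test_that("largest-remainder apportionment reproduces the 74:17:5 shares over 96 errors", {
  # enough specimens that 96 errors are available at every level
  cfg <- sim_config(n_families = 8, genera_per_family = 3, species_per_genus = 3,
                    samples_per_species = 5, loci = sim_loci("rbcL", 10))
  tx <- generate_taxonomy(cfg, seed = 31)
  rate <- 96 / nrow(tx)
  inj <- inject_misidentifications(tx, rate = rate, seed = 32)
  counts <- table(factor(inj$errors$level, c("family", "genus", "species")))
  expect_equal(as.vector(counts), c(74L, 17L, 5L))
  expect_equal(percent(counts[["family"]], sum(counts)), 77.1)
  expect_equal(percent(counts[["genus"]], sum(counts)), 17.7)
  expect_equal(percent(counts[["species"]], sum(counts)), 5.2)
})

test_that("species-level injection fails cleanly in a 1-species-per-genus taxonomy", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2, species_per_genus = 1,
                    samples_per_species = 2, loci = sim_loci("rbcL", 10))
  tx <- generate_taxonomy(cfg, seed = 41)
  expect_error(
    inject_misidentifications(tx, rate = 0.5, mix = c(family = 0, genus = 0,
                                                      species = 1), seed = 42),
    "species-level")
})

test_that("per-locus recovery draws are Bernoulli at the configured rate", {
  cfg <- sim_config(n_families = 4, genera_per_family = 2, species_per_genus = 2,
                    samples_per_species = 4,
                    loci = sim_loci("rbcL", 30, recovery = 0.7))
  fracs <- vapply(1:15, function(s) {
    sim <- simulate_dataset(cfg, seed = 300 + s)
    recovery_stats(sim$dataset)$per_locus$fraction
  }, 0)
  expect_equal(mean(fracs), 0.7, tolerance = 0.05)
})
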