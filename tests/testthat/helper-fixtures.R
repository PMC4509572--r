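# Shared fixtures: tiny hand-written datasets and simulation configs.

toy_specimens <- function() {
  data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1"),
    species = c("Alpha una", "Alpha una", "Alpha duo", "Alpha duo", "Beta tria"),
    genus = c("Alpha", "Alpha", "Alpha", "Alpha", "Beta"),
    family = c("Alphaceae", "Alphaceae", "Alphaceae", "Alphaceae", "Betaceae"),
    plot = c("P1", "P1", "P2", "P2", "P1"),
    stringsAsFactors = FALSE)
}

toy_alignment <- function(seqs, locus = "locusA") {
  locus_alignment(seqs, locus)
}

# uniform loci for simulation-based tests
sim_loci <- function(names, length = 500, inter = 0.05, intra = 0.001,
                     recovery = 1, per_family = FALSE) {
  lapply(names, function(nm) {
    list(name = nm, length = length, inter = inter, intra = intra,
         recovery = recovery, per_family = per_family)
  })
}

# a small clean two-locus configuration used across tests
small_cfg <- function(...) {
  sim_config(n_families = 3, genera_per_family = 2, species_per_genus = 2,
             samples_per_species = 2:3,
             loci = sim_loci(c("rbcL", "matK")), ...)
}
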