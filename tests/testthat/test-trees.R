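test_that("p-distance scores mismatches over comparable sites with pairwise deletion", {
  a <- toy_alignment(c(x = "ACGT", y = "ACGT", z = "AGGT", w = "AC-T"))
  D <- p_distance(a)
  expect_equal(D$values["x", "y"], 0)
  expect_equal(D$values["x", "z"], 0.25)
  expect_equal(D$values["x", "w"], 0)           # 0 mismatches over 3 sites
  expect_equal(D$comparable_sites["x", "w"], 3)
  expect_equal(diag(D$values), setNames(rep(0, 4), a$members))
  expect_true(isSymmetric(D$values))
})

test_that("K2P distance matches its closed form and flags saturation", {
  # one transition among four sites: P = 0.25, Q = 0 -> -log(0.5)/2
  a <- toy_alignment(c(x = "ACGT", y = "GCGT"))
  D <- k2p_distance(a)
  expect_equal(D$values["x", "y"], -0.5 * log(0.5), tolerance = 1e-12)

  ident <- k2p_distance(toy_alignment(c(x = "ACGT", y = "ACGT")))
  expect_equal(ident$values["x", "y"], 0)

  # pure transversions at half the sites: 1 - 2Q = 0 -> saturated
  sat <- k2p_distance(toy_alignment(c(x = "AAGG", y = "CAGG", z = "CCGG")))
  expect_true(sat$saturated["x", "z"])
  expect_true(is.na(sat$values["x", "z"]))
  expect_false(sat$saturated["x", "y"])
})

test_that("p and K2P distances agree to first order for closely related pairs", {
  set.seed(5)
  for (rep in 1:20) {
    L <- 1000
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    y <- x
    k <- sample(0:15, 1)  # p <= 0.015
    pos <- sample(L, k)
    y[pos] <- vapply(y[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    a <- toy_alignment(c(x = paste(x, collapse = ""), y = paste(y, collapse = "")))
    p <- p_distance(a)$values["x", "y"]
    k2 <- k2p_distance(a)$values["x", "y"]
    expect_lt(abs(p - k2), 0.01)
  }
})

test_that("NJ on three taxa reproduces the three-point branch lengths", {
  D <- structure(list(
    members = c("a", "b", "c"),
    values = matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    comparable_sites = matrix(10, 3, 3), undefined = matrix(FALSE, 3, 3),
    saturated = matrix(FALSE, 3, 3), model = "p"),
    class = "distance_matrix")
  tr <- neighbor_joining(D)
  len <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(len[["a"]], (3 + 4 - 5) / 2)  # 1
  expect_equal(len[["b"]], (3 + 5 - 4) / 2)  # 2
  expect_equal(len[["c"]], (4 + 5 - 3) / 2)  # 3
})

test_that("NJ recovers the generating topology on additive matrices (exhaustive oracle, n <= 6)", {
  set.seed(11)
  for (n in c(4, 5, 6)) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(n, rooted = FALSE,
                              tip.label = paste0("t", seq_len(n)))
      true_tree$edge.length <- runif(nrow(true_tree$edge), 0.5, 2)
      D_mat <- ape::cophenetic.phylo(true_tree)
      D_mat <- D_mat[sort(rownames(D_mat)), sort(rownames(D_mat))]
      D <- structure(list(
        members = rownames(D_mat), values = D_mat,
        comparable_sites = matrix(100, n, n),
        undefined = matrix(FALSE, n, n, dimnames = dimnames(D_mat)),
        saturated = matrix(FALSE, n, n, dimnames = dimnames(D_mat)),
        model = "p"), class = "distance_matrix")
      nj_tree <- neighbor_joining(D)
      best <- oracle_best_topology(D_mat)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_tree), ape::unroot(best))), 0)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_tree), ape::unroot(true_tree))), 0)
    }
  }
})

test_that("NJ output is invariant to member permutation", {
  set.seed(13)
  true_tree <- ape::rtree(7, rooted = FALSE)
  true_tree$edge.length <- runif(nrow(true_tree$edge), 0.5, 2)
  D_mat <- ape::cophenetic.phylo(true_tree)
  mk <- function(m) {
    n <- nrow(m)
    structure(list(members = rownames(m), values = m,
                   comparable_sites = matrix(100, n, n),
                   undefined = matrix(FALSE, n, n, dimnames = dimnames(m)),
                   saturated = matrix(FALSE, n, n, dimnames = dimnames(m)),
                   model = "p"), class = "distance_matrix")
  }
  t1 <- neighbor_joining(mk(D_mat))
  perm <- sample(rownames(D_mat))
  t2 <- neighbor_joining(mk(D_mat[perm, perm]))
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("negative NJ branch lengths are clamped to zero", {
  # a non-additive matrix known to produce negative NJ branches
  m <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- 0.1; m["b", "a"] <- 0.1  # squeeze to force negativity
  D <- structure(list(members = letters[1:4], values = m,
                      comparable_sites = matrix(100, 4, 4),
                      undefined = matrix(FALSE, 4, 4, dimnames = dimnames(m)),
                      saturated = matrix(FALSE, 4, 4, dimnames = dimnames(m)),
                      model = "p"), class = "distance_matrix")
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support saturates with clean signal, stays in range, and is seed-deterministic", {
  # 600 columns cleanly splitting xy | zw
  x <- strrep("A", 600)
  z <- strrep("C", 600)
  a <- toy_alignment(c(x1 = x, x2 = x, z1 = z, z2 = z))
  D <- p_distance(a)
  base <- neighbor_joining(D)
  tr <- bootstrap_support(a, base, replicates = 100, seed = 1, model = "p")
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_equal(sup, 100)

  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 2)
  sm <- combination_supermatrix(sim$dataset, c("rbcL", "matK"))
  D2 <- k2p_distance(sm)
  b2 <- neighbor_joining(D2)
  t1 <- bootstrap_support(sm, b2, replicates = 60, seed = 42)
  t2 <- bootstrap_support(sm, b2, replicates = 60, seed = 42)
  expect_identical(t1$node.label, t2$node.label)
  sup2 <- t1$node.label[!is.na(t1$node.label)]
  expect_true(all(sup2 >= 0 & sup2 <= 100))

  expect_error(bootstrap_support(a, base, replicates = 0), "replicates")
})

test_that("bootstrap resampling respects partition boundaries", {
  # locus 1 splits xy|zw; locus 2 is constant. If resampling is done within
  # partitions, every replicate keeps ~500 informative columns and support
  # stays 100; pooled resampling could drift, but the partition map must at
  # least reproduce the saturated case deterministically.
  a <- toy_alignment(c(x1 = strrep("A", 500), x2 = strrep("A", 500),
                       z1 = strrep("C", 500), z2 = strrep("C", 500)), "l1")
  b <- toy_alignment(c(x1 = strrep("G", 100), x2 = strrep("G", 100),
                       z1 = strrep("G", 100), z2 = strrep("G", 100)), "l2")
  sm <- concatenate(list(l1 = a, l2 = b))
  D <- p_distance(sm)
  base <- neighbor_joining(D)
  tr <- bootstrap_support(sm, base, replicates = 50, seed = 3, model = "p",
                          partitions = sm$partitions)
  expect_equal(tr$node.label[!is.na(tr$node.label)], 100)
})

test_that("intraspecific variable sites are tallied and split within- vs between-plot", {
  spec <- toy_specimens()
  # a1 (P1) vs a2 (P1): identical; b1 (P2) vs b2 (P2): 1 within-plot difference
  ds <- dataset(spec, list(l = toy_alignment(c(
    a1 = strrep("A", 100),
    a2 = strrep("A", 100),
    b1 = paste0("C", strrep("G", 99)),
    b2 = paste0("T", strrep("G", 99))), "l")))
  tv <- intraspecific_variation(ds, "l")
  alpha_una <- tv$per_species[tv$per_species$species == "Alpha una", ]
  expect_equal(alpha_una$n_variable_sites, 0)
  alpha_duo <- tv$per_species[tv$per_species$species == "Alpha duo", ]
  expect_equal(alpha_duo$n_variable_sites, 1)
  expect_equal(alpha_duo$n_within_plot, 1)

  # same difference but across plots
  spec2 <- spec
  spec2$plot[spec2$sample_id == "b2"] <- "P3"
  ds2 <- dataset(spec2, ds$alignments)
  tv2 <- intraspecific_variation(ds2, "l")
  duo2 <- tv2$per_species[tv2$per_species$species == "Alpha duo", ]
  expect_equal(duo2$n_between_plot, 1)
  expect_equal(duo2$n_within_plot, 0)
})

test_that("plot-structured divergence yields more between-plot than within-plot variable sites", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2, species_per_genus = 2,
                    samples_per_species = 4,
                    loci = sim_loci("rbcL", 1500, intra = 0.0005),
                    plots = c(A = 1, B = 1), plot_sep_height = 0.005,
                    species_crown_frac = 0.2)
  between <- 0; within <- 0
  for (s in 1:10) {
    sim <- simulate_dataset(cfg, seed = 500 + s)
    tv <- intraspecific_variation(sim$dataset, "rbcL")
    between <- between + sum(tv$per_species$n_between_plot)
    within <- within + sum(tv$per_species$n_within_plot)
  }
  expect_gt(between, within)
})
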