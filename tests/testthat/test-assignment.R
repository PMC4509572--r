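test_that("aligned identity scores unambiguous columns only", {
  expect_equal(pairwise_identity("ACGT", "ACGT")$identity, 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA")$identity, 0.75)
  gapped <- pairwise_identity("AC-T", "ACGT")
  expect_equal(gapped$identity, 1.0)
  expect_equal(gapped$scored_sites, 3L)
  allgap <- pairwise_identity("---N", "ACGT")
  expect_true(allgap$unscorable)
  expect_error(pairwise_identity("ACG", "ACGT"), "equal-length")
})

test_that("free-end-gap identity matches the worked overlap case", {
  r <- pairwise_identity("ACGTACGT", "GTACG", mode = "free_end_global")
  expect_equal(r$identity, 1.0)
  expect_equal(r$scored_sites, 5L)
  expect_equal(r$score, 5)
})

test_that("free-end-gap alignment agrees with the exhaustive oracle on short strings", {
  set.seed(19)
  for (rep in 1:25) {
    q <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), replace = TRUE),
               collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1), replace = TRUE),
               collapse = "")
    got <- pairwise_identity(q, s, mode = "free_end_global")
    want <- oracle_free_end(q, s)
    expect_equal(got$score, want$score, info = paste(q, s))
    expect_equal(got$identity, want$identity, info = paste(q, s))
    expect_equal(got$scored_sites, want$cols, info = paste(q, s))
  }
})

test_that("the >=95 % / dominance rule handles its boundary cases", {
  rule <- barcodeval:::apply_assignment_rule
  # conspecific identities {0.99, 0.98}, best heterospecific 0.90 -> correct
  r <- rule(c(s1 = 0.99, s2 = 0.98, h1 = 0.90),
            c("A", "A", "B"), "A")
  expect_equal(r$outcome, "correct")
  # best conspecific below threshold -> no assignment
  expect_equal(rule(c(s1 = 0.94, h1 = 0.90), c("A", "B"), "A")$outcome,
               "no_assignment")
  # a heterospecific outscores the conspecific -> incorrect
  expect_equal(rule(c(s1 = 0.96, h1 = 0.97), c("A", "B"), "A")$outcome,
               "incorrect")
  # exact tie with a heterospecific -> incorrect (strict dominance)
  expect_equal(rule(c(s1 = 0.96, h1 = 0.96), c("A", "B"), "A")$outcome,
               "incorrect")
  # dominance must hold for every member of the best species
  expect_equal(rule(c(s1 = 0.99, s2 = 0.80, h1 = 0.90),
                    c("A", "A", "B"), "A")$outcome, "incorrect")
  # all pairs unscorable
  expect_equal(rule(c(s1 = NA_real_), "A", "A")$outcome, "unscorable")
})

test_that("assign_query agrees with a literal brute-force oracle on random databases", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    n <- sample(8:30, 1)
    L <- 40
    n_sp <- sample(2:5, 1)
    species <- paste0("Gen", sample(1:2, n_sp, replace = TRUE), " sp", seq_len(n_sp))
    anc <- lapply(seq_len(n_sp), function(i) sample(bases, L, replace = TRUE))
    labels <- sample(seq_len(n_sp), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- anc[[labels[i]]]
      k <- rbinom(1, L, 0.04)
      if (k > 0) {
        pos <- sample(L, k)
        s[pos] <- sample(bases, k, replace = TRUE)
      }
      paste(s, collapse = "")
    }, "")
    db <- data.frame(
      sample_id = sprintf("d%02d", seq_len(n)), sequence = seqs,
      species = species[labels],
      genus = vapply(strsplit(species[labels], " "), `[`, "", 1),
      stringsAsFactors = FALSE)
    qi <- sample(n, 1)
    query <- setNames(db$sequence[qi], db$sample_id[qi])
    rest <- db[-qi, ]
    got <- assign_query(query, rest,
                        truth_species = db$species[qi],
                        truth_genus = db$genus[qi])
    want_sp <- oracle_assign(query, rest$sequence, rest$species,
                             db$species[qi], 0.95)
    want_gn <- oracle_assign(query, rest$sequence, rest$species,
                             db$genus[qi], 0.95, db_groups = rest$genus)
    expect_equal(got$species$outcome, want_sp)
    expect_equal(got$genus$outcome, want_gn)
  }
})

test_that("raising the threshold never upgrades an outcome to correct", {
  set.seed(29)
  rule <- barcodeval:::apply_assignment_rule
  rank_of <- c(correct = 3, incorrect = 2, no_assignment = 1, unscorable = 0)
  for (rep in 1:200) {
    k <- sample(3:8, 1)
    ids <- round(runif(k, 0.85, 1), 3)
    taxa <- sample(c("A", "B", "C"), k, replace = TRUE)
    o_low <- rule(ids, taxa, "A", threshold = 0.90)$outcome
    o_high <- rule(ids, taxa, "A", threshold = 0.97)$outcome
    if (o_high == "correct") expect_equal(o_low, "correct")
    if (o_low == "no_assignment") expect_equal(o_high, "no_assignment")
  }
})

test_that("leave-one-out separated-species limit reaches 100 % and singletons report empty denominators", {
  spec <- toy_specimens()
  # conspecifics identical; species >5 % apart
  ds <- dataset(spec, list(l = toy_alignment(c(
    a1 = strrep("A", 40), a2 = strrep("A", 40),
    b1 = strrep("C", 40), b2 = strrep("C", 40),
    c1 = strrep("G", 40)), "l")))
  r <- evaluate_leave_one_out(ds, "l")
  sp <- r$report[r$report$rank == "species", ]
  expect_equal(sp$correct, 4)
  expect_equal(sp$rate, 100.0)
  expect_equal(sp$no_assignment, 1)  # the singleton c1

  # all singletons: species denominator zero, reported as such
  solo <- data.frame(sample_id = c("x1", "y1"),
                     species = c("Xa una", "Ya una"),
                     genus = c("Xa", "Ya"), family = c("Xaceae", "Yaceae"),
                     plot = "P1", stringsAsFactors = FALSE)
  ds2 <- dataset(solo, list(l = toy_alignment(
    c(x1 = strrep("A", 40), y1 = strrep("C", 40)), "l")))
  r2 <- evaluate_leave_one_out(ds2, "l")
  sp2 <- r2$report[r2$report$rank == "species", ]
  expect_equal(sp2$correct + sp2$incorrect, 0)
  expect_true(is.na(sp2$rate))
})

test_that("species-level LOO success never exceeds genus-level success", {
  for (s in 1:5) {
    cfg <- sim_config(n_families = 2, genera_per_family = 3,
                      species_per_genus = 2:3, samples_per_species = 2,
                      loci = sim_loci("rbcL", 400, intra = 0.003),
                      species_crown_frac = 0.08)
    sim <- simulate_dataset(cfg, seed = 900 + s)
    r <- evaluate_leave_one_out(sim$dataset, "rbcL")$report
    sp <- r[r$rank == "species", ]
    gn <- r[r$rank == "genus", ]
    # count-level check (rates share no denominator): every species-correct
    # query is genus-correct
    pq <- evaluate_leave_one_out(sim$dataset, "rbcL")$per_query
    sp_ok <- pq$query_id[pq$species_outcome == "correct"]
    gn_ok <- pq$query_id[pq$genus_outcome == "correct"]
    expect_true(all(sp_ok %in% gn_ok))
    expect_lte(sp$correct, gn$correct)
  }
})

test_that("multi-locus identity is the scored-site-weighted per-locus average", {
  spec <- toy_specimens()[1:2, ]
  ds <- dataset(spec, list(
    l1 = toy_alignment(c(a1 = "AAAA", a2 = "AAAT"), "l1"),      # 3/4
    l2 = toy_alignment(c(a1 = "CCCCCC", a2 = "CCCCCC"), "l2"))) # 6/6
  im <- identity_matrix(ds, c("l1", "l2"))
  expect_equal(im$identity["a1", "a2"], 9 / 10)
  expect_equal(im$scored_sites["a1", "a2"], 10)
})

test_that("cross-plot evaluation filters queries to shared taxa and matches LOO for the database plot", {
  cfg <- sim_config(n_families = 2, genera_per_family = 2, species_per_genus = 2,
                    samples_per_species = 3:4, loci = sim_loci("rbcL", 600),
                    plots = c(A = 2, B = 1))
  sim <- simulate_dataset(cfg, seed = 33)
  cp <- evaluate_cross_plot(sim$dataset, db_plot = "A", loci = "rbcL")
  expect_setequal(unique(cp$report$query_plot), c("A", "B"))

  spec <- sim$dataset$specimens
  members <- sim$dataset$alignments$rbcL$members
  a_species <- unique(spec$species[spec$plot == "A" & spec$sample_id %in% members])
  b_queries <- cp$per_query$query_id[cp$per_query$query_plot == "B" &
                                       cp$per_query$rank == "species"]
  # every species-level query from B belongs to a species present in A
  expect_true(all(spec$species[match(b_queries, spec$sample_id)] %in% a_species))

  # db == query plot reduces to leave-one-out within that plot
  a_only <- spec[spec$plot == "A", ]
  ds_a <- dataset(a_only, list(rbcL = locus_alignment(
    sim$dataset$alignments$rbcL$seqs[intersect(members, a_only$sample_id)],
    "rbcL")))
  loo_a <- evaluate_leave_one_out(ds_a, "rbcL")$per_query
  cp_aa <- cp$per_query[cp$per_query$query_plot == "A" &
                          cp$per_query$rank == "species", ]
  shared_ids <- intersect(loo_a$query_id, cp_aa$query_id)
  expect_equal(
    cp_aa$species_outcome[match(shared_ids, cp_aa$query_id)],
    loo_a$species_outcome[match(shared_ids, loo_a$query_id)])

  expect_error(evaluate_cross_plot(sim$dataset, db_plot = "Z", loci = "rbcL"),
               "unknown plot")
})
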