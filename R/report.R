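# Pipeline orchestration and report arithmetic: clade-richness ratios,
# shared-taxa counts between plots, and the full report bundle.

#' Clade-richness ratios
#'
#' Individuals-per-genus (I/G) and species-per-genus (S/G) ratios, the
#' quantities used to compare reference libraries across floras. I/G is
#' printed half-up to one decimal; S/G to one and to two decimals (both
#' conventions appear in published comparisons).
#'
#' @param individuals,species,genera counts.
#' @return list with `ig`, `sg`, `sg2` (two-decimal S/G) and the raw counts.
#' @export
richness_ratios <- function(individuals, species, genera) {
  if (genera < 1) abort_validation("genera must be >= 1")
  list(ig = round_half_up(individuals / genera, 1),
       sg = round_half_up(species / genera, 1),
       sg2 = round_half_up(species / genera, 2),
       individuals = individuals, species = species, genera = genera)
}

#' Shared species and genus counts between plot pairs
#'
#' For each unordered plot pair and locus, counts the species (and genera)
#' having at least one sequenced individual in both plots.
#'
#' @param ds a `barcode_dataset`.
#' @param loci locus names (default: all).
#' @param plot_pairs optional list of 2-vectors; default all unordered pairs.
#' @return data.frame: `plot_a`, `plot_b`, `locus`, `shared_species`,
#'   `shared_genera`.
#' @export
shared_taxa_counts <- function(ds, loci = names(ds$alignments), plot_pairs = NULL) {
  plots <- sort(unique(ds$specimens$plot))
  if (length(plots) < 2) abort_validation("need >= 2 plots")
  if (is.null(plot_pairs)) {
    plot_pairs <- utils::combn(plots, 2, simplify = FALSE)
  }
  bad <- setdiff(unique(unlist(plot_pairs)), plots)
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown plot label(s): %s", paste(bad, collapse = ", ")))
  }
  sp_of <- setNames(ds$specimens$species, ds$specimens$sample_id)
  gen_of <- setNames(ds$specimens$genus, ds$specimens$sample_id)
  plot_of <- setNames(ds$specimens$plot, ds$specimens$sample_id)
  rows <- list()
  for (locus in loci) {
    mem <- locus_members(ds$alignments[[locus]])
    for (pr in plot_pairs) {
      a <- mem[plot_of[mem] == pr[1]]
      b <- mem[plot_of[mem] == pr[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        plot_a = pr[1], plot_b = pr[2], locus = locus,
        shared_species = length(intersect(unique(sp_of[a]), unique(sp_of[b]))),
        shared_genera = length(intersect(unique(gen_of[a]), unique(gen_of[b]))),
        stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows)
}

#' Build a supermatrix for a locus combination of a dataset
#'
#' Folds per-family loci block-diagonally, then concatenates the requested
#' loci under the union member policy.
#'
#' @param ds a `barcode_dataset`.
#' @param loci locus names in the desired partition order.
#' @return a `supermatrix`.
#' @export
combination_supermatrix <- function(ds, loci) {
  alns <- lapply(loci, function(l) flat_alignment(ds, l))
  names(alns) <- loci
  concatenate(alns, member_policy = "union")
}

#' NJ + bootstrap support tree for a locus combination
#'
#' Members involved in undefined (no comparable sites) or saturated pairs
#' are dropped (greedily, logged in `attr(, "dropped")`) before NJ.
#'
#' @param ds a `barcode_dataset`.
#' @param loci locus combination.
#' @param model distance model, `"k2p"` (default) or `"p"`.
#' @param replicates bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap resampling.
#' @return a support tree (`phylo` with `node.label` percentages);
#'   `attr(, "dropped")` lists members removed to resolve undefined pairs.
#' @export
combination_tree <- function(ds, loci, model = c("k2p", "p"),
                             replicates = 1000, seed = NULL) {
  model <- match.arg(model)
  sm <- combination_supermatrix(ds, loci)
  D <- if (model == "p") p_distance(sm) else k2p_distance(sm)
  D <- drop_undefined_members(D)
  keep <- D$members
  if (length(keep) < 4) abort_validation("fewer than 4 connectable members")
  sm_kept <- sm
  sm_kept$members <- keep
  sm_kept$seqs <- sm$seqs[keep]
  base <- neighbor_joining(D)
  tree <- bootstrap_support(sm_kept, base, replicates = replicates, seed = seed,
                            model = model, partitions = sm$partitions)
  attr(tree, "dropped") <- attr(D, "dropped")
  tree
}

#' Run the full evaluation pipeline and write the report bundle
#'
#' Stages: sequence-recovery statistics; per-combination NJ + bootstrap trees
#' with supported-monophyly resolution rates at species/genus/family rank;
#' leave-one-out and cross-plot similarity-based identification; taxonomy
#' conflict audit on the core-barcode combination; shared-taxa counts;
#' clade-richness ratios; per-locus intraspecific variable-site tallies.
#' Every stage's table is written even when empty. A manifest records the
#' configuration and seed, so a bundle is reproducible byte for byte.
#'
#' @param ds a `barcode_dataset` (e.g. from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param out_dir output directory.
#' @param combinations list of locus-name vectors to evaluate (default:
#'   each single locus plus the cumulative combinations of the configured
#'   locus order).
#' @param core_loci loci used for the misidentification audit (default the
#'   first two, conventionally rbcL+matK).
#' @param replicates bootstrap replicates (default 1000).
#' @param cutoff support cutoff for resolution and the audit gate
#'   (default 50).
#' @param threshold identity threshold for assignment (default 0.95).
#' @param model distance model for trees (default `"k2p"`).
#' @param db_plot plot used as cross-plot reference database (default: the
#'   plot with most sequenced specimens).
#' @param seed integer seed controlling bootstrap resampling.
#' @return invisibly, a list with all stage results (`recovery`,
#'   `resolution`, `loo`, `cross_plot`, `audit`, `shared`, `ratios`,
#'   `intraspecific`, `manifest`).
#' @export
run_pipeline <- function(ds, out_dir, combinations = NULL, core_loci = NULL,
                         replicates = 1000, cutoff = 50, threshold = 0.95,
                         model = "k2p", db_plot = NULL, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  loci <- names(ds$alignments)
  if (is.null(combinations)) {
    combinations <- c(as.list(loci),
                      lapply(seq_along(loci)[-1], function(k) loci[seq_len(k)]))
    combinations <- unique(combinations)
  }
  core_loci <- core_loci %||% loci[seq_len(min(2, length(loci)))]
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  recovery <- recovery_stats(ds)
  write_tsv(recovery$per_locus, "recovery_per_locus.tsv")

  resolution <- list()
  trees <- list()
  for (i in seq_along(combinations)) {
    combo <- combinations[[i]]
    label <- paste(combo, collapse = "+")
    tree <- combination_tree(ds, combo, model = model, replicates = replicates,
                             seed = seed + i)
    trees[[label]] <- tree
    write_support_tree(tree, file.path(out_dir, paste0(
      "tree_", gsub("[^A-Za-z0-9]+", "_", label), ".nwk")))
    keep <- ds$specimens$sample_id %in% tree$tip.label
    resolution[[label]] <- resolution_report(tree, ds$specimens[keep, ],
                                             label = label, cutoff = cutoff)
  }
  resolution <- rbind_rows(resolution)
  write_tsv(resolution, "resolution.tsv")

  loo <- lapply(combinations, function(combo) {
    evaluate_leave_one_out(ds, combo, threshold = threshold)$report
  })
  loo <- rbind_rows(loo)
  write_tsv(loo, "assignment_leave_one_out.tsv")

  plot_of <- setNames(ds$specimens$plot, ds$specimens$sample_id)
  if (is.null(db_plot)) {
    seq_members <- unique(unlist(lapply(ds$alignments, locus_members),
                                 use.names = FALSE))
    db_plot <- names(sort(table(plot_of[seq_members]), decreasing = TRUE))[1]
  }
  cross <- tryCatch(
    evaluate_cross_plot(ds, db_plot, loci = loci, threshold = threshold)$report,
    barcodeval_validation_error = function(e) {
      data.frame(mode = "cross_plot", label = paste(loci, collapse = "+"),
                 query_plot = NA_character_, rank = NA_character_,
                 n_queries = 0L, correct = 0L, incorrect = 0L,
                 no_assignment = 0L, unscorable = 0L, rate = NA_real_,
                 n_shared = 0L, stringsAsFactors = FALSE)
    })
  write_tsv(cross, "assignment_cross_plot.tsv")

  core_label <- paste(core_loci, collapse = "+")
  audit_tree <- trees[[core_label]] %||%
    combination_tree(ds, core_loci, model = model, replicates = replicates,
                     seed = seed)
  audit_specimens <- ds$specimens[ds$specimens$sample_id %in% audit_tree$tip.label, ]
  flags <- flag_conflicts(audit_tree, audit_specimens, min_support = cutoff)
  audit <- audit_summary(flags, n_audited = nrow(audit_specimens))
  write_tsv(flags, "audit_flags.tsv")
  jsonlite::write_json(audit, file.path(out_dir, "audit_summary.json"),
                       auto_unbox = TRUE, dataframe = "rows", na = "null")

  shared <- if (length(unique(ds$specimens$plot)) >= 2) {
    shared_taxa_counts(ds)
  } else {
    data.frame(plot_a = character(0), plot_b = character(0), locus = character(0),
               shared_species = integer(0), shared_genera = integer(0))
  }
  write_tsv(shared, "shared_taxa.tsv")

  ratios <- richness_ratios(nrow(ds$specimens),
                            length(unique(ds$specimens$species)),
                            length(unique(ds$specimens$genus)))
  jsonlite::write_json(ratios, file.path(out_dir, "richness_ratios.json"),
                       auto_unbox = TRUE)

  intra <- lapply(loci, function(l) {
    tl <- intraspecific_variation(ds, l)$per_species
    if (nrow(tl) > 0) tl$locus <- l else tl$locus <- character(0)
    tl
  })
  intra <- rbind_rows(intra)
  write_tsv(intra, "intraspecific_variation.tsv")

  manifest <- list(
    seed = seed, replicates = replicates, cutoff = cutoff,
    threshold = threshold, model = model, db_plot = db_plot,
    combinations = vapply(combinations, paste, "", collapse = "+"),
    core_loci = core_label,
    n_specimens = nrow(ds$specimens),
    package_version = as.character(utils::packageVersion("barcodeval")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(recovery = recovery, resolution = resolution, loo = loo,
                 cross_plot = cross, audit = list(flags = flags, summary = audit),
                 shared = shared, ratios = ratios, intraspecific = intra,
                 trees = trees, manifest = manifest))
}
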