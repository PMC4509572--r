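# Synthetic barcode-data generator: nested taxonomy, a height-banded
# pure-birth specimen genealogy shared by all loci, JC69 substitutions,
# Bernoulli per-locus sequence recovery and injectable field
# misidentification errors.

#' Simulation configuration
#'
#' Defaults emulate a scaled-down plot-based tropical tree flora: nested
#' taxonomy with 1-6 individuals per species, four barcode loci with
#' per-locus sequence recovery rates matching a realistic field campaign
#' (rbcL highest, ITS lowest), a non-globally-alignable locus handled per
#' family, four plots with unequal sampling effort, and a morphological
#' misidentification rate just under 10 percent dominated by family-level
#' errors. Divergence heights are in expected substitutions per site;
#' intraspecific height must be below interspecific height (the generator
#' refuses inverted-barcode-gap configurations unless
#' `allow_inverted_gap = TRUE`).
#'
#' @param n_families number of families.
#' @param genera_per_family,species_per_genus,samples_per_species integer
#'   value or range (vector) sampled per parent unit.
#' @param loci list of per-locus parameter lists with fields `name`,
#'   `length`, `inter` (root height over families), `intra` (conspecific
#'   star height), `recovery` (Bernoulli sequence-recovery probability),
#'   `per_family` (logical: alignable only within families).
#' @param plots named numeric vector of plot allocation weights.
#' @param genus_crown_frac,species_crown_frac crown heights of genera and of
#'   species within genera, as fractions of `inter`.
#' @param plot_sep_height optional between-plot intraspecific divergence
#'   height; default `NULL` means no plot substructure (equals `intra`).
#' @param misid_rate fraction of specimens whose recorded identification is
#'   corrupted.
#' @param misid_mix named weights for the level mix of injected errors.
#' @param allow_inverted_gap permit `intra >= inter` (for pathological-case
#'   testing only).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 8,
                       genera_per_family = 1:3,
                       species_per_genus = 1:3,
                       samples_per_species = 1:6,
                       loci = list(
                         list(name = "rbcL", length = 550, inter = 0.05,
                              intra = 0.001, recovery = 0.908, per_family = FALSE),
                         list(name = "matK", length = 800, inter = 0.05,
                              intra = 0.001, recovery = 0.795, per_family = FALSE),
                         list(name = "trnH-psbA", length = 450, inter = 0.05,
                              intra = 0.001, recovery = 0.856, per_family = TRUE),
                         list(name = "ITS", length = 650, inter = 0.05,
                              intra = 0.001, recovery = 0.710, per_family = FALSE)),
                       plots = c(BB = 1019, JJYL = 725, GGYL = 220, LSL = 88),
                       genus_crown_frac = 0.4,
                       species_crown_frac = 0.15,
                       plot_sep_height = NULL,
                       misid_rate = 0,
                       misid_mix = c(family = 74, genus = 17, species = 5),
                       allow_inverted_gap = FALSE) {
  cfg <- list(n_families = n_families, genera_per_family = genera_per_family,
              species_per_genus = species_per_genus,
              samples_per_species = samples_per_species, loci = loci,
              plots = plots, genus_crown_frac = genus_crown_frac,
              species_crown_frac = species_crown_frac,
              plot_sep_height = plot_sep_height, misid_rate = misid_rate,
              misid_mix = misid_mix, allow_inverted_gap = allow_inverted_gap)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (any(c(cfg$n_families, cfg$genera_per_family, cfg$species_per_genus,
            cfg$samples_per_species) < 1)) {
    abort_validation("taxonomy counts must be positive")
  }
  for (l in cfg$loci) {
    if (l$recovery < 0 || l$recovery > 1) {
      abort_validation(sprintf("locus %s: recovery_rate must be in [0,1]", l$name))
    }
    if (!cfg$allow_inverted_gap && l$intra >= l$inter) {
      abort_validation(sprintf(
        "locus %s: intraspecific height %g >= interspecific height %g (inverted barcode gap); set allow_inverted_gap = TRUE to override",
        l$name, l$intra, l$inter))
    }
  }
  if (cfg$misid_rate < 0 || cfg$misid_rate > 1) {
    abort_validation("misid_rate must be in [0,1]")
  }
  if (is.null(names(cfg$plots)) || any(cfg$plots <= 0)) {
    abort_validation("plots must be a named vector of positive weights")
  }
  structure(cfg, class = "sim_config")
}

# internal: one draw from an integer value-or-range
draw_count <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

# internal: pseudo-Latin name factory (deterministic given the RNG stream)
make_names <- function(n, suffixes) {
  syl <- c("ba", "cal", "dro", "fi", "gan", "lo", "mir", "nes", "pho", "qui",
           "ru", "sten", "tal", "vel", "xan", "zor")
  out <- character(0)
  while (length(out) < n) {
    cand <- paste0(
      sample(syl, n, replace = TRUE), sample(syl, n, replace = TRUE),
      sample(suffixes, n, replace = TRUE))
    out <- unique(c(out, cand))
  }
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  vapply(out[seq_len(n)], cap, "")
}

#' Generate a nested synthetic taxonomy with specimen records
#'
#' Families, genera, species and specimens are drawn per the configured
#' counts/ranges; species names are synthetic binomials consistent with
#' their genus; specimens are allocated to plots by the configured weights.
#' Deterministic given `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return data.frame of specimen records (the ground-truth taxonomy).
#' @export
generate_taxonomy <- function(cfg, seed = NULL) {
  with_seed_if(seed, {
    fam_names <- sort(paste0(make_names(cfg$n_families, c("aceae"))))
    rows <- list()
    gen_total <- 0L
    used_genera <- character(0)
    for (fam in fam_names) {
      n_gen <- draw_count(cfg$genera_per_family)
      gen_names <- character(0)
      while (length(gen_names) < n_gen) {  # genus names unique across families
        cand <- make_names(n_gen, c("ia", "us", "um", "odendron"))
        gen_names <- unique(c(gen_names, setdiff(cand, used_genera)))
      }
      gen_names <- sort(gen_names[seq_len(n_gen)])
      used_genera <- c(used_genera, gen_names)
      for (gen in gen_names) {
        gen_total <- gen_total + 1L
        n_sp <- draw_count(cfg$species_per_genus)
        epithets <- sort(tolower(make_names(n_sp, c("ensis", "folia", "carpa",
                                                    "flora", "phylla"))))
        for (ep in epithets) {
          n_samples <- draw_count(cfg$samples_per_species)
          rows[[length(rows) + 1L]] <- data.frame(
            species = paste(gen, ep), genus = gen, family = fam,
            n_samples = n_samples, stringsAsFactors = FALSE)
        }
      }
    }
    tab <- do.call(rbind, rows)
    n_total <- sum(tab$n_samples)
    specimens <- data.frame(
      sample_id = sprintf("XB%04d", seq_len(n_total)),
      species = rep(tab$species, tab$n_samples),
      genus = rep(tab$genus, tab$n_samples),
      family = rep(tab$family, tab$n_samples),
      plot = sample(names(cfg$plots), n_total, replace = TRUE,
                    prob = cfg$plots / sum(cfg$plots)),
      stringsAsFactors = FALSE)
    validate_specimens(specimens)
  })
}

# ---- genealogy shape -------------------------------------------------------
# The genealogy is shared by all loci: a unit-height pure-birth (Yule) tree
# at each nesting level (families within the flora, genera within each
# family, species within each genus), realized per locus by mapping each
# level's splits into that locus's height band, plus conspecific stars
# (optionally substructured by plot).

# internal: unit-height ultrametric Yule topology over k labels
unit_yule <- function(labels) {
  k <- length(labels)
  if (k == 1L) return(NULL)
  phy <- ape::rphylo(k, birth = 1, death = 0)
  depth <- ape::node.depth.edgelength(phy)
  phy$edge.length <- phy$edge.length / max(depth)
  phy$tip.label <- sample(labels)  # random attachment of labels to tips
  phy
}

# internal: draw the genealogy shape for a taxonomy
genealogy_shape <- function(specimens) {
  fams <- sort(unique(specimens$family))
  shape <- list(
    family_tree = unit_yule(fams),
    genus_trees = list(), species_trees = list())
  for (fam in fams) {
    gens <- sort(unique(specimens$genus[specimens$family == fam]))
    shape$genus_trees[[fam]] <- unit_yule(gens)
    for (gen in gens) {
      sps <- sort(unique(specimens$species[specimens$genus == gen]))
      shape$species_trees[[gen]] <- unit_yule(sps)
    }
  }
  shape
}

# internal: newick fragment gluing child subtrees under a unit tree rescaled
# to crown height H; children is a named list of list(str, height).
glue_level <- function(children, unit_phy, H) {
  hts <- vapply(children, `[[`, 0, "height")
  if (any(hts >= H)) {
    abort_validation("level heights must nest (child crown below parent crown)")
  }
  if (length(children) == 1L) {
    ch <- children[[1]]
    return(list(str = sprintf("(%s:%.10g)", ch$str, H - ch$height), height = H))
  }
  # recovery may have emptied some children: prune the level tree to the
  # ones present (pruned crowns may coalesce below H, which is fine)
  if (length(children) < length(unit_phy$tip.label)) {
    unit_phy <- ape::keep.tip(unit_phy, names(children))
  }
  B <- max(hts)
  depth <- ape::node.depth.edgelength(unit_phy)
  unit_h <- max(depth) - depth  # node heights, tips ~0, root 1
  ntip <- length(unit_phy$tip.label)
  height_of <- function(node) {
    if (node <= ntip) children[[unit_phy$tip.label[node]]]$height
    else B + unit_h[node] * (H - B)
  }
  build <- function(node) {
    if (node <= ntip) return(children[[unit_phy$tip.label[node]]]$str)
    kids <- unit_phy$edge[unit_phy$edge[, 1] == node, 2]
    parts <- vapply(kids, function(k) {
      sprintf("%s:%.10g", build(k), height_of(node) - height_of(k))
    }, "")
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  root <- ntip + 1L
  list(str = build(root), height = H)
}

# internal: subtree for one species' specimens (star, optionally split by
# plot when plot_sep > intra)
species_subtree <- function(ids, plots, intra, plot_sep) {
  if (length(ids) == 1L) return(list(str = ids, height = 0))
  if (is.null(plot_sep) || plot_sep <= intra || length(unique(plots)) == 1L) {
    return(list(
      str = sprintf("(%s)", paste(sprintf("%s:%.10g", ids, intra), collapse = ",")),
      height = intra))
  }
  groups <- split(ids, plots)
  parts <- vapply(names(groups), function(p) {
    g <- groups[[p]]
    if (length(g) == 1L) {
      sprintf("%s:%.10g", g, plot_sep)
    } else {
      sprintf("(%s):%.10g",
              paste(sprintf("%s:%.10g", g, intra), collapse = ","),
              plot_sep - intra)
    }
  }, "")
  list(str = sprintf("(%s)", paste(parts, collapse = ",")), height = plot_sep)
}

# internal: realized specimen tree for one locus (or one family's subtree
# for a per-family locus). Returns an ape phylo.
realize_tree <- function(specimens, shape, inter, intra,
                         genus_crown_frac, species_crown_frac,
                         plot_sep = NULL, family = NULL) {
  sp_crown <- species_crown_frac * inter
  gen_crown <- genus_crown_frac * inter
  genus_node <- function(gen) {
    sps <- sort(unique(specimens$species[specimens$genus == gen]))
    kids <- lapply(sps, function(sp) {
      rows <- specimens[specimens$species == sp, , drop = FALSE]
      species_subtree(rows$sample_id, rows$plot, intra, plot_sep)
    })
    names(kids) <- sps
    glue_level(kids, shape$species_trees[[gen]], sp_crown)
  }
  family_node <- function(fam) {
    gens <- sort(unique(specimens$genus[specimens$family == fam]))
    kids <- lapply(gens, genus_node)
    names(kids) <- gens
    glue_level(kids, shape$genus_trees[[fam]], gen_crown)
  }
  top <- if (!is.null(family)) {
    family_node(family)
  } else {
    fams <- sort(unique(specimens$family))
    kids <- lapply(fams, family_node)
    names(kids) <- fams
    if (length(kids) == 1L) kids[[1]] else glue_level(kids, shape$family_tree, inter)
  }
  phy <- ape::read.tree(text = paste0(top$str, ";"))
  ape::collapse.singles(phy)
}

# internal: JC69 evolution of L sites along a phylo; returns a character
# matrix of tip sequences (rows = tips)
jc_evolve <- function(phy, L) {
  phy <- ape::reorder.phylo(phy, "cladewise")  # parents before children
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  seqs <- matrix(NA_integer_, nnode, L)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]; t <- phy$edge.length[e]
    child <- seqs[p, ]
    if (t > 0) {
      psub <- 0.75 * (1 - exp(-4 * t / 3))
      mut <- which(stats::runif(L) < psub)
      if (length(mut) > 0) {
        # jump uniformly to one of the three other bases
        child[mut] <- ((child[mut] - 1L + sample.int(3L, length(mut),
                                                     replace = TRUE)) %% 4L) + 1L
      }
    }
    seqs[ch, ] <- child
  }
  bases <- c("A", "C", "G", "T")
  out <- matrix(bases[seqs[seq_len(ntip), , drop = FALSE]], ntip, L)
  rownames(out) <- phy$tip.label
  out
}

#' Evolve one barcode locus over a synthetic taxonomy
#'
#' Sequences evolve under JC69 along a shared specimen genealogy: nested
#' height-banded pure-birth trees (family root height = `inter`, genus and
#' species crowns at the configured fractions) with conspecific star
#' genealogies of height `intra`, so the expected pairwise intraspecific
#' distance is about `2 * intra`. Specimens pass an independent Bernoulli
#' recovery draw; no indels are generated, so the data are born aligned.
#' Per-family loci are evolved independently within each family (each family
#' block has its own coordinate system).
#'
#' @param specimens specimen records (true taxonomy).
#' @param locus locus parameter list (see [sim_config()] `loci`).
#' @param shape genealogy shape from a previous call (internal reuse);
#'   drawn fresh when `NULL`.
#' @param cfg a [sim_config()] supplying crown fractions and plot
#'   separation; defaults used when `NULL`.
#' @param seed optional integer seed.
#' @return a [locus_alignment()], or a named list of per-family alignments
#'   when `locus$per_family` is `TRUE`. `NULL` if no specimen survives the
#'   recovery draw.
#' @export
evolve_locus <- function(specimens, locus, shape = NULL, cfg = NULL, seed = NULL) {
  cfg <- cfg %||% sim_config()
  with_seed_if(seed, {
    if (is.null(shape)) shape <- genealogy_shape(specimens)
    keep <- specimens$sample_id[stats::runif(nrow(specimens)) < locus$recovery]
    if (length(keep) == 0) return(NULL)
    sub <- specimens[specimens$sample_id %in% keep, , drop = FALSE]
    evolve_one <- function(spm, family = NULL) {
      if (nrow(spm) == 1L) {
        m <- matrix(sample(c("A", "C", "G", "T"), locus$length, replace = TRUE),
                    1, locus$length, dimnames = list(spm$sample_id, NULL))
      } else {
        phy <- realize_tree(spm, shape, locus$inter, locus$intra,
                            cfg$genus_crown_frac, cfg$species_crown_frac,
                            plot_sep = cfg$plot_sep_height, family = family)
        m <- jc_evolve(phy, locus$length)
      }
      locus_alignment(setNames(apply(m, 1, paste, collapse = ""), rownames(m)),
                      locus$name)
    }
    if (isTRUE(locus$per_family)) {
      fams <- sort(unique(sub$family))
      out <- lapply(fams, function(fam) {
        evolve_one(sub[sub$family == fam, , drop = FALSE], family = fam)
      })
      names(out) <- fams
      out
    } else {
      evolve_one(sub)
    }
  })
}

#' Inject field misidentification errors into specimen records
#'
#' Corrupts the recorded taxonomy of `round(rate * N)` specimens. The level
#' mix is apportioned deterministically (largest remainder), so e.g. a
#' 74:17:5 mix over 96 errors yields exactly 74/17/5. A family-level error
#' relabels a specimen with a species from a different family; genus-level:
#' a different genus of the same family; species-level: a different species
#' of the same genus. The true labels stay in the returned error list.
#'
#' @param specimens true specimen records.
#' @param rate fraction of specimens to corrupt.
#' @param mix named weights over `family`, `genus`, `species`.
#' @param seed optional integer seed.
#' @return list with `specimens` (corrupted records) and `errors`
#'   data.frame (`sample_id`, `level`, true and recorded triples).
#' @export
inject_misidentifications <- function(specimens, rate,
                                      mix = c(family = 74, genus = 17, species = 5),
                                      seed = NULL) {
  n <- nrow(specimens)
  n_err <- round(rate * n)
  empty <- data.frame(sample_id = character(0), level = character(0),
                      true_species = character(0), true_genus = character(0),
                      true_family = character(0), recorded_species = character(0),
                      recorded_genus = character(0), recorded_family = character(0),
                      stringsAsFactors = FALSE)
  if (rate == 0 || n_err == 0) {
    return(list(specimens = specimens, errors = empty))
  }
  mix <- mix[c("family", "genus", "species")]
  mix[is.na(mix)] <- 0
  p <- mix / sum(mix)
  counts <- floor(n_err * p)
  rem <- n_err - sum(counts)
  if (rem > 0) {
    frac <- n_err * p - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  sp_tab <- unique(specimens[c("species", "genus", "family")])
  with_seed_if(seed, {
    victims <- sample(specimens$sample_id, n)  # shuffled candidate order
    out <- specimens
    errors <- list()
    used <- character(0)
    for (level in c("family", "genus", "species")) {
      need <- counts[[level]]
      for (k in seq_len(need)) {
        placed <- FALSE
        for (v in setdiff(victims, used)) {
          row <- specimens[specimens$sample_id == v, ]
          donors <- switch(level,
            family = sp_tab[sp_tab$family != row$family, , drop = FALSE],
            genus = sp_tab[sp_tab$family == row$family &
                             sp_tab$genus != row$genus, , drop = FALSE],
            species = sp_tab[sp_tab$genus == row$genus &
                               sp_tab$species != row$species, , drop = FALSE])
          if (nrow(donors) == 0) next
          d <- donors[sample.int(nrow(donors), 1L), ]
          i <- which(out$sample_id == v)
          out$species[i] <- d$species; out$genus[i] <- d$genus
          out$family[i] <- d$family
          errors[[v]] <- data.frame(
            sample_id = v, level = level,
            true_species = row$species, true_genus = row$genus,
            true_family = row$family,
            recorded_species = d$species, recorded_genus = d$genus,
            recorded_family = d$family, stringsAsFactors = FALSE)
          used <- c(used, v)
          placed <- TRUE
          break
        }
        if (!placed) {
          abort_validation(sprintf(
            "cannot inject a %s-level error: no eligible specimen/donor", level))
        }
      }
    }
    errors <- rbind_rows(errors)
    list(specimens = out, errors = errors[order(errors$sample_id), , drop = FALSE])
  })
}

# internal: regroup per-family alignment blocks by (possibly corrupted)
# recorded family labels. A misidentified specimen's sequence lands in the
# block of its recorded family, exactly as a family-based alignment workflow
# would misfile it.
regroup_blocks <- function(per_family, fam_of, locus) {
  seqs <- unlist(lapply(per_family, `[[`, "seqs"))
  ids <- unlist(lapply(per_family, `[[`, "members"), use.names = FALSE)
  names(seqs) <- ids
  groups <- split(ids, fam_of[ids])
  out <- lapply(groups, function(g) locus_alignment(seqs[g], locus))
  out[order(names(out))]
}

#' Simulate a complete barcode dataset
#'
#' Draws a taxonomy, a shared genealogy, per-locus alignments with recovery
#' missingness, and (when `misid_rate > 0`) corrupted recorded labels. The
#' dataset carries the recorded (possibly corrupted) labels, as a field
#' campaign would; the ground truth travels alongside. Sequences always
#' evolve along the true genealogy; for per-family loci the blocks are
#' grouped by recorded family, so a misidentified specimen's sequence sits
#' in the wrong family's block (as it would after family-based alignment of
#' field-labeled material).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; the whole simulation is deterministic
#'   given the seed.
#' @return list with `dataset` (a `barcode_dataset` using recorded labels),
#'   `truth` (true specimen records) and `errors` (injected error list).
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  with_seed_if(seed, {
    truth <- generate_taxonomy(cfg)
    inj <- inject_misidentifications(truth, cfg$misid_rate, cfg$misid_mix)
    shape <- genealogy_shape(truth)
    fam_of <- setNames(inj$specimens$family, inj$specimens$sample_id)
    alignments <- list()
    for (locus in cfg$loci) {
      a <- evolve_locus(truth, locus, shape = shape, cfg = cfg)
      if (is.null(a)) next
      if (isTRUE(locus$per_family)) a <- regroup_blocks(a, fam_of, locus$name)
      alignments[[locus$name]] <- a
    }
    list(dataset = dataset(inj$specimens, alignments), truth = truth,
         errors = inj$errors)
  })
}

#' Write ground truth alongside a dataset directory
#' @param truth true specimen records.
#' @param errors injected-error data.frame.
#' @param dir dataset directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, errors, dir) {
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(errors, file.path(dir, "injected_errors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
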