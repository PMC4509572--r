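# Algorithmic first pass of the reciprocal-illumination audit: flag leaves
# whose placement on the core-barcode tree conflicts with their recorded
# taxonomy. (The second pass - herbarium voucher review - is human work and
# out of scope.)

# internal: all "clades" (bipartition sides) of an unrooted tree, as tip-name
# vectors per edge side, with the defining edge's support and whether the
# edge is pendant (pendant edges can never carry bootstrap support).
edge_sides <- function(phy) {
  ntip <- length(phy$tip.label)
  tips <- phy$tip.label
  nodes <- unique(phy$edge[, 2])
  desc <- phangorn::Descendants(phy, nodes, type = "tips")
  sup_lookup <- if (is.null(phy$node.label)) NULL else phy$node.label
  sides <- list()
  for (i in seq_along(nodes)) {
    child <- nodes[i]
    side <- tips[desc[[i]]]
    support <- if (child <= ntip || is.null(sup_lookup)) {
      NA_real_
    } else {
      as.numeric(sup_lookup[child - ntip])
    }
    sides[[i]] <- list(side = side, complement = setdiff(tips, side),
                       support = support, pendant = child <= ntip)
  }
  sides
}

# internal: gate contribution of one edge side. On a tree with bootstrap
# labels, pendant edges provide no support evidence (-Inf) and unlabeled
# internal edges are treated as satisfied (Inf); on a tree without any
# labels the gate is inactive (everything Inf).
gate_support <- function(e, labeled) {
  if (labeled && e$pendant) return(-Inf)
  if (is.na(e$support)) Inf else e$support
}

#' Flag specimens whose tree placement conflicts with recorded taxonomy
#'
#' A leaf is flagged when the smallest clade (bipartition side of the
#' unrooted tree) containing it and at least one other leaf contains no
#' recorded conspecific, and the separation from its recorded conspecifics
#' is supported: the gate is the maximum bootstrap support over edges whose
#' leaf-side excludes every recorded conspecific (for a leaf whose recorded
#' species has no other member, over edges grouping the leaf with the
#' single neighbouring species). Leaves of singleton recorded species are
#' flagged only when they nest with part of one other species, so a
#' singleton sitting as sister to a complete clade of another taxon is not
#' a conflict. The neighbourhood taxon is the majority species/genus/family
#' among the other leaves of the smallest enclosing clade (ties broken
#' lexicographically). On a bootstrapped tree, pendant edges carry no
#' support and never satisfy the gate; on a tree without support values the
#' gate is inactive. Note that both leaves of a recorded-conspecific-free
#' cherry can be flagged (either may be the mislabeled one); resolving which
#' is the second, human step of reciprocal illumination.
#'
#' @param tree `phylo` over specimens, typically with bootstrap
#'   `node.label` from [bootstrap_support()].
#' @param specimens specimen records covering every leaf.
#' @param min_support support gate percentage (default 50, matching the
#'   resolution cutoff).
#' @return data.frame ordered by `sample_id`: recorded and neighbourhood
#'   species/genus/family, `level` (`family`, `genus`, `species` or
#'   `unknown`) and `support` of the gating edge.
#' @export
flag_conflicts <- function(tree, specimens, min_support = 50) {
  tips <- tree$tip.label
  missing <- setdiff(tips, specimens$sample_id)
  if (length(missing) > 0) {
    abort_validation(sprintf("unlabeled leaves: %s", paste(missing, collapse = ", ")))
  }
  sp_of <- setNames(specimens$species, specimens$sample_id)
  gen_of <- setNames(specimens$genus, specimens$sample_id)
  fam_of <- setNames(specimens$family, specimens$sample_id)
  sides <- edge_sides(tree)
  flags <- list()
  for (x in tips) {
    x_sides <- lapply(sides, function(e) {
      side <- if (x %in% e$side) e$side else e$complement
      list(side = side, support = e$support, pendant = e$pendant)
    })
    x_sides <- Filter(function(e) length(e$side) >= 2 && length(e$side) < length(tips),
                      x_sides)
    if (length(x_sides) == 0) next
    sizes <- vapply(x_sides, function(e) length(e$side), 0L)
    minimal <- x_sides[sizes == min(sizes)]
    if (length(minimal) > 1) {
      keys <- vapply(minimal, function(e) paste(sort(e$side), collapse = "\r"), "")
      minimal <- minimal[order(keys)]
    }
    clade <- minimal[[1]]$side
    others <- setdiff(clade, x)
    M <- setdiff(names(sp_of)[sp_of == sp_of[[x]]], x)
    M <- intersect(M, tips)
    if (any(others %in% M)) next
    majority <- function(v) {
      tab <- sort(table(v), decreasing = TRUE)
      names(tab)[tab == max(tab)][order(names(tab)[tab == max(tab)])][1]
    }
    nb_species <- majority(sp_of[others])
    nb_genus <- majority(gen_of[others])
    nb_family <- majority(fam_of[others])
    labeled <- !is.null(tree$node.label)
    if (length(M) > 0) {
      # supported separation of x from all its recorded conspecifics
      gate <- vapply(x_sides, function(e) {
        if (any(M %in% e$side)) return(-Inf)
        gate_support(e, labeled)
      }, 0)
    } else {
      # singleton recorded species: flagged only when nesting with part of
      # one other species (sister to that species' complete clade is not a
      # conflict)
      if (length(unique(sp_of[others])) != 1L) next
      nb_members <- intersect(names(sp_of)[sp_of == nb_species], tips)
      if (length(others) >= length(nb_members)) next
      gate <- vapply(x_sides, function(e) {
        oth <- setdiff(e$side, x)
        if (length(oth) == 0 || !all(oth %in% nb_members)) return(-Inf)
        gate_support(e, labeled)
      }, 0)
    }
    best_gate <- max(gate)
    if (best_gate < min_support) next
    rec <- list(species = sp_of[[x]], genus = gen_of[[x]], family = fam_of[[x]])
    level <- classify_level(rec,
                            list(species = nb_species, genus = nb_genus,
                                 family = nb_family))
    flags[[x]] <- data.frame(
      sample_id = x,
      recorded_species = rec$species, recorded_genus = rec$genus,
      recorded_family = rec$family,
      neighborhood_species = nb_species, neighborhood_genus = nb_genus,
      neighborhood_family = nb_family,
      level = level,
      support = if (is.finite(best_gate)) best_gate else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(flags)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), recorded_species = character(0),
                      recorded_genus = character(0), recorded_family = character(0),
                      neighborhood_species = character(0),
                      neighborhood_genus = character(0),
                      neighborhood_family = character(0), level = character(0),
                      support = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(out$sample_id), , drop = FALSE]
}

#' Conflict level from recorded vs neighbourhood taxonomy
#'
#' The level is the shallowest rank of disagreement: `family` if the
#' families differ, else `genus` if the genera differ, else `species`.
#' Records with placeholder taxonomy (`species == "unknown"`) are classified
#' `unknown`. Pure function of the two taxonomy triples.
#'
#' @param recorded,neighborhood lists (or one-row data.frames) with
#'   `species`, `genus`, `family`.
#' @return one of `"family"`, `"genus"`, `"species"`, `"unknown"`.
#' @export
classify_level <- function(recorded, neighborhood) {
  if (recorded$species == "unknown") return("unknown")
  if (recorded$family != neighborhood$family) return("family")
  if (recorded$genus != neighborhood$genus) return("genus")
  "species"
}

#' Summarize an audit
#'
#' @param flags data.frame from [flag_conflicts()].
#' @param n_audited number of specimens audited (>= 1).
#' @param exclude_unknowns when `TRUE`, per-level shares are computed over
#'   flagged samples excluding `unknown`-level flags (both conventions are
#'   seen in published accounts of the same audit, which is why the
#'   denominator is explicit).
#' @return list with `n_flagged`, `n_audited`, `rate_pct` (half-up, one
#'   decimal) and `levels` data.frame (`level`, `n`, `share_pct`).
#' @export
audit_summary <- function(flags, n_audited, exclude_unknowns = FALSE) {
  if (n_audited < 1) abort_validation("n_audited must be >= 1")
  n_flagged <- nrow(flags)
  lev <- factor(flags$level, levels = c("family", "genus", "species", "unknown"))
  counts <- table(lev)
  den <- if (exclude_unknowns) n_flagged - counts[["unknown"]] else n_flagged
  levels_df <- data.frame(
    level = names(counts), n = as.integer(counts),
    share_pct = if (n_flagged > 0 && den > 0) {
      percent(as.integer(counts), den)
    } else {
      rep(NA_real_, length(counts))
    },
    stringsAsFactors = FALSE)
  if (exclude_unknowns) {
    levels_df$share_pct[levels_df$level == "unknown"] <- NA_real_
  }
  list(n_flagged = n_flagged, n_audited = n_audited,
       rate_pct = percent(n_flagged, n_audited), levels = levels_df)
}
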