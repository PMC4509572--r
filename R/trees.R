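# Distance computation, Neighbor-Joining, nonparametric bootstrap support.
#
# Site counting is done once per alignment via 0/1 indicator matrices (one
# per base); all pairwise counts (comparable sites, matches, transitions,
# transversions) are then dense matrix cross-products, which keeps the
# bootstrap loop in BLAS rather than R.

# internal: indicator encoding of an alignment
encode_alignment <- function(aln) {
  m <- aln_matrix(aln)
  list(A = (m == "A") * 1, C = (m == "C") * 1,
       G = (m == "G") * 1, T = (m == "T") * 1,
       members = aln$members, length = aln$length)
}

# internal: pairwise site counts, optionally on a column subset (cols may
# contain duplicates, as in bootstrap resampling)
pair_counts <- function(enc, cols = NULL) {
  A <- enc$A; C <- enc$C; G <- enc$G; T <- enc$T
  if (!is.null(cols)) {
    A <- A[, cols, drop = FALSE]; C <- C[, cols, drop = FALSE]
    G <- G[, cols, drop = FALSE]; T <- T[, cols, drop = FALSE]
  }
  V <- A + C + G + T
  comparable <- tcrossprod(V)
  matches <- tcrossprod(A) + tcrossprod(C) + tcrossprod(G) + tcrossprod(T)
  transitions <- tcrossprod(A, G) + tcrossprod(G, A) +
    tcrossprod(C, T) + tcrossprod(T, C)
  mismatches <- comparable - matches
  dimnames(comparable) <- dimnames(matches) <- dimnames(transitions) <-
    dimnames(mismatches) <- list(enc$members, enc$members)
  list(comparable = comparable, matches = matches, mismatches = mismatches,
       transitions = transitions, transversions = mismatches - transitions)
}

# internal: distance matrix object from counts
dist_from_counts <- function(pc, model) {
  n <- nrow(pc$comparable)
  undefined <- pc$comparable == 0
  saturated <- matrix(FALSE, n, n, dimnames = dimnames(pc$comparable))
  if (model == "p") {
    values <- pc$mismatches / pc$comparable
  } else {
    P <- pc$transitions / pc$comparable
    Q <- pc$transversions / pc$comparable
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    saturated <- !undefined & (a1 <= 0 | a2 <= 0)
    a1[a1 <= 0 | is.na(a1)] <- 1  # masked below; avoids log-domain warnings
    a2[a2 <= 0 | is.na(a2)] <- 1
    values <- -0.5 * log(a1) - 0.25 * log(a2)
    values[saturated] <- NA_real_
  }
  values[undefined] <- NA_real_
  diag(values) <- 0
  diag(undefined) <- FALSE
  structure(list(members = rownames(pc$comparable), values = values,
                 comparable_sites = pc$comparable, undefined = undefined,
                 saturated = saturated, model = model),
            class = "distance_matrix")
}

#' Uncorrected p-distance with pairwise deletion
#'
#' For each pair, distance = mismatches / comparable sites, a site being
#' comparable iff both characters are in `{A,C,G,T}` (gaps and `N` are
#' deleted pairwise). A pair with zero comparable sites is undefined (`NA`
#' value, flagged in `$undefined`), never silently 0.
#'
#' @param aln a `locus_alignment` or `supermatrix`.
#' @return object of class `distance_matrix` with fields `members`,
#'   `values`, `comparable_sites`, `undefined`, `saturated`, `model`.
#' @export
p_distance <- function(aln) {
  if (length(aln$members) < 2) abort_validation("need >= 2 members")
  dist_from_counts(pair_counts(encode_alignment(aln)), "p")
}

#' Kimura two-parameter distance with pairwise deletion
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with transition and
#' transversion proportions P and Q over comparable sites. Pairs whose log
#' arguments are not positive are flagged as saturated (`NA` value).
#'
#' @inheritParams p_distance
#' @return a `distance_matrix` (see [p_distance()]).
#' @export
k2p_distance <- function(aln) {
  if (length(aln$members) < 2) abort_validation("need >= 2 members")
  dist_from_counts(pair_counts(encode_alignment(aln)), "k2p")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s, %d members, %d undefined pair(s)\n",
              x$model, length(x$members), sum(x$undefined) / 2))
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param D a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- as.data.frame(D$values)
  df <- cbind(sample_id = D$members, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-Joining tree
#'
#' Classic Saitou-Nei agglomeration (via \pkg{ape}'s implementation) on a
#' pairwise-deletion distance matrix. Negative branch lengths are clamped to
#' zero with the remainder transferred to an adjacent sibling edge
#' (Kuhner-Felsenstein convention); downstream code uses topology and
#' support only. Undefined pairs must be resolved by the caller first (see
#' [drop_undefined_members()]).
#'
#' @param D a `distance_matrix`.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (length(D$members) < 3) abort_validation("need >= 3 members for NJ")
  if (any(D$undefined | D$saturated)) {
    bad <- which(D$undefined | D$saturated, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    abort_validation(sprintf(
      "undefined/saturated distance(s), e.g. %s vs %s; filter members or add loci",
      D$members[bad[1, 1]], D$members[bad[1, 2]]))
  }
  phy <- ape::nj(D$values)
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    len <- phy$edge.length[e]
    sib <- setdiff(which(phy$edge[, 1] == phy$edge[e, 1]), e)
    if (length(sib) > 0) {
      phy$edge.length[sib[1]] <- phy$edge.length[sib[1]] + len
    }
    phy$edge.length[e] <- 0
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Drop members involved in undefined or saturated pairs
#'
#' Greedily removes the member participating in the most undefined pairs
#' until none remain (ties broken by member name), so NJ can run on the
#' remainder. Returns the reduced matrix with the dropped ids in
#' `attr(, "dropped")`.
#'
#' @param D a `distance_matrix`.
#' @return a `distance_matrix` without undefined pairs.
#' @export
drop_undefined_members <- function(D) {
  bad <- D$undefined | D$saturated
  dropped <- character(0)
  while (any(bad)) {
    deg <- rowSums(bad)
    worst <- names(sort(deg[deg == max(deg)]))[1]
    keep <- setdiff(rownames(bad), worst)
    dropped <- c(dropped, worst)
    bad <- bad[keep, keep, drop = FALSE]
    D$values <- D$values[keep, keep, drop = FALSE]
    D$comparable_sites <- D$comparable_sites[keep, keep, drop = FALSE]
    D$undefined <- D$undefined[keep, keep, drop = FALSE]
    D$saturated <- D$saturated[keep, keep, drop = FALSE]
    D$members <- keep
  }
  attr(D, "dropped") <- dropped
  D
}

# internal: canonical key for the bipartition defined by a tip set.
# The key is the side NOT containing the reference tip (the lexicographically
# smallest leaf label), so both orientations of a split map to one key.
split_key <- function(side, all_tips, ref = min(all_tips)) {
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "\r")
}

# internal: non-trivial splits of an unrooted tree.
# Returns a named character vector: names = internal node ids (as character),
# values = canonical keys. Pendant edges and the root node are excluded.
tree_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  all_tips <- phy$tip.label
  ref <- min(all_tips)
  internal <- setdiff(unique(phy$edge[, 2]), seq_len(ntip))
  if (length(internal) == 0) return(setNames(character(0), character(0)))
  desc <- phangorn::Descendants(phy, internal, type = "tips")
  keys <- vapply(desc, function(idx) {
    side <- all_tips[idx]
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    split_key(side, all_tips, ref)
  }, "")
  keys <- setNames(keys, as.character(internal))
  keys[!is.na(keys)]
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Columns are resampled with replacement (independently within each
#' partition when a partition map is supplied, preserving family-block
#' structure), the distance matrix and NJ tree are rebuilt per replicate,
#' and each internal edge of the original tree receives the percentage of
#' replicate trees containing the same bipartition. Replicates in which a
#' pair loses all comparable sites are redrawn (counted in
#' `attr(, "redraws")`). Support is attached to the original tree's
#' bipartitions; no consensus topology is substituted.
#'
#' @param aln alignment or supermatrix the base tree was built from.
#' @param base_tree the NJ tree from [neighbor_joining()] on `aln`.
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed optional integer seed.
#' @param model `"k2p"` (default) or `"p"`.
#' @param partitions optional partition data.frame (`label`, `start`, `end`,
#'   0-based half-open), e.g. `sm$partitions`.
#' @param max_redraws cap on redraws per replicate before giving up on the
#'   undefined pair (the offending members are then dropped for that
#'   replicate).
#' @return `base_tree` with `node.label` set to support percentages in
#'   `[0, 100]` (root label `NA`).
#' @export
bootstrap_support <- function(aln, base_tree, replicates = 1000, seed = NULL,
                              model = c("k2p", "p"), partitions = NULL,
                              max_redraws = 100) {
  model <- match.arg(model)
  if (replicates < 1) abort_validation("replicates must be >= 1")
  enc <- encode_alignment(aln)
  if (is.null(partitions) && !is.null(aln$partitions)) partitions <- aln$partitions
  blocks <- if (is.null(partitions)) {
    list(seq_len(enc$length))
  } else {
    lapply(seq_len(nrow(partitions)),
           function(i) (partitions$start[i] + 1L):partitions$end[i])
  }
  base_keys <- tree_splits(base_tree)
  counts <- setNames(numeric(length(base_keys)), base_keys)
  redraws <- 0L
  with_seed_if(seed, {
    for (b in seq_len(replicates)) {
      for (attempt in seq_len(max_redraws + 1L)) {
        cols <- unlist(lapply(blocks, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
        pc <- pair_counts(enc, cols)
        D <- dist_from_counts(pc, model)
        ok <- !any(D$undefined | D$saturated)
        if (ok) break
        redraws <- redraws + 1L
      }
      if (!ok) D <- drop_undefined_members(D)
      if (length(D$members) < 4) next
      rep_tree <- neighbor_joining(D)
      rk <- tree_splits(rep_tree)
      hit <- base_keys[base_keys %in% rk]
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / replicates
  ntip <- length(base_tree$tip.label)
  labels <- rep(NA_real_, base_tree$Nnode)
  node_of_key <- as.integer(names(base_keys))
  labels[node_of_key - ntip] <- support[base_keys]
  base_tree$node.label <- labels
  attr(base_tree, "redraws") <- redraws
  base_tree
}

# internal: named support lookup (split key -> support) from a tree whose
# node.label holds bootstrap percentages
support_by_split <- function(phy) {
  keys <- tree_splits(phy)
  ntip <- length(phy$tip.label)
  sup <- phy$node.label[as.integer(names(keys)) - ntip]
  setNames(as.numeric(sup), keys)
}

#' Write a support tree as Newick with support as internal node labels
#' @param phy a `phylo` with numeric `node.label` support values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(phy, path) {
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Per-species intraspecific variable-site tally
#'
#' For every species with at least two sequences at the locus, flags each
#' alignment column where two or more unambiguous states occur among
#' conspecific sequences, and classifies the variable site as within-plot
#' (some single plot already shows two states) or between-plot (each plot is
#' internally uniform, so the variation only appears across plots).
#'
#' @param ds a `barcode_dataset`.
#' @param locus locus name.
#' @return list with `per_species` summary data.frame (species, n_seqs,
#'   n_variable_sites, n_within_plot, n_between_plot) and `per_site` detail
#'   data.frame (species, site, n_states, type).
#' @export
intraspecific_variation <- function(ds, locus) {
  aln <- flat_alignment(ds, locus)
  m <- aln_matrix(aln)
  plot_of <- setNames(ds$specimens$plot, ds$specimens$sample_id)
  sp_of <- setNames(ds$specimens$species, ds$specimens$sample_id)
  species <- sort(unique(sp_of[aln$members]))
  per_species <- list()
  per_site <- list()
  for (sp in species) {
    ids <- aln$members[sp_of[aln$members] == sp]
    if (length(ids) < 2) next
    sub <- m[ids, , drop = FALSE]
    sub[!(sub %in% c("A", "C", "G", "T"))] <- NA
    n_states <- apply(sub, 2, function(col) length(unique(col[!is.na(col)])))
    var_sites <- which(n_states >= 2)
    type <- character(0)
    if (length(var_sites) > 0) {
      plots <- plot_of[ids]
      type <- vapply(var_sites, function(j) {
        col <- sub[, j]
        within <- any(vapply(split(col, plots), function(v) {
          length(unique(v[!is.na(v)])) >= 2
        }, TRUE))
        if (within) "within_plot" else "between_plot"
      }, "")
      per_site[[sp]] <- data.frame(
        species = sp, site = var_sites, n_states = n_states[var_sites],
        type = type, stringsAsFactors = FALSE)
    }
    per_species[[sp]] <- data.frame(
      species = sp, n_seqs = length(ids), n_variable_sites = length(var_sites),
      n_within_plot = sum(type == "within_plot"),
      n_between_plot = sum(type == "between_plot"),
      stringsAsFactors = FALSE)
  }
  list(per_species = rbind_rows(per_species) %||%
         data.frame(species = character(0), n_seqs = integer(0),
                    n_variable_sites = integer(0), n_within_plot = integer(0),
                    n_between_plot = integer(0)),
       per_site = rbind_rows(per_site) %||% {
         data.frame(species = character(0), site = integer(0),
                    n_states = integer(0), type = character(0))
       })
}
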