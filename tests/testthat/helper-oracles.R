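# Independent oracles: brute-force/enumerative reimplementations used to
# cross-check the package's efficient code paths. They deliberately share no
# tree/identity machinery with the implementation (adjacency BFS instead of
# descendant tables, per-character loops instead of matrix cross-products,
# exhaustive enumeration instead of dynamic programming).

# ---- tree utilities (adjacency-based, independent of phangorn) -------------

# tip labels on each side of every edge, found by BFS after deleting the edge
oracle_edge_sides <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lapply(seq_len(nrow(phy$edge)), function(e) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    # BFS from b without crossing the deleted edge (a, b)
    seen <- rep(FALSE, nn); seen[b] <- TRUE; queue <- b
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (v == b) nb <- setdiff(nb, a)
      if (v == a) nb <- setdiff(nb, b)
      for (w in nb) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    side_b <- phy$tip.label[which(seen[seq_len(ntip)])]
    list(side = side_b, complement = setdiff(phy$tip.label, side_b),
         child = phy$edge[e, 2])
  })
}

# least-squares branch-length fit residual of a distance matrix on a topology
oracle_ls_residual <- function(phy, D) {
  tips <- rownames(D)
  sides <- oracle_edge_sides(phy)
  pairs <- utils::combn(tips, 2, simplify = FALSE)
  A <- sapply(sides, function(e) {
    vapply(pairs, function(pr) {
      as.numeric(xor(pr[1] %in% e$side, pr[2] %in% e$side))
    }, 0)
  })
  d <- vapply(pairs, function(pr) D[pr[1], pr[2]], 0)
  beta <- qr.coef(qr(A), d)
  beta[is.na(beta)] <- 0
  sum((A %*% beta - d)^2)
}

# exhaustive search: the unrooted topology with minimal least-squares residual
oracle_best_topology <- function(D) {
  tips <- rownames(D)
  cands <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  resid <- vapply(cands, oracle_ls_residual, 0, D = D)
  cands[[which.min(resid)]]
}

# ---- identity / assignment -------------------------------------------------

# per-character aligned identity, independent of the indicator-matrix path
oracle_identity <- function(q, s) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  ok <- qc %in% c("A", "C", "G", "T") & sc %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(qc[ok] == sc[ok]) / sum(ok)
}

# literal statement of the >=95 % / strict-dominance rule for one query
oracle_assign <- function(query_seq, db_seqs, db_units, truth, threshold,
                          db_groups = db_units) {
  ids <- vapply(db_seqs, oracle_identity, 0, q = query_seq)
  keep <- !is.na(ids)
  if (!any(keep)) return("unscorable")
  ids <- ids[keep]; db_units <- db_units[keep]; db_groups <- db_groups[keep]
  if (!any(db_groups == truth) || max(ids[db_groups == truth]) < threshold) {
    return("no_assignment")
  }
  best <- max(ids)
  winners <- which(ids == best)
  if (length(unique(db_groups[winners])) > 1) return("incorrect")
  G <- db_groups[winners[1]]
  outside <- ids[db_groups != G]
  ok <- FALSE
  for (B in unique(db_units[winners])) {
    if (length(outside) == 0 || min(ids[db_units == B]) > max(outside)) ok <- TRUE
  }
  if (!ok) return("incorrect")
  if (G == truth) "correct" else "incorrect"
}

# ---- free-end-gap alignment: exhaustive enumeration ------------------------

# all strict global alignments of q vs s (gap always penalized), as tuples
# (score, matches, columns)
oracle_all_alignments <- function(qc, sc, match = 1, mismatch = -1, gap = -2) {
  recurse <- function(i, j) {
    if (i > length(qc) && j > length(sc)) {
      return(list(c(0, 0, 0)))
    }
    out <- list()
    if (i <= length(qc) && j <= length(sc)) {
      eq <- qc[i] == sc[j] && qc[i] %in% c("A", "C", "G", "T")
      for (t in recurse(i + 1, j + 1)) {
        out[[length(out) + 1]] <- t + c(if (eq) match else mismatch,
                                        as.numeric(eq), 1)
      }
    }
    if (i <= length(qc)) {
      for (t in recurse(i + 1, j)) {
        out[[length(out) + 1]] <- t + c(gap, 0, 1)
      }
    }
    if (j <= length(sc)) {
      for (t in recurse(i, j + 1)) {
        out[[length(out) + 1]] <- t + c(gap, 0, 1)
      }
    }
    out
  }
  recurse(1, 1)
}

# best free-end-gap alignment by exhausting all (prefix skip, suffix skip)
# combinations (each end's free run lies in a single sequence) and all strict
# alignments of the remaining cores; lexicographic (score, matches, -cols)
oracle_free_end <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  lead <- c(lapply(0:m, function(a) c(a, 0)), lapply(seq_len(n), function(b) c(0, b)))
  tail <- c(lapply(0:m, function(cc) c(cc, 0)), lapply(seq_len(n), function(d) c(0, d)))
  best <- c(-Inf, -1, Inf)
  for (L in lead) {
    for (Tl in tail) {
      if (L[1] + Tl[1] > m || L[2] + Tl[2] > n) next
      core_q <- if (L[1] + 1 <= m - Tl[1]) qc[(L[1] + 1):(m - Tl[1])] else character(0)
      core_s <- if (L[2] + 1 <= n - Tl[2]) sc[(L[2] + 1):(n - Tl[2])] else character(0)
      for (t in oracle_all_alignments(core_q, core_s, match, mismatch, gap)) {
        cand <- c(t[1], t[2], t[3])
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && (cand[2] > best[2] ||
                                    (cand[2] == best[2] && cand[3] < best[3])))) {
          best <- cand
        }
      }
    }
  }
  list(score = best[1], matches = best[2], cols = best[3],
       identity = if (best[3] > 0) best[2] / best[3] else NA_real_)
}

# ---- conflict flags: clade enumeration oracle ------------------------------

oracle_flags <- function(tree, specimens, min_support = 50) {
  tips <- tree$tip.label
  sp <- setNames(specimens$species, specimens$sample_id)
  sides <- oracle_edge_sides(tree)
  ntip <- length(tips)
  labeled <- !is.null(tree$node.label)
  gate_of <- function(e) {
    if (labeled && e$child <= ntip) return(-Inf)  # pendant edge, no support
    if (!labeled || e$child <= ntip) return(Inf)
    s <- as.numeric(tree$node.label[e$child - ntip])
    if (is.na(s)) Inf else s
  }
  flagged <- character(0)
  for (x in tips) {
    cl <- list(); cgate <- numeric(0)
    for (e in sides) {
      side <- if (x %in% e$side) e$side else e$complement
      if (length(side) >= 2 && length(side) < ntip) {
        cl[[length(cl) + 1]] <- side
        cgate <- c(cgate, gate_of(e))
      }
    }
    if (length(cl) == 0) next
    sz <- vapply(cl, length, 0L)
    ix <- which(sz == min(sz))
    ix <- ix[order(vapply(cl[ix], function(v) paste(sort(v), collapse = "|"), ""))][1]
    smallest <- cl[[ix]]
    others <- setdiff(smallest, x)
    consp <- setdiff(intersect(tips, names(sp)[sp == sp[[x]]]), x)
    if (any(others %in% consp)) next
    maj <- function(v) {
      tb <- table(v); mx <- names(tb)[tb == max(tb)]; sort(mx)[1]
    }
    if (length(consp) > 0) {
      gate <- -Inf
      for (k in seq_along(cl)) {
        if (!any(consp %in% cl[[k]])) gate <- max(gate, cgate[k])
      }
    } else {
      if (length(unique(sp[others])) != 1) next
      nbm <- setdiff(intersect(tips, names(sp)[sp == maj(sp[others])]), x)
      if (length(others) >= length(nbm)) next  # sister to the complete clade
      gate <- -Inf
      for (k in seq_along(cl)) {
        oth <- setdiff(cl[[k]], x)
        if (length(oth) > 0 && all(oth %in% nbm)) gate <- max(gate, cgate[k])
      }
    }
    if (gate >= min_support) flagged <- c(flagged, x)
  }
  sort(flagged)
}
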