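#' Monophyly status of taxa on a support tree
#'
#' A taxon whose leaf set S satisfies `2 <= |S| < n` is monophyletic iff the
#' bipartition `S | complement` exists in the unrooted tree, and supported
#' iff that edge's bootstrap support meets the cutoff. A taxon comprising
#' every leaf of the tree is monophyletic with support treated as satisfied
#' (no separating edge exists). Taxa with a single sampled leaf are
#' excluded (`excluded_singleton`), mirroring the "samples >= 2" accounting
#' convention. The same function scores genus or family discrimination by
#' passing genus or family labels.
#'
#' @param tree `phylo` with bootstrap percentages in `node.label` (see
#'   [bootstrap_support()]); trees without node labels are treated as having
#'   full support.
#' @param labels named character vector: `sample_id` -> taxon name at the
#'   rank being scored; every leaf must be labeled.
#' @param cutoff support percentage defining "successful" resolution
#'   (default 50).
#' @return data.frame with columns `taxon`, `n_leaves`, `status`
#'   (`supported_monophyletic`, `unsupported_monophyletic`,
#'   `non_monophyletic`, `excluded_singleton`) and `support` (`NA` when no
#'   separating edge exists or the taxon is not monophyletic).
#' @export
monophyly_status <- function(tree, labels, cutoff = 50) {
  tips <- tree$tip.label
  unlabeled <- setdiff(tips, names(labels))
  if (length(unlabeled) > 0) {
    abort_validation(sprintf("unlabeled leaves: %s",
                             paste(unlabeled, collapse = ", ")))
  }
  n <- length(tips)
  ref <- min(tips)
  keys <- tree_splits(tree)
  sup <- if (is.null(tree$node.label)) {
    setNames(rep(100, length(keys)), keys)
  } else {
    support_by_split(tree)
  }
  taxa <- sort(unique(labels[tips]))
  out <- lapply(taxa, function(tx) {
    S <- tips[labels[tips] == tx]
    if (length(S) < 2) {
      return(data.frame(taxon = tx, n_leaves = length(S),
                        status = "excluded_singleton", support = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (length(S) == n) {
      return(data.frame(taxon = tx, n_leaves = n,
                        status = "supported_monophyletic", support = NA_real_,
                        stringsAsFactors = FALSE))
    }
    if (length(S) == n - 1) {
      # complement is a single leaf: the pendant edge always defines this
      # split, so the taxon is monophyletic; a pendant edge carries no
      # bootstrap support, so support is treated as satisfied.
      return(data.frame(taxon = tx, n_leaves = length(S),
                        status = "supported_monophyletic", support = NA_real_,
                        stringsAsFactors = FALSE))
    }
    key <- split_key(S, tips, ref)
    if (!(key %in% names(sup))) {
      return(data.frame(taxon = tx, n_leaves = length(S),
                        status = "non_monophyletic", support = NA_real_,
                        stringsAsFactors = FALSE))
    }
    s <- unname(sup[key])
    status <- if (is.na(s) || s >= cutoff) {
      # NA here means the split exists but has no attached support value
      # (e.g. no bootstrap was run); treated as satisfied
      "supported_monophyletic"
    } else {
      "unsupported_monophyletic"
    }
    data.frame(taxon = tx, n_leaves = length(S), status = status, support = s,
               stringsAsFactors = FALSE)
  })
  rbind_rows(out)
}

#' Resolution rate from monophyly statuses
#'
#' Rate = supported monophyletic taxa / taxa with >= 2 sampled leaves, as a
#' percentage rounded half-up to one decimal.
#'
#' @param statuses output of [monophyly_status()].
#' @param label combination/locus label to attach (e.g. `"rbcL+matK"`).
#' @param rank rank label (`"species"`, `"genus"`, `"family"`).
#' @return one-row data.frame: `label`, `rank`, `eligible`, `supported`,
#'   `rate`.
#' @export
resolution_rates <- function(statuses, label = "", rank = "species") {
  eligible <- sum(statuses$status != "excluded_singleton")
  if (eligible == 0) abort_validation("no taxa with >= 2 sampled leaves")
  supported <- sum(statuses$status == "supported_monophyletic")
  data.frame(label = label, rank = rank, eligible = eligible,
             supported = supported, rate = percent(supported, eligible),
             stringsAsFactors = FALSE)
}

#' Score species, genus and family resolution for one tree
#'
#' Convenience wrapper running [monophyly_status()] at the three ranks with
#' labels taken from the specimen table.
#'
#' @param tree support tree over specimens.
#' @param specimens specimen records.
#' @param label combination label for the report rows.
#' @param cutoff support cutoff (default 50).
#' @return data.frame with one row per rank (see [resolution_rates()]).
#' @export
resolution_report <- function(tree, specimens, label = "", cutoff = 50) {
  ranks <- c(species = "species", genus = "genus", family = "family")
  out <- lapply(names(ranks), function(rk) {
    labels <- setNames(specimens[[rk]], specimens$sample_id)
    st <- monophyly_status(tree, labels, cutoff = cutoff)
    resolution_rates(st, label = label, rank = rk)
  })
  rbind_rows(out)
}
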