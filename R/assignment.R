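# Similarity-based identification: pairwise identity, the >=95 %-identity
# plus conspecific-dominance decision rule, leave-one-out and cross-plot
# reference-database evaluation.

#' Pairwise sequence identity
#'
#' `aligned` mode scores the columns where both sequences have an
#' unambiguous base (`A,C,G,T`); identity = identical columns / scored
#' columns. `free_end_global` mode computes a best-scoring global alignment
#' with free terminal gaps (match +1, mismatch -1, gap -2) and scores
#' identity over the aligned region (terminal-gap columns excluded; internal
#' gap columns count in the denominator). Among equal-score alignments the
#' one maximizing matches, then minimizing aligned columns, is reported, so
#' the result is deterministic.
#'
#' @param query,subject character strings (equal length in `aligned` mode).
#' @param mode `"aligned"` or `"free_end_global"`.
#' @return list with `identity` (fraction, `NA` if unscorable),
#'   `scored_sites`, `unscorable` flag and, in `free_end_global` mode,
#'   `score`.
#' @export
pairwise_identity <- function(query, subject, mode = c("aligned", "free_end_global")) {
  mode <- match.arg(mode)
  if (!nzchar(query) || !nzchar(subject)) abort_validation("empty sequence")
  q <- strsplit(toupper(query), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  if (mode == "aligned") {
    if (length(q) != length(s)) {
      abort_validation("aligned mode requires equal-length sequences")
    }
    both <- q %in% c("A", "C", "G", "T") & s %in% c("A", "C", "G", "T")
    n <- sum(both)
    if (n == 0) {
      return(list(identity = NA_real_, scored_sites = 0L, unscorable = TRUE))
    }
    return(list(identity = sum(q[both] == s[both]) / n, scored_sites = n,
                unscorable = FALSE))
  }
  free_end_identity(q, s)
}

# internal: overlap (free-end-gap) alignment by dynamic programming.
# Cell value is the lexicographically best (score, matches, -columns) tuple;
# leading gaps are free via zero first row/column, trailing gaps free via
# maximising over the last row/column.
free_end_identity <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  m <- length(q); n <- length(s)
  S <- matrix(0, m + 1, n + 1)   # score
  M <- matrix(0L, m + 1, n + 1)  # matches on best path
  K <- matrix(0L, m + 1, n + 1)  # aligned columns on best path
  better <- function(s1, m1, k1, s2, m2, k2) {
    s1 > s2 || (s1 == s2 && (m1 > m2 || (m1 == m2 && k1 < k2)))
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      eq <- q[i] == s[j] && q[i] %in% c("A", "C", "G", "T")
      ds <- S[i, j] + if (eq) match else mismatch
      dm <- M[i, j] + as.integer(eq)
      dk <- K[i, j] + 1L
      us <- S[i, j + 1] + gap; um <- M[i, j + 1]; uk <- K[i, j + 1] + 1L
      ls <- S[i + 1, j] + gap; lm <- M[i + 1, j]; lk <- K[i + 1, j] + 1L
      bs <- ds; bm <- dm; bk <- dk
      if (better(us, um, uk, bs, bm, bk)) { bs <- us; bm <- um; bk <- uk }
      if (better(ls, lm, lk, bs, bm, bk)) { bs <- ls; bm <- lm; bk <- lk }
      S[i + 1, j + 1] <- bs; M[i + 1, j + 1] <- bm; K[i + 1, j + 1] <- bk
    }
  }
  best <- c(-Inf, -1L, .Machine$integer.max)
  consider <- function(i, j) {
    if (better(S[i, j], M[i, j], K[i, j], best[1], best[2], best[3])) {
      best <<- c(S[i, j], M[i, j], K[i, j])
    }
  }
  for (j in seq_len(n + 1)) consider(m + 1, j)
  for (i in seq_len(m + 1)) consider(i, n + 1)
  if (best[3] == 0) {
    return(list(identity = NA_real_, scored_sites = 0L, unscorable = TRUE,
                score = best[1]))
  }
  list(identity = best[2] / best[3], scored_sites = as.integer(best[3]),
       unscorable = FALSE, score = best[1])
}

#' Pairwise identity matrix over dataset members for a locus combination
#'
#' Per pair, matches and comparable (both-unambiguous) sites are summed over
#' the shared loci, so the multi-locus identity is the scored-site-weighted
#' average of the per-locus identities. A pair sharing no scored site has
#' `NA` identity.
#'
#' @param ds a `barcode_dataset`.
#' @param loci character vector of locus names (family-block loci are folded
#'   block-diagonally first).
#' @return list with `identity` matrix, `scored_sites` matrix and `members`
#'   (specimens with at least one of the loci).
#' @export
identity_matrix <- function(ds, loci) {
  missing_loci <- setdiff(loci, names(ds$alignments))
  if (length(missing_loci) > 0 || length(loci) == 0) {
    abort_format(sprintf("unknown or empty locus combination: %s",
                         paste(missing_loci, collapse = ", ")))
  }
  alns <- lapply(loci, function(l) flat_alignment(ds, l))
  members <- unique(unlist(lapply(alns, `[[`, "members"), use.names = FALSE))
  k <- length(members)
  matches <- matrix(0, k, k, dimnames = list(members, members))
  comparable <- matrix(0, k, k, dimnames = list(members, members))
  for (a in alns) {
    pc <- pair_counts(encode_alignment(a))
    idx <- a$members
    matches[idx, idx] <- matches[idx, idx] + pc$matches
    comparable[idx, idx] <- comparable[idx, idx] + pc$comparable
  }
  identity <- matches / comparable
  identity[comparable == 0] <- NA_real_
  list(identity = identity, scored_sites = comparable, members = members)
}

# internal: the literal decision rule for one query at one rank.
# ids: named identities to subjects (NA = unscorable pair); units: subject
# species; groups: subject labels at the rank being scored (equal to units
# at species rank, the species' genera at genus rank); truth: the query's
# recorded label at that rank.
#
# (i)  the query must reach >= threshold identity to some subject of its
#      recorded group, else no_assignment;
# (ii) the best-matching species must strictly dominate every subject
#      outside its own group. At species rank this is the literal
#      "all sequences of the species show higher identity than sequences of
#      other taxa"; at genus rank, subjects of other species in the same
#      genus are not competitors (they are evidence for the same genus), so
#      only other-genus subjects must be dominated. This derived genus rule
#      guarantees that a correct species assignment implies a correct genus
#      assignment.
apply_assignment_rule <- function(ids, units, truth, threshold = 0.95,
                                  groups = units) {
  force(groups)  # the default must capture units before any subsetting below
  scorable <- !is.na(ids)
  if (!any(scorable)) {
    return(list(outcome = "unscorable", assigned = NA_character_,
                best_identity = NA_real_))
  }
  ids <- ids[scorable]; units <- units[scorable]; groups <- groups[scorable]
  con <- groups == truth
  max_con <- if (any(con)) max(ids[con]) else -Inf
  best <- max(ids)
  if (max_con < threshold) {
    return(list(outcome = "no_assignment", assigned = NA_character_,
                best_identity = best))
  }
  top_groups <- unique(groups[ids == best])
  if (length(top_groups) > 1) {
    # tie across groups at the top: strict dominance is impossible
    return(list(outcome = "incorrect", assigned = NA_character_,
                best_identity = best))
  }
  G <- top_groups
  top_units <- unique(units[ids == best])
  other <- groups != G
  max_other <- if (any(other)) max(ids[other]) else -Inf
  dominates <- any(vapply(top_units, function(B) {
    min(ids[units == B]) > max_other
  }, TRUE))
  if (!dominates) {
    return(list(outcome = "incorrect", assigned = NA_character_,
                best_identity = best))
  }
  list(outcome = if (G == truth) "correct" else "incorrect",
       assigned = G, best_identity = best)
}

#' Assign one query against a reference database
#'
#' An assignment is correct when (i) the query shows identity >= `threshold`
#' to at least one sequence of its recorded species and (ii) every sequence
#' of the best-matching species shows strictly higher identity than every
#' sequence of any other species (ties with a heterospecific break the
#' strict-dominance requirement and score as incorrect). Failure of (i)
#' yields `no_assignment`; failure of (ii), or a best species different from
#' the recorded one, yields `incorrect`. The genus-level outcome applies the
#' same rule at genus granularity: the best-matching species must dominate
#' every other-genus subject (congeners of the best species count as
#' evidence for the same genus, not competitors), so a correct species
#' assignment always implies a correct genus assignment. Subjects whose
#' pair with the query is unscorable are ignored; if all are, the query is
#' `unscorable`.
#'
#' @param query named character vector of length 1 (name = query id,
#'   value = aligned sequence), not present in the database.
#' @param database data.frame with columns `sample_id`, `sequence`,
#'   `species`, `genus`; sequences aligned to the query.
#' @param threshold identity threshold (default 0.95).
#' @param truth_species,truth_genus the query's recorded labels; defaults
#'   assume the query id appears in `database`-style metadata supplied via
#'   these arguments.
#' @param mode passed to [pairwise_identity()].
#' @return list with `query_id`, `species` and `genus` outcome lists
#'   (`outcome`, `assigned`, `best_identity`).
#' @export
assign_query <- function(query, database, truth_species, truth_genus,
                         threshold = 0.95, mode = "aligned") {
  if (nrow(database) == 0) abort_validation("empty database")
  ids <- vapply(database$sequence, function(s) {
    pairwise_identity(unname(query), s, mode = mode)$identity
  }, 0)
  names(ids) <- database$sample_id
  list(query_id = names(query) %||% NA_character_,
       species = apply_assignment_rule(ids, database$species, truth_species,
                                       threshold),
       genus = apply_assignment_rule(ids, database$species, truth_genus,
                                     threshold, groups = database$genus))
}

# internal: evaluate a set of queries against subject sets, given a
# precomputed identity matrix. subjects_of(q) returns the subject ids.
evaluate_queries <- function(im, queries, subjects_of, specimens, threshold) {
  sp_of <- setNames(specimens$species, specimens$sample_id)
  gen_of <- setNames(specimens$genus, specimens$sample_id)
  rows <- lapply(queries, function(q) {
    subjects <- subjects_of(q)
    ids <- im$identity[q, subjects]
    names(ids) <- subjects
    sp <- apply_assignment_rule(ids, unname(sp_of[subjects]), sp_of[[q]], threshold)
    gn <- apply_assignment_rule(ids, unname(sp_of[subjects]), gen_of[[q]], threshold,
                                groups = unname(gen_of[subjects]))
    data.frame(query_id = q, species_outcome = sp$outcome,
               species_assigned = sp$assigned %||% NA_character_,
               genus_outcome = gn$outcome,
               genus_assigned = gn$assigned %||% NA_character_,
               best_identity = sp$best_identity, stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

# internal: summarize per-query outcomes into rate rows
summarize_outcomes <- function(per_query, mode, label, query_plot = NA_character_) {
  out <- lapply(c("species", "genus"), function(rk) {
    oc <- per_query[[paste0(rk, "_outcome")]]
    correct <- sum(oc == "correct")
    incorrect <- sum(oc == "incorrect")
    defined <- correct + incorrect
    data.frame(mode = mode, label = label, query_plot = query_plot, rank = rk,
               n_queries = length(oc), correct = correct, incorrect = incorrect,
               no_assignment = sum(oc == "no_assignment"),
               unscorable = sum(oc == "unscorable"),
               rate = if (defined > 0) percent(correct, defined) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rbind_rows(out)
}

#' Leave-one-out identification evaluation
#'
#' Every specimen with at least one of the loci serves as both database and
#' query: each is queried against all others under the >=95 % identity plus
#' conspecific-dominance rule. Identification rates are computed over
#' queries with a defined outcome (correct or incorrect); `no_assignment`
#' and `unscorable` counts are reported separately.
#'
#' @param ds a `barcode_dataset`.
#' @param loci locus names to combine.
#' @param threshold identity threshold (default 0.95).
#' @param label report label (default: loci joined by `+`).
#' @return list with `report` (one row per rank) and `per_query` data.frame.
#' @export
evaluate_leave_one_out <- function(ds, loci, threshold = 0.95,
                                   label = paste(loci, collapse = "+")) {
  im <- identity_matrix(ds, loci)
  queries <- im$members
  per_query <- evaluate_queries(
    im, queries, function(q) setdiff(im$members, q), ds$specimens, threshold)
  list(report = summarize_outcomes(per_query, "leave_one_out", label),
       per_query = per_query)
}

#' Cross-plot (regional database) identification evaluation
#'
#' One plot's specimens form the reference database; specimens of the query
#' plots are queried against it. Species-level queries are restricted to
#' species with at least one sequenced individual in the database plot, and
#' genus-level queries to genera so represented. When the query plot equals
#' the database plot, the evaluation reduces to leave-one-out within the
#' plot.
#'
#' @param ds a `barcode_dataset`.
#' @param db_plot plot label providing the database.
#' @param query_plots plot labels to query (default: all plots, including
#'   `db_plot`).
#' @param loci locus names to combine.
#' @param threshold identity threshold (default 0.95).
#' @param label report label.
#' @return list with `report` (one row per query plot and rank, including
#'   shared-taxon filter counts `n_shared`) and `per_query`.
#' @export
evaluate_cross_plot <- function(ds, db_plot, query_plots = NULL, loci,
                                threshold = 0.95,
                                label = paste(loci, collapse = "+")) {
  plots <- unique(ds$specimens$plot)
  if (!db_plot %in% plots) abort_validation(sprintf("unknown plot: %s", db_plot))
  query_plots <- query_plots %||% plots
  bad <- setdiff(query_plots, plots)
  if (length(bad) > 0) {
    abort_validation(sprintf("unknown plot(s): %s", paste(bad, collapse = ", ")))
  }
  im <- identity_matrix(ds, loci)
  plot_of <- setNames(ds$specimens$plot, ds$specimens$sample_id)
  sp_of <- setNames(ds$specimens$species, ds$specimens$sample_id)
  gen_of <- setNames(ds$specimens$genus, ds$specimens$sample_id)
  db <- im$members[plot_of[im$members] == db_plot]
  if (length(db) == 0) abort_validation("empty database plot")
  db_species <- unique(sp_of[db])
  db_genera <- unique(gen_of[db])
  reports <- list(); per_query <- list()
  for (qp in query_plots) {
    cand <- im$members[plot_of[im$members] == qp]
    for (rk in c("species", "genus")) {
      shared_set <- if (rk == "species") db_species else db_genera
      lab_of <- if (rk == "species") sp_of else gen_of
      queries <- cand[lab_of[cand] %in% shared_set]
      if (length(queries) == 0) {
        reports[[paste(qp, rk)]] <- data.frame(
          mode = "cross_plot", label = label, query_plot = qp, rank = rk,
          n_queries = 0L, correct = 0L, incorrect = 0L, no_assignment = 0L,
          unscorable = 0L, rate = NA_real_, n_shared = 0L,
          stringsAsFactors = FALSE)
        next
      }
      pq <- evaluate_queries(im, queries, function(q) setdiff(db, q),
                             ds$specimens, threshold)
      summ <- summarize_outcomes(pq, "cross_plot", label, query_plot = qp)
      summ <- summ[summ$rank == rk, ]
      summ$n_shared <- length(intersect(unique(lab_of[cand]), shared_set))
      reports[[paste(qp, rk)]] <- summ
      pq$rank <- rk; pq$query_plot <- qp
      per_query[[paste(qp, rk)]] <- pq
    }
  }
  list(report = rbind_rows(reports),
       per_query = if (length(per_query) > 0) {
         rbind_rows(per_query)
       } else NULL)
}
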