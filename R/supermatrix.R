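#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Columns are laid out in the caller's locus order; partitions are recorded
#' as 0-based half-open `[start, end)` ranges. Under the `union` member
#' policy a member missing a locus is padded with `-` across that locus's
#' columns; the padding encodes absence of data (not an indel) and all
#' downstream distance/identity code treats it as missing via pairwise
#' deletion.
#'
#' @param alignments named list: locus -> `locus_alignment` (use
#'   [concatenate_family_blocks()] first for per-family loci).
#' @param member_policy `"union"` (default) or `"intersection"`.
#' @return object of class `supermatrix` (fields `members`, `seqs`,
#'   `length`, `partitions`).
#' @export
concatenate <- function(alignments, member_policy = c("union", "intersection")) {
  member_policy <- match.arg(member_policy)
  if (length(alignments) == 0) abort_format("no alignments to concatenate")
  member_sets <- lapply(alignments, `[[`, "members")
  members <- if (member_policy == "union") {
    unique(unlist(member_sets, use.names = FALSE))
  } else {
    Reduce(intersect, member_sets)
  }
  if (length(members) == 0) {
    abort_validation("empty member set under intersection policy")
  }
  pieces <- vector("list", length(alignments))
  start <- 0L
  partitions <- data.frame(label = names(alignments), start = NA_integer_,
                           end = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    pad <- strrep("-", a$length)
    piece <- setNames(rep(pad, length(members)), members)
    present <- intersect(members, a$members)
    piece[present] <- a$seqs[present]
    pieces[[i]] <- piece
    partitions$start[i] <- start
    partitions$end[i] <- start + a$length
    start <- start + a$length
  }
  seqs <- do.call(paste0, pieces)
  names(seqs) <- members
  structure(list(members = members, seqs = seqs, length = start,
                 partitions = partitions),
            class = c("supermatrix", "locus_alignment"))
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d sequences x %d columns, %d partitions (%s)\n",
              length(x$members), x$length, nrow(x$partitions),
              paste(x$partitions$label, collapse = ", ")))
  invisible(x)
}

#' Fold per-family alignments of one locus into a block-diagonal alignment
#'
#' Loci that cannot be globally aligned (typically trnH-psbA) are aligned
#' within each family; each family then receives its own disjoint column
#' range and a member's row is its family-block sequence with `-` elsewhere.
#' Cross-family signal for such a locus is absent by construction: a
#' cross-family pair has zero comparable sites at this locus and distance
#' code flags it as undefined rather than scoring 0 (other loci must supply
#' the cross-family signal).
#'
#' @param per_family named list: family -> `locus_alignment`.
#' @param specimens specimen records used to check that each block's members
#'   belong to that family.
#' @param locus locus name for the result (default: from the first block).
#' @return a `locus_alignment` whose `partitions` attribute records the
#'   family blocks.
#' @export
concatenate_family_blocks <- function(per_family, specimens, locus = NULL) {
  if (length(per_family) == 0) abort_format("no family blocks")
  if (is.null(names(per_family)) || any(!nzchar(names(per_family)))) {
    abort_format("per_family must be named by family")
  }
  locus <- locus %||% per_family[[1]]$locus
  fam_of <- setNames(specimens$family, specimens$sample_id)
  seen <- character(0)
  for (fam in names(per_family)) {
    mem <- per_family[[fam]]$members
    dup <- intersect(mem, seen)
    if (length(dup) > 0) {
      abort_validation(sprintf(
        "member(s) assigned to two family blocks: %s", paste(dup, collapse = ", ")))
    }
    seen <- c(seen, mem)
    wrong <- mem[fam_of[mem] != fam]
    if (length(wrong) > 0) {
      abort_validation(sprintf(
        "block %s contains members of another family: %s",
        fam, paste(wrong, collapse = ", ")))
    }
  }
  if (length(per_family) == 1L) {
    out <- per_family[[1]]
    out$locus <- locus
    return(out)
  }
  blocks <- lapply(per_family, function(a) {
    locus_alignment(a$seqs, a$locus)
  })
  names(blocks) <- paste(locus, names(per_family), sep = "/")
  sm <- concatenate(blocks, member_policy = "union")
  structure(list(locus = locus, members = sm$members, seqs = sm$seqs,
                 length = sm$length, partitions = sm$partitions),
            class = "locus_alignment")
}

#' Write a supermatrix: FASTA + RAxML-style partition file + JSON map
#'
#' The partition text file carries 1-based inclusive coordinates
#' (`DNA, label = start-end`) for interoperability; the JSON map keeps the
#' package's native 0-based half-open ranges.
#'
#' @param sm a `supermatrix`.
#' @param stem output path stem; writes `<stem>.fasta`, `<stem>.partitions`
#'   and `<stem>.partitions.json`.
#' @return `stem`, invisibly.
#' @export
write_supermatrix <- function(sm, stem) {
  write_locus_fasta(sm, paste0(stem, ".fasta"))
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$label,
                     sm$partitions$start + 1L, sm$partitions$end),
             paste0(stem, ".partitions"))
  jsonlite::write_json(sm$partitions, paste0(stem, ".partitions.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(stem)
}
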