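#' @importFrom stats setNames
NULL

ALLOWED_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Construct a per-locus alignment
#'
#' Sequences are upper-cased and any character outside `A,C,G,T,N,-` (e.g.
#' IUPAC ambiguity codes) is collapsed to `N`; identity and distance rules in
#' this package only speak of unambiguous identical sites, so ambiguity
#' carries no extra information here. Rows must be equal length: inputs are
#' required to be pre-aligned.
#'
#' @param seqs named character vector of aligned sequences; names are
#'   specimen `sample_id`s.
#' @param locus locus name.
#' @return an object of class `locus_alignment` with fields `locus`,
#'   `members`, `seqs` and `length`.
#' @export
locus_alignment <- function(seqs, locus) {
  if (length(seqs) == 0) abort_format(sprintf("locus %s: empty alignment", locus))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort_format(sprintf("locus %s: sequences must be named by sample_id", locus))
  }
  if (anyDuplicated(ids)) {
    abort_validation(sprintf(
      "locus %s: duplicate sample_id(s): %s", locus,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  seqs <- gsub(sprintf("[^%s]", paste(ALLOWED_CHARS, collapse = "")), "N", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    abort_validation(sprintf(
      "locus %s: ragged alignment (row lengths %s); inputs must be pre-aligned",
      locus, paste(sort(unique(lens)), collapse = ", ")))
  }
  if (lens[1] < 1) abort_validation(sprintf("locus %s: zero-length alignment", locus))
  structure(
    list(locus = locus, members = ids, seqs = setNames(as.character(seqs), ids),
         length = unname(lens[1])),
    class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("<locus_alignment> %s: %d sequences x %d columns\n",
              x$locus, length(x$members), x$length))
  invisible(x)
}

#' Alignment as a character matrix (one column per site)
#' @param aln a `locus_alignment` or `supermatrix`.
#' @return character matrix with rownames = members.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$members
  m
}

#' Read and validate a specimen metadata table
#'
#' Expects a UTF-8 tab-separated file with header columns `sample_id`,
#' `species`, `genus`, `family`, `plot` (extra columns are ignored).
#' Taxonomy must be internally consistent: each species maps to exactly one
#' genus and each genus to exactly one family; the genus must be the first
#' token of the species binomial unless the species is the placeholder
#' `"unknown"`.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated specimen records.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  validate_specimens(df)
}

#' Validate specimen records
#' @param df data.frame with columns sample_id, species, genus, family, plot.
#' @return the validated data.frame (required columns only, as character).
#' @export
validate_specimens <- function(df) {
  required <- c("sample_id", "species", "genus", "family", "plot")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- df[required]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id)) {
    abort_validation(sprintf(
      "duplicate sample_id(s): %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  known <- df$species != "unknown"
  tok <- vapply(strsplit(df$species[known], " ", fixed = TRUE), `[`, "", 1L)
  bad <- df$genus[known] != tok
  if (any(bad)) {
    abort_validation(sprintf(
      "species whose binomial does not start with its genus: %s",
      paste(unique(df$species[known][bad]), collapse = ", ")))
  }
  sp2gen <- unique(df[known, c("species", "genus", "family")])
  dup_sp <- unique(sp2gen$species[duplicated(sp2gen$species)])
  if (length(dup_sp) > 0) {
    rows <- sp2gen[sp2gen$species %in% dup_sp, ]
    abort_validation(sprintf(
      "species mapped to more than one genus/family: %s",
      paste(sprintf("%s -> %s/%s", rows$species, rows$genus, rows$family),
            collapse = "; ")))
  }
  gen2fam <- unique(df[known, c("genus", "family")])
  dup_gen <- unique(gen2fam$genus[duplicated(gen2fam$genus)])
  if (length(dup_gen) > 0) {
    rows <- gen2fam[gen2fam$genus %in% dup_gen, ]
    abort_validation(sprintf(
      "genus mapped to more than one family: %s",
      paste(sprintf("%s -> %s", rows$genus, rows$family), collapse = "; ")))
  }
  rownames(df) <- NULL
  df
}

#' Read one pre-aligned locus from a FASTA file
#'
#' Record ids must be `sample_id`s matching the metadata table exactly
#' (case-sensitive); taxonomy is never parsed from FASTA headers.
#'
#' @param path FASTA file of aligned sequences (gaps allowed).
#' @param locus locus name to attach.
#' @return a [locus_alignment()].
#' @export
read_locus_fasta <- function(path, locus) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort_format(sprintf("locus %s: empty or missing FASTA %s", locus, path))
  }
  dna <- ape::read.FASTA(path, type = "DNA")
  if (length(dna) == 0) abort_format(sprintf("locus %s: no records in %s", locus, path))
  seqs <- vapply(as.character(dna), paste, "", collapse = "")
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- vapply(strsplit(names(dna), "[ \t]"), `[`, "", 1L)
  locus_alignment(seqs, locus)
}

#' Write a locus alignment to FASTA
#' @param aln a `locus_alignment` or `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$members), unname(aln$seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a barcode dataset
#'
#' A dataset couples validated specimen records with per-locus alignments.
#' Every alignment member must have a specimen record, but a specimen may be
#' missing from any locus (this models PCR/sequencing failure; specimens
#' absent from all loci are retained). An alignment entry may also be a named
#' list of per-family alignments for loci that are only alignable within
#' families; use [concatenate_family_blocks()] to fold these into a single
#' block-diagonal locus.
#'
#' @param specimens data.frame of specimen records (see
#'   [validate_specimens()]).
#' @param alignments named list: locus name -> `locus_alignment`, or locus
#'   name -> named list (family -> `locus_alignment`).
#' @return object of class `barcode_dataset`.
#' @export
dataset <- function(specimens, alignments = list()) {
  specimens <- validate_specimens(specimens)
  if (length(alignments) > 0 &&
      (is.null(names(alignments)) || any(!nzchar(names(alignments))))) {
    abort_format("alignments must be a named list (locus -> alignment)")
  }
  for (locus in names(alignments)) {
    entry <- alignments[[locus]]
    alns <- if (inherits(entry, "locus_alignment")) list(entry) else entry
    for (a in alns) {
      unknown <- setdiff(a$members, specimens$sample_id)
      if (length(unknown) > 0) {
        abort_validation(sprintf(
          "locus %s: members with no specimen record: %s", locus,
          paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(list(specimens = specimens, alignments = alignments),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("<barcode_dataset> %d specimens, %d species, loci: %s\n",
              nrow(x$specimens), length(unique(x$specimens$species)),
              paste(names(x$alignments), collapse = ", ")))
  invisible(x)
}

# internal: member ids of a locus entry (flat or per-family)
locus_members <- function(entry) {
  if (inherits(entry, "locus_alignment")) return(entry$members)
  unique(unlist(lapply(entry, `[[`, "members"), use.names = FALSE))
}

# internal: a flat locus_alignment for a dataset entry, folding family blocks
flat_alignment <- function(ds, locus) {
  entry <- ds$alignments[[locus]]
  if (is.null(entry)) abort_format(sprintf("no such locus: %s", locus))
  if (inherits(entry, "locus_alignment")) return(entry)
  concatenate_family_blocks(entry, ds$specimens, locus = locus)
}

#' Sequence-recovery statistics
#'
#' Per-locus counts and fractions of specimens with a recovered sequence,
#' plus the any-marker union (specimens with at least one locus). Fractions
#' are reported both of all specimens and, optionally, of a caller-supplied
#' denominator (e.g. PCR-positive sample counts, which published success
#' tables sometimes use without saying so).
#'
#' @param ds a `barcode_dataset`.
#' @param denominator optional named integer vector (locus -> denominator)
#'   for the alternative per-locus percentages.
#' @return list with `per_locus` (data.frame: locus, n, fraction, pct and,
#'   when supplied, pct_of_denominator), `n_specimens`, `any_marker_count`,
#'   `any_marker_fraction`, `any_marker_pct`.
#' @export
recovery_stats <- function(ds, denominator = NULL) {
  n <- nrow(ds$specimens)
  if (n == 0) abort_validation("empty dataset")
  loci <- names(ds$alignments)
  members <- lapply(ds$alignments, locus_members)
  counts <- vapply(members, length, 0L)
  per_locus <- data.frame(
    locus = loci,
    n = as.integer(counts),
    fraction = counts / n,
    pct = percent(counts, n),
    stringsAsFactors = FALSE)
  if (!is.null(denominator)) {
    den <- denominator[loci]
    per_locus$pct_of_denominator <- percent(counts, as.numeric(den))
  }
  rownames(per_locus) <- NULL
  any_count <- length(unique(unlist(members, use.names = FALSE)))
  list(per_locus = per_locus,
       n_specimens = n,
       any_marker_count = any_count,
       any_marker_fraction = any_count / n,
       any_marker_pct = percent(any_count, n))
}

#' Write a dataset to a directory (TSV + per-locus FASTA)
#'
#' Emits `specimens.tsv` plus one `<locus>.fasta` per flat locus and
#' `<locus>.<family>.fasta` per family block, the same formats
#' [read_dataset()] consumes.
#'
#' @param ds a `barcode_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(ds$specimens, file.path(dir, "specimens.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (locus in names(ds$alignments)) {
    entry <- ds$alignments[[locus]]
    if (inherits(entry, "locus_alignment")) {
      write_locus_fasta(entry, file.path(dir, paste0(locus, ".fasta")))
    } else {
      for (fam in names(entry)) {
        write_locus_fasta(entry[[fam]],
                          file.path(dir, paste0(locus, ".", fam, ".fasta")))
      }
    }
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir directory containing `specimens.tsv` and `*.fasta`.
#' @return a `barcode_dataset`.
#' @export
read_dataset <- function(dir) {
  specimens <- read_specimen_table(file.path(dir, "specimens.tsv"))
  fastas <- sort(list.files(dir, pattern = "\\.fasta$"))
  alignments <- list()
  for (f in fastas) {
    stem <- sub("\\.fasta$", "", f)
    parts <- strsplit(stem, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) {
      alignments[[stem]] <- read_locus_fasta(file.path(dir, f), stem)
    } else {
      locus <- parts[1]
      fam <- paste(parts[-1], collapse = ".")
      alignments[[locus]][[fam]] <-
        read_locus_fasta(file.path(dir, f), locus)
    }
  }
  dataset(specimens, alignments)
}
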