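# Sequence and alignment I/O: FASTA (via Biostrings), Clustal (via seqinr),
# and the tab-separated group/label table.

#' Read unaligned protein sequences from FASTA
#'
#' Headers may carry pipe-separated optional labels,
#' `id|accession|species|taxon_group|isozyme`; missing fields default to
#' `"unknown"`.  An unparseable header degrades to id-only.  The DGK class is
#' derived from the isozyme via [isozyme_class()].  Gap characters are not
#' allowed here (use [read_alignment()] for aligned input); `*` terminators
#' are stripped and residues upper-cased.
#'
#' @param path path to a FASTA file.
#' @return a `seq_records` data frame with columns `id`, `accession`,
#'   `species`, `taxon_group`, `isozyme`, `dgk_class`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("empty FASTA file: %s", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  recs <- .parse_fasta_headers(headers)
  if (anyDuplicated(recs$id)) {
    dup <- unique(recs$id[duplicated(recs$id)])
    .stopf("duplicate sequence id(s) in %s: %s", path, paste(dup, collapse = ", "))
  }
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) .stopf("empty sequence for id '%s'", recs$id[[i]])
    bad <- regexpr(sprintf("[^%s]", paste(.valid_residues(), collapse = "")),
                   seqs[[i]])
    if (bad > 0L)
      .stopf("invalid residue '%s' at position %d in sequence '%s'",
             substr(seqs[[i]], bad, bad), bad, recs$id[[i]])
  }
  recs$residues <- unname(seqs)
  class(recs) <- c("seq_records", "data.frame")
  recs
}

.parse_fasta_headers <- function(headers) {
  fields <- strsplit(headers, "|", fixed = TRUE)
  one <- function(f) {
    f <- trimws(f)
    id <- if (length(f) >= 1L && nzchar(f[[1L]])) f[[1L]] else NA_character_
    acc <- if (length(f) >= 2L && nzchar(f[[2L]])) f[[2L]] else "unknown"
    sp  <- if (length(f) >= 3L && nzchar(f[[3L]])) f[[3L]] else "unknown"
    tg  <- if (length(f) >= 4L && nzchar(f[[4L]])) tolower(f[[4L]]) else "unknown"
    iso <- if (length(f) >= 5L && nzchar(f[[5L]])) f[[5L]] else "unknown"
    iso <- tryCatch(canonical_isozyme(iso), error = function(e) "unknown")
    if (!tg %in% c(.taxon_groups, "unknown")) tg <- "other"
    data.frame(id = id, accession = acc, species = sp, taxon_group = tg,
               isozyme = iso, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(fields, one))
  if (anyNA(out$id)) .stopf("FASTA header with empty id")
  out$dgk_class <- isozyme_class(out$isozyme)
  out
}

#' Write protein sequences to FASTA
#'
#' Inverse of [read_fasta()]: headers are re-assembled as
#' `id|accession|species|taxon_group|isozyme` (id-only when all labels are
#' `"unknown"`), and residues wrapped at 60 columns, so write/read round-trips
#' are byte-stable.
#'
#' @param records a `seq_records` data frame (or any data frame with `id` and
#'   `residues` columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  lab <- function(r, col) if (col %in% names(records)) r[[col]] else "unknown"
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    extra <- c(lab(r, "accession"), lab(r, "species"),
               lab(r, "taxon_group"), lab(r, "isozyme"))
    header <- if (all(extra == "unknown")) r$id else
      paste(c(r$id, extra), collapse = "|")
    body <- gsub("(.{60})", "\\1\n", r$residues)
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", header), strsplit(body, "\n")[[1L]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein multiple alignment
#'
#' Supports aligned FASTA and Clustal `.aln` dialects.  Gap characters `-`
#' and `.` are both accepted and normalised to `-`; residues are upper-cased.
#' All rows must have equal length.
#'
#' @param path path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return a [prot_aln] object.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) .stopf("empty alignment file: %s", path)
    rows <- as.character(set)
    names(rows) <- vapply(strsplit(names(set), "|", fixed = TRUE),
                          function(f) trimws(f[[1L]]), character(1))
  } else {
    rows <- .read_clustal(path)
  }
  prot_aln(rows)
}

# Minimal Clustal block parser: a header line, then interleaved blocks of
# "<name> <segment>" lines; conservation lines (leading whitespace, only
# * : . space) and blank lines are skipped.  Tolerates files Clustal X and
# relatives emit, including trailing residue counts.
.read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE|Kalign)", lines[[1L]],
                               ignore.case = TRUE))
    .stopf("not a Clustal alignment (missing CLUSTAL header): %s", path)
  segs <- list()
  for (ln in lines[-1L]) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                       # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.\\-]+)(\\s+\\d+)?\\s*$", ln))[[1L]]
    if (length(m) == 0L)
      .stopf("unparseable Clustal line: '%s'", ln)
    nm <- m[[2L]]
    segs[[nm]] <- c(segs[[nm]], m[[3L]])
  }
  if (!length(segs)) .stopf("no sequences found in Clustal file: %s", path)
  vapply(segs, paste, character(1), collapse = "")
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a [prot_aln] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  rows <- aln_strings(aln)
  lines <- character(0)
  for (i in seq_along(rows)) {
    body <- gsub("(.{60})", "\\1\n", rows[[i]])
    body <- sub("\n$", "", body)
    lines <- c(lines, paste0(">", names(rows)[[i]]), strsplit(body, "\n")[[1L]])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a group/label table
#'
#' Reads a TSV with header columns `id`, `accession`, `species`,
#' `taxon_group`, `isozyme` and returns a `group_scheme`: the per-sequence
#' isozyme labels plus the derived five-class grouping.  Both Latin and Greek
#' isozyme spellings are accepted and stored canonically as Latin;
#' `"unknown"` rows are allowed.
#'
#' @param path path to the TSV file.
#' @return a `group_scheme` data frame.
#' @export
parse_group_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "isozyme")
  if (!all(need %in% names(tab)))
    .stopf("group table must have columns 'id' and 'isozyme' (got: %s)",
           paste(names(tab), collapse = ", "))
  group_scheme(ids = tab$id, isozyme = tab$isozyme,
               accession = if ("accession" %in% names(tab)) tab$accession,
               species = if ("species" %in% names(tab)) tab$species,
               taxon_group = if ("taxon_group" %in% names(tab)) tab$taxon_group)
}

#' Construct a group scheme
#'
#' @param ids unique sequence ids.
#' @param isozyme isozyme label per id (Latin or Greek; `"unknown"` allowed).
#' @param accession,species,taxon_group optional per-id metadata.
#' @return a `group_scheme` data frame with derived `dgk_class`.
#' @export
group_scheme <- function(ids, isozyme, accession = NULL, species = NULL,
                         taxon_group = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    .stopf("duplicate id(s) in group scheme: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  iso <- canonical_isozyme(isozyme)
  n <- length(ids)
  fill <- function(x) if (is.null(x)) rep("unknown", n) else as.character(x)
  out <- data.frame(id = ids, accession = fill(accession),
                    species = fill(species), taxon_group = fill(taxon_group),
                    isozyme = iso, dgk_class = isozyme_class(iso),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_scheme", "data.frame")
  out
}

#' Look up group labels for sequence ids
#'
#' @param scheme a `group_scheme`.
#' @param ids sequence ids to look up (must all be present).
#' @param grouping `"by_class"` or `"by_isozyme"`.
#' @return character vector of labels, one per id.
#' @export
group_labels <- function(scheme, ids, grouping = c("by_class", "by_isozyme")) {
  grouping <- match.arg(grouping)
  idx <- match(ids, scheme$id)
  if (anyNA(idx))
    .stopf("id(s) absent from group scheme: %s",
           paste(ids[is.na(idx)], collapse = ", "))
  if (grouping == "by_class") scheme$dgk_class[idx] else scheme$isozyme[idx]
}

#' @export
print.group_scheme <- function(x, ...) {
  cat(sprintf("Group scheme: %d sequences, %d isozymes, %d classes\n",
              nrow(x), length(setdiff(unique(x$isozyme), "unknown")),
              length(setdiff(unique(x$dgk_class), "unknown"))))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
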