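# Column-level analytics on a protein multiple alignment.
#
# An alignment is stored as a character matrix (one residue per cell, gap =
# '-'), rows named by sequence id.  Columns are 1-based and intervals closed,
# matching the residue-numbering style of signature figures.

#' Construct a protein alignment
#'
#' @param rows a named character vector of equal-length gapped residue strings,
#'   or a character matrix (one residue per cell) with rownames.
#' @return a `prot_aln` object (character matrix, class `prot_aln`).
#' @export
#' @examples
#' prot_aln(c(s1 = "AC-D", s2 = "ACAD"))
prot_aln <- function(rows) {
  if (is.matrix(rows)) {
    m <- rows
  } else {
    nm <- names(rows)
    rows <- toupper(as.character(rows))
    names(rows) <- nm
    if (is.null(names(rows)) || any(!nzchar(names(rows))))
      .stopf("alignment rows must be named by sequence id")
    rows <- chartr(".", "-", rows)
    lens <- nchar(rows)
    if (length(unique(lens)) != 1L) {
      off <- names(rows)[lens != lens[[1L]]]
      .stopf("ragged alignment: row(s) %s have length(s) %s, expected %d",
             paste(off, collapse = ", "),
             paste(unique(lens[lens != lens[[1L]]]), collapse = ", "),
             lens[[1L]])
    }
    if (lens[[1L]] == 0L) .stopf("alignment rows are empty")
    m <- do.call(rbind, strsplit(rows, ""))
    rownames(m) <- names(rows)
  }
  m[] <- toupper(m)
  m[m == "."] <- "-"
  if (is.null(rownames(m))) .stopf("alignment matrix must have rownames")
  if (anyDuplicated(rownames(m)))
    .stopf("duplicate sequence id(s): %s",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  ok <- m %in% c(.valid_residues(), "-")
  if (!all(ok)) {
    i <- which(!ok)[[1L]]
    .stopf("invalid character '%s' in alignment (row '%s', column %d)",
           m[[i]], rownames(m)[(i - 1L) %% nrow(m) + 1L],
           (i - 1L) %/% nrow(m) + 1L)
  }
  class(m) <- c("prot_aln", "matrix")
  m
}

#' @export
print.prot_aln <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  show <- utils::head(aln_strings(x), 6)
  w <- max(nchar(names(show)))
  for (i in seq_along(show))
    cat(sprintf("  %-*s %s%s\n", w, names(show)[[i]],
                substr(show[[i]], 1, 60), if (ncol(x) > 60) "..." else ""))
  if (nrow(x) > 6) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Collapse an alignment to gapped strings
#' @param aln a `prot_aln`.
#' @return named character vector of gapped row strings.
#' @export
aln_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

.check_cols <- function(aln, cols) {
  if (any(cols < 1L | cols > ncol(aln)))
    .stopf("column index out of range 1..%d", ncol(aln))
}

.check_ids <- function(aln, ids) {
  miss <- setdiff(ids, rownames(aln))
  if (length(miss))
    .stopf("id(s) not in alignment: %s", paste(miss, collapse = ", "))
}

#' Residue profile of one alignment column
#'
#' Frequencies are over non-gap characters; ambiguity codes (X, B, Z, U)
#' count in the gap-fraction denominator but never toward the consensus.
#' Consensus ties are broken alphabetically.
#'
#' @param aln a `prot_aln`.
#' @param col 1-based column index.
#' @return a list with `column`, `freq` (named numeric over non-gap,
#'   non-ambiguous residues), `consensus`, `consensus_fraction`,
#'   `gap_fraction`.
#' @export
column_profile <- function(aln, col) {
  .check_cols(aln, col)
  chars <- unclass(aln)[, col]
  n <- length(chars)
  gap_fraction <- sum(chars == "-") / n
  core <- chars[!(chars %in% c("-", .aa_ambiguous))]
  denom <- sum(chars != "-")   # non-gap count incl. ambiguity codes
  if (length(core) == 0L) {
    freq <- numeric(0)
    consensus <- NA_character_
    consensus_fraction <- 0
  } else {
    tab <- table(core)
    freq <- as.numeric(tab) / sum(tab)
    names(freq) <- names(tab)
    # consensus fraction uses the non-gap, non-ambiguous count as denominator
    cf <- as.numeric(tab) / (denom - sum(chars %in% .aa_ambiguous))
    best <- names(tab)[tab == max(tab)]
    consensus <- sort(best)[[1L]]
    consensus_fraction <- cf[[match(consensus, names(tab))]]
  }
  list(column = col, freq = freq, consensus = consensus,
       consensus_fraction = consensus_fraction, gap_fraction = gap_fraction)
}

#' Is a column conserved over a subset of rows?
#'
#' A column is conserved when the consensus fraction over the subset reaches
#' `threshold` and no subset row is gapped there (gap-veto: a column with any
#' gap in the evaluated set can never count as a conserved flank residue).
#'
#' @param aln a `prot_aln`.
#' @param col 1-based column index.
#' @param subset sequence ids to evaluate (default: all rows).
#' @param threshold consensus-fraction threshold in (0.5, 1].
#' @return logical.
#' @export
is_conserved <- function(aln, col, subset = rownames(aln), threshold = 0.8) {
  .check_cols(aln, col)
  if (length(subset) == 0L) .stopf("subset must be non-empty")
  .check_ids(aln, subset)
  stopifnot(threshold > 0.5, threshold <= 1)
  chars <- unclass(aln)[subset, col]
  if (any(chars == "-")) return(FALSE)
  core <- chars[!chars %in% .aa_ambiguous]
  if (length(core) == 0L) return(FALSE)
  tab <- table(core)
  # same denominator convention as column_profile: ambiguity codes excluded
  max(tab) / length(core) >= threshold
}

#' Remove every column containing a gap
#'
#' Mirrors the standard complete-column gap deletion applied before distance
#' and likelihood computations: only columns with zero gap characters are
#' kept, in their original order.
#'
#' @param aln a `prot_aln`.
#' @return a list with `alignment` (the gap-free `prot_aln`) and `removed`
#'   (1-based indices of the dropped columns).
#' @export
strip_gap_columns <- function(aln) {
  m <- unclass(aln)
  has_gap <- colSums(m == "-") > 0L
  if (all(has_gap)) .stopf("all columns contain gaps; nothing left to keep")
  kept <- m[, !has_gap, drop = FALSE]
  out <- kept
  class(out) <- c("prot_aln", "matrix")
  list(alignment = out, removed = which(has_gap))
}

#' Map alignment columns to ungapped reference coordinates
#'
#' @param aln a `prot_aln`.
#' @param ref_id id of the reference row (e.g. the human DGK-epsilon homolog).
#' @return a `ref_map` list: `ref_id`, `to_residue` (length-ncols integer,
#'   `NA` at reference-gap columns), `to_column` (residue number -> column).
#' @export
map_reference <- function(aln, ref_id) {
  .check_ids(aln, ref_id)
  row <- unclass(aln)[ref_id, ]
  nongap <- row != "-"
  to_residue <- rep(NA_integer_, length(row))
  to_residue[nongap] <- seq_len(sum(nongap))
  to_column <- which(nongap)
  structure(list(ref_id = ref_id, to_residue = to_residue,
                 to_column = to_column),
            class = "ref_map")
}

# Render a column interval in reference coordinates: "12-19" when the
# reference has residues there, "after 11" when the whole locus falls in a
# reference gap.
.ref_anchor <- function(rmap, a, b) {
  res <- rmap$to_residue[a:b]
  if (all(is.na(res))) {
    prev <- rmap$to_residue[seq_len(a - 1L)]
    prev <- prev[!is.na(prev)]
    n <- if (length(prev)) max(prev) else 0L
    sprintf("after %d", n)
  } else {
    sprintf("%d-%d", min(res, na.rm = TRUE), max(res, na.rm = TRUE))
  }
}

#' Pairwise sequence identity between two alignment rows
#'
#' Pairwise-deletion denominator: identity = matches / columns where both
#' rows are non-gap.
#'
#' @param aln a `prot_aln`.
#' @param id1,id2 sequence ids.
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(aln, id1, id2) {
  .check_ids(aln, c(id1, id2))
  m <- unclass(aln)
  a <- m[id1, ]; b <- m[id2, ]
  both <- a != "-" & b != "-"
  if (!any(both)) .stopf("no shared non-gap columns between '%s' and '%s'", id1, id2)
  sum(a[both] == b[both]) / sum(both)
}
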