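# Local best-hit isozyme classifier: a desk-scale stand-in for a database
# similarity survey.  Queries are scored against a labelled reference panel by
# Smith-Waterman local alignment (BLOSUM62, affine gaps 11/1 — the classical
# protein-search defaults) and assigned to the best-scoring isozyme, then
# aggregated into a taxon-group x isozyme presence/absence matrix.

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`).  The classical empty-alignment floor
#' applies: when no positive-scoring alignment exists the score is 0.
#' Alignment is delegated to `Biostrings::pairwiseAlignment`.
#'
#' @param q,r residue strings (no gaps).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (defaults 11, 1).
#' @return list with `score` and the aligned `pattern`/`subject` strings
#'   (empty when the floor applies).
#' @export
smith_waterman <- function(q, r, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  q <- toupper(q); r <- toupper(r)
  for (s in c(q, r)) {
    bad <- regexpr(sprintf("[^%s]", paste(.valid_residues(), collapse = "")), s)
    if (bad > 0L)
      .stopf("invalid residue '%s' at position %d", substr(s, bad, bad), bad)
  }
  al <- Biostrings::pairwiseAlignment(
    q, r, type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = FALSE)
  sc <- Biostrings::score(al)
  if (sc <= 0)
    return(list(score = 0, pattern = "", subject = ""))
  list(score = sc,
       pattern = as.character(Biostrings::alignedPattern(al)),
       subject = as.character(Biostrings::alignedSubject(al)))
}

#' Assign a query protein to the closest isozyme
#'
#' Scores the query against every panel member; the best isozyme is the one
#' holding the highest-scoring member.  Thresholds are relative to the
#' query's self-score: `no_hit` below `s_min`, `ambiguous` when the margin
#' over the runner-up isozyme is below `m_min`, else `confident`.
#'
#' @param query residue string (or one-row `seq_records`).
#' @param panel a `seq_records` data frame with `isozyme` labels covering at
#'   least two isozymes.
#' @param s_min minimum best score as a fraction of self-score (default 0.4).
#' @param m_min minimum best-vs-runner-up margin as a fraction of self-score
#'   (default 0.05).
#' @return data frame with `best_isozyme`, `best_score`, `runner_up`,
#'   `margin`, `verdict`.
#' @export
assign_isozyme <- function(query, panel, s_min = 0.4, m_min = 0.05) {
  if (is.data.frame(query)) query <- query$residues[[1L]]
  if (nrow(panel) == 0L) .stopf("empty reference panel")
  isos <- setdiff(unique(panel$isozyme), "unknown")
  if (length(isos) < 2L) .stopf("panel must cover at least 2 isozymes")
  self <- smith_waterman(query, query)$score
  scores <- vapply(panel$residues, function(r) smith_waterman(query, r)$score,
                   numeric(1))
  by_iso <- vapply(isos, function(z) max(scores[panel$isozyme == z]), numeric(1))
  ord <- order(-by_iso, isos)          # deterministic: ties by isozyme name
  best <- isos[ord[[1L]]]; runner <- isos[ord[[2L]]]
  best_s <- by_iso[[ord[[1L]]]]; run_s <- by_iso[[ord[[2L]]]]
  verdict <- if (best_s < s_min * self) "no_hit"
  else if ((best_s - run_s) < m_min * self) "ambiguous"
  else "confident"
  data.frame(best_isozyme = best, best_score = best_s, runner_up = runner,
             margin = best_s - run_s, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Classify a set of queries against a panel
#'
#' @param queries a `seq_records` data frame (with `species` and
#'   `taxon_group` carried through).
#' @param panel a labelled `seq_records` panel.
#' @param s_min,m_min see [assign_isozyme()].
#' @return data frame of assignments, one row per query.
#' @export
classify_queries <- function(queries, panel, s_min = 0.4, m_min = 0.05) {
  out <- lapply(seq_len(nrow(queries)), function(i) {
    a <- assign_isozyme(queries$residues[[i]], panel, s_min, m_min)
    cbind(data.frame(id = queries$id[[i]], species = queries$species[[i]],
                     taxon_group = queries$taxon_group[[i]],
                     stringsAsFactors = FALSE), a)
  })
  do.call(rbind, out)
}

#' Presence/absence matrix from isozyme assignments
#'
#' Rows are taxon groups, columns the ten isozymes; a cell is `"+"` when
#' every surveyed species in the group has at least one confident assignment
#' to that isozyme, `"+/-"` when only some do, `"-"` when none does.
#'
#' @param assignments output of [classify_queries()] (must carry `species`
#'   and `taxon_group`).
#' @return character matrix with taxon groups as rownames and the ten
#'   isozymes as colnames.
#' @export
build_matrix <- function(assignments) {
  stopifnot(all(c("species", "taxon_group", "best_isozyme", "verdict") %in%
                  names(assignments)))
  bad <- setdiff(unique(assignments$taxon_group), .taxon_groups)
  if (length(bad))
    .stopf("unknown taxon group(s): %s", paste(bad, collapse = ", "))
  groups <- sort(unique(assignments$taxon_group))
  mat <- matrix("-", length(groups), length(.isozyme_names),
                dimnames = list(groups, .isozyme_names))
  for (g in groups) {
    sub <- assignments[assignments$taxon_group == g, , drop = FALSE]
    species <- unique(sub$species)
    for (z in .isozyme_names) {
      hit <- vapply(species, function(sp) any(
        sub$species == sp & sub$best_isozyme == z & sub$verdict == "confident"),
        logical(1))
      mat[g, z] <- if (all(hit)) "+" else if (any(hit)) "+/-" else "-"
    }
  }
  mat
}

#' Write a presence/absence matrix as TSV
#' @param mat output of [build_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(mat, path) {
  utils::write.table(cbind(group = rownames(mat), as.data.frame(mat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
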