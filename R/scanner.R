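# Conserved signature indel (CSI) scanner.
#
# A CSI is a fixed-length (or, for inserts, narrowly variable-length) indel in
# a protein alignment that is flanked on both sides by conserved residues and
# whose presence/absence pattern is uniform within one or more groups of
# homologs and uniformly opposite in all others.  The scanner detects indel
# loci as clusters of overlapping gap runs, applies the flanking-conservation
# rule, and classifies each locus's group specificity.
#
# Polarity caveat: verdicts are reported as insert_relative / deletion_relative
# only.  With no outgroup for the protein family there is no way to infer the
# ancestral state, so "insert" and "deletion" describe the difference relative
# to the other compared groups, never the direction of the historical event.

#' Find maximal gap runs per row
#'
#' @param aln a `prot_aln`.
#' @return data frame with columns `id`, `start`, `end`, `length`,
#'   `touches_terminus` (run abuts the first or last alignment column).
#' @export
find_gap_runs <- function(aln) {
  m <- unclass(aln)
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap)) {
      out[[i]] <- data.frame(
        id = rownames(m)[[i]], start = starts[gap], end = ends[gap],
        length = r$lengths[gap],
        touches_terminus = starts[gap] == 1L | ends[gap] == ncol(m),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id = character(0), start = integer(0), end = integer(0),
                      length = integer(0), touches_terminus = logical(0))
  rownames(out) <- NULL
  out
}

#' Cluster gap runs into indel loci
#'
#' Single-linkage merging of runs whose column intervals overlap; the locus
#' interval is the union hull.  Terminal runs (ragged sequence ends) are
#' excluded first: they reflect fragment boundaries, not indel events.
#'
#' @param runs output of [find_gap_runs()].
#' @param link_overlap merge overlapping runs (default TRUE; FALSE keeps each
#'   run as its own locus, useful for debugging).
#' @return list of loci; each locus is a list with `start`, `end`, and `runs`
#'   (the member gap runs).
#' @export
cluster_loci <- function(runs, link_overlap = TRUE) {
  runs <- runs[!runs$touches_terminus, , drop = FALSE]
  if (nrow(runs) == 0L) return(list())
  runs <- runs[order(runs$start, runs$end, runs$id), , drop = FALSE]
  loci <- list()
  cur <- runs[1L, , drop = FALSE]
  cur_start <- cur$start; cur_end <- cur$end
  for (i in seq_len(nrow(runs))[-1L]) {
    r <- runs[i, , drop = FALSE]
    if (link_overlap && r$start <= cur_end) {
      cur <- rbind(cur, r)
      cur_end <- max(cur_end, r$end)
    } else {
      loci[[length(loci) + 1L]] <- list(start = cur_start, end = cur_end, runs = cur)
      cur <- r; cur_start <- r$start; cur_end <- r$end
    }
  }
  loci[[length(loci) + 1L]] <- list(start = cur_start, end = cur_end, runs = cur)
  loci
}

#' Assess flanking conservation of an indel locus
#'
#' Counts conserved columns (per [is_conserved()], evaluated over all rows
#' with the gap-veto) in the windows `[a-window, a-1]` and `[b+1, b+window]`,
#' clipped to the alignment.  The locus passes when both sides have at least
#' `min_conserved` conserved columns — the classical requirement that a
#' signature indel sit inside a well-conserved neighbourhood (at least 5-6
#' conserved residues within the neighbouring 30-40 amino acids on each side).
#'
#' @param aln a `prot_aln`.
#' @param locus a locus from [cluster_loci()] (or a list with `start`, `end`).
#' @param window flank window width in columns (10-60; default 30).
#' @param min_conserved required conserved columns per side (default 5).
#' @param threshold consensus threshold for [is_conserved()] (default 0.8).
#' @return list with `start`, `end`, `left_window`, `right_window`,
#'   `left_conserved`, `right_conserved`, `pass`.
#' @export
assess_flanks <- function(aln, locus, window = 30L, min_conserved = 5L,
                          threshold = 0.8) {
  stopifnot(window >= 10L, window <= 60L, min_conserved >= 1L)
  a <- locus$start; b <- locus$end
  if (a < 1L || b > ncol(aln) || a > b)
    .stopf("locus [%d,%d] outside alignment 1..%d", a, b, ncol(aln))
  left <- seq.int(max(1L, a - window), a - 1L)
  if (a == 1L) left <- integer(0)
  right <- if (b == ncol(aln)) integer(0) else seq.int(b + 1L, min(ncol(aln), b + window))
  count <- function(cols) sum(vapply(cols, function(cc)
    is_conserved(aln, cc, threshold = threshold), logical(1)))
  lc <- count(left); rc <- count(right)
  list(start = a, end = b,
       left_window = range0(left), right_window = range0(right),
       left_conserved = lc, right_conserved = rc,
       pass = lc >= min_conserved && rc >= min_conserved)
}

range0 <- function(x) if (length(x)) c(min(x), max(x)) else c(NA_integer_, NA_integer_)

# Per-row gapped length within [a,b].
.locus_gap_lengths <- function(aln, a, b) {
  seg <- unclass(aln)[, a:b, drop = FALSE]
  rowSums(seg == "-")
}

#' Classify the group specificity of an indel locus
#'
#' Rows are labelled under the chosen grouping; rows with `"unknown"` labels
#' are excluded with a warning.  Each row is scored by its residue count in
#' the locus hull; the groups then partition into a residue-bearing side and
#' a fully-gapped side.  The signature side is the minority side (fewer
#' groups; ties broken toward the gapped side), and the verdict is:
#'
#' * `group_specific` — exactly one group on the signature side;
#' * `shared_by_groups` — two or more signature groups with a common length;
#' * `paired_lengths` — two or more signature groups, each internally uniform
#'   but with different lengths at the same locus;
#' * `unclassified` — any group mixed (beyond `exceptions` rows) or no
#'   contrast between sides.
#'
#' State is `insert_relative` when the signature groups bear residues that
#' all other groups lack, `deletion_relative` when they are gapped where all
#' others have residues.  For deletion calls the gapped length is the locus
#' width (uniform); for insert calls the length range is min-max of the
#' residue counts over the signature rows.
#'
#' @param aln a `prot_aln`.
#' @param locus a locus from [cluster_loci()].
#' @param scheme a `group_scheme`.
#' @param grouping `"by_class"` or `"by_isozyme"`.
#' @param exceptions number of rows allowed to contradict an otherwise
#'   uniform pattern (default 0: strictly exceptionless).
#' @return a one-row data frame (a `csi_call`): `locus_start`, `locus_end`,
#'   `verdict`, `groups`, `state`, `len_min`, `len_max`, `lengths`,
#'   `exceptions`.
#' @export
classify_specificity <- function(aln, locus, scheme,
                                 grouping = c("by_class", "by_isozyme"),
                                 exceptions = 0L) {
  grouping <- match.arg(grouping)
  a <- locus$start; b <- locus$end
  width <- b - a + 1L
  ids <- rownames(aln)
  labs <- group_labels(scheme, ids, grouping)
  known <- labs != "unknown"
  if (any(!known))
    .warnf("excluding %d row(s) with unknown %s label", sum(!known), grouping)
  ids <- ids[known]; labs <- labs[known]
  if (length(unique(labs)) < 2L)
    .stopf("grouping covers fewer than 2 groups at locus [%d,%d]", a, b)
  g <- .locus_gap_lengths(aln, a, b)[ids]
  res <- width - g                      # residues each row carries in the hull

  call0 <- function(verdict, groups = "", state = "", lens = integer(0), exc = 0L) {
    lr <- if (length(lens)) range(lens) else c(NA_integer_, NA_integer_)
    out <- data.frame(locus_start = a, locus_end = b, verdict = verdict,
                      groups = groups, state = state,
                      len_min = lr[[1L]], len_max = lr[[2L]],
                      lengths = paste(sort(lens), collapse = ","),  # row-order free
                      exceptions = exc, stringsAsFactors = FALSE)
    class(out) <- c("csi_call", "data.frame")
    out
  }

  # Per group: majority state (bearing residues vs fully gapped) and the
  # number of rows contradicting it.
  groups <- sort(unique(labs))
  bearing <- res > 0L
  state_by_group <- logical(length(groups)); viol <- 0L
  viol_rows <- character(0)
  for (k in seq_along(groups)) {
    v <- bearing[labs == groups[[k]]]
    maj <- sum(v) >= length(v) / 2
    state_by_group[[k]] <- maj
    viol <- viol + sum(v != maj)
    viol_rows <- c(viol_rows, ids[labs == groups[[k]]][v != maj])
  }
  if (viol > exceptions) return(call0("unclassified", exc = viol))
  keep <- !(ids %in% viol_rows)         # drop excepted rows from length stats

  Bg <- groups[state_by_group]          # residue-bearing groups
  Ng <- groups[!state_by_group]         # fully-gapped groups
  if (length(Bg) == 0L || length(Ng) == 0L)
    return(call0("unclassified", exc = viol))

  # Signature side: the minority side of the group partition (ties resolved
  # toward the gapped side, i.e. a deletion-relative reading).
  del_side <- length(Ng) <= length(Bg)
  if (del_side) {
    target <- Ng; state <- "deletion_relative"
    lens <- rep(width, sum(labs %in% Ng & keep))
    lens_by_group <- stats::setNames(rep(width, length(Ng)), Ng)
  } else {
    target <- Bg; state <- "insert_relative"
    sel <- labs %in% Bg & keep
    lens <- res[sel]
    lens_by_group <- vapply(Bg, function(gr) {
      v <- unique(res[labs == gr & keep])
      if (length(v) == 1L) as.integer(v) else NA_integer_  # NA marks ranges
    }, integer(1))
  }

  if (length(target) == 1L)
    return(call0("group_specific", target, state, lens, viol))

  # >= 2 signature groups: shared length vs paired lengths
  uni <- !anyNA(lens_by_group)
  if (uni && length(unique(lens_by_group)) > 1L) {
    ord <- order(names(lens_by_group))
    grp_str <- paste(sprintf("%s:%d", names(lens_by_group)[ord],
                             lens_by_group[ord]), collapse = ";")
    return(call0("paired_lengths", grp_str, state,
                 unname(lens_by_group), viol))
  }
  call0("shared_by_groups", paste(sort(target), collapse = "+"), state,
        lens, viol)
}

#' Scan an alignment for conserved signature indels
#'
#' Full pipeline: [find_gap_runs()] -> [cluster_loci()] -> [assess_flanks()]
#' (loci failing the flank rule are dropped) -> [classify_specificity()]
#' (unclassified loci are dropped unless `keep_unclassified`).  Calls are
#' sorted by locus start and, when `ref_id` is given, annotated with
#' reference coordinates via [map_reference()].
#'
#' @param aln a `prot_aln`.
#' @param scheme a `group_scheme` covering the alignment rows.
#' @param grouping `"by_class"` or `"by_isozyme"`.
#' @param window,min_conserved,threshold flank-rule parameters
#'   (see [assess_flanks()]).
#' @param exceptions allowed contradicting rows (see [classify_specificity()]).
#' @param keep_unclassified keep loci with verdict `unclassified`.
#' @param ref_id optional reference row id for coordinate anchoring.
#' @return a `csi_calls` data frame, one row per call, with flank evidence and
#'   (optionally) `ref_anchor` columns.
#' @export
csi_scan <- function(aln, scheme, grouping = c("by_class", "by_isozyme"),
                     window = 30L, min_conserved = 5L, threshold = 0.8,
                     exceptions = 0L, keep_unclassified = FALSE,
                     ref_id = NULL) {
  grouping <- match.arg(grouping)
  runs <- find_gap_runs(aln)
  loci <- cluster_loci(runs)
  calls <- list()
  for (locus in loci) {
    fl <- assess_flanks(aln, locus, window = window,
                        min_conserved = min_conserved, threshold = threshold)
    if (!fl$pass) next
    call <- classify_specificity(aln, locus, scheme, grouping = grouping,
                                 exceptions = exceptions)
    if (call$verdict == "unclassified" && !keep_unclassified) next
    call$flank_left <- fl$left_conserved
    call$flank_right <- fl$right_conserved
    calls[[length(calls) + 1L]] <- call
  }
  if (length(calls) == 0L) {
    out <- data.frame(locus_start = integer(0), locus_end = integer(0),
                      verdict = character(0), groups = character(0),
                      state = character(0), len_min = integer(0),
                      len_max = integer(0), lengths = character(0),
                      exceptions = integer(0), flank_left = integer(0),
                      flank_right = integer(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, calls)
    out <- out[order(out$locus_start, out$locus_end), , drop = FALSE]
  }
  if (!is.null(ref_id)) {
    rmap <- map_reference(aln, ref_id)
    out$ref_anchor <- if (nrow(out)) vapply(seq_len(nrow(out)), function(i)
      .ref_anchor(rmap, out$locus_start[[i]], out$locus_end[[i]]),
      character(1)) else character(0)
    attr(out, "ref_id") <- ref_id
  }
  rownames(out) <- NULL
  attr(out, "params") <- list(grouping = grouping, window = window,
                              min_conserved = min_conserved,
                              threshold = threshold, exceptions = exceptions)
  class(out) <- c("csi_calls", "data.frame")
  out
}

#' @export
print.csi_calls <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("CSI calls: %d locus/loci (grouping %s, flank window %d, >=%d conserved, threshold %.2f)\n",
              nrow(x), p$grouping, p$window, p$min_conserved, p$threshold))
  cat("Polarity is relative to the compared groups; no ancestral state is inferred.\n")
  print.data.frame(x)
  invisible(x)
}

#' Write CSI calls as TSV
#' @param calls a `csi_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_csi_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a signature excerpt
#'
#' Fixed-width text block in the style of published signature figures: the
#' top row is shown verbatim; in every other row `-` marks identity with the
#' top row, a residue letter marks a difference, and `.` marks a gap (so the
#' block plus the top line reconstructs the original residues exactly).
#'
#' @param aln a `prot_aln`.
#' @param call one row of a `csi_calls` data frame.
#' @param context columns of context either side of the locus (default 30).
#' @param ref_maps optional list of `ref_map` objects; their coordinates for
#'   the excerpt are printed in the header.
#' @return character vector of text lines.
#' @export
render_signature <- function(aln, call, context = 30L, ref_maps = NULL) {
  a <- max(1L, call$locus_start - context)
  b <- min(ncol(aln), call$locus_end + context)
  m <- unclass(aln)[, a:b, drop = FALSE]
  ids <- rownames(m)
  w <- max(nchar(ids)) + 2L
  header <- sprintf("Signature %s [%d-%d] %s %s", call$verdict,
                    call$locus_start, call$locus_end, call$groups, call$state)
  if (!is.null(ref_maps)) {
    anchors <- vapply(ref_maps, function(rm)
      sprintf("%s:%s", rm$ref_id, .ref_anchor(rm, call$locus_start, call$locus_end)),
      character(1))
    header <- paste(header, paste(anchors, collapse = " "))
  }
  top <- m[1L, ]
  lines <- c(header,
             sprintf("%-*s %s", w, ids[[1L]], paste(top, collapse = "")))
  for (i in seq_len(nrow(m))[-1L]) {
    r <- m[i, ]
    shown <- ifelse(r == "-", ".", ifelse(r == top, "-", r))
    lines <- c(lines, sprintf("%-*s %s", w, ids[[i]], paste(shown, collapse = "")))
  }
  lines
}

#' Check the ATP-binding motif (G-X-G-X-X-G)
#'
#' Slides a 6-column window across the alignment looking for the classical
#' kinase ATP-binding motif: positions 1, 3 and 6 are glycine.  The reported
#' window is the one matched (gap-free, all three G) by the largest fraction
#' of rows, provided that fraction is at least 0.5.  For each isozyme the
#' residues at the three G positions are tabulated and substitutions flagged.
#'
#' @param aln a `prot_aln`.
#' @param scheme a `group_scheme`.
#' @return a list with `window` (start column, or NA when not found) and
#'   `report` (per-isozyme data frame with the three G-position residues and
#'   a `deviant` flag), or an empty report with a warning when no window
#'   reaches 50\% support.
#' @export
check_atp_motif <- function(aln, scheme) {
  m <- unclass(aln)
  nc <- ncol(m)
  best_frac <- 0; best_start <- NA_integer_
  if (nc >= 6L) for (s in seq_len(nc - 5L)) {
    win <- m[, s:(s + 5L), drop = FALSE]
    ok <- rowSums(win == "-") == 0L &
      win[, 1L] == "G" & win[, 3L] == "G" & win[, 6L] == "G"
    frac <- mean(ok)
    if (frac > best_frac) { best_frac <- frac; best_start <- s }
  }
  empty <- data.frame(isozyme = character(0), g1 = character(0),
                      g3 = character(0), g6 = character(0),
                      deviant = logical(0), stringsAsFactors = FALSE)
  if (is.na(best_start) || best_frac < 0.5) {
    .warnf("ATP-binding motif G-X-G-X-X-G not found in any gap-free window")
    return(list(window = NA_integer_, report = empty))
  }
  s <- best_start
  iso <- group_labels(scheme, rownames(m), "by_isozyme")
  rep_rows <- lapply(sort(unique(iso)), function(z) {
    rows <- m[iso == z, c(s, s + 2L, s + 5L), drop = FALSE]
    g <- apply(rows, 2L, function(col) {
      tab <- sort(table(col), decreasing = TRUE)
      paste(names(tab), collapse = "/")
    })
    data.frame(isozyme = z, g1 = g[[1L]], g3 = g[[2L]], g6 = g[[3L]],
               deviant = any(rows != "G"), stringsAsFactors = FALSE)
  })
  list(window = s, report = do.call(rbind, rep_rows))
}
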