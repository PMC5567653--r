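# End-to-end orchestration: scan -> tree -> (optional) classify -> report.
# The R functions are the interface; run_pipeline() is the single entry point
# a script would call.  All artifacts are plain text and diffable: timestamps
# are confined to the log.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every parameter at its module
#' default; unknown keys in `overrides` are rejected.
#'
#' @param overrides named list of values to override.
#' @return a `run_config` list.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    alignment = NULL,          # path to aligned FASTA, or a prot_aln
    groups = NULL,             # path to group TSV, or a group_scheme
    queries = NULL,            # optional seq_records / FASTA path for classify
    panel = NULL,              # optional labelled panel for classify
    out_dir = "csindel_out",
    grouping = "by_class",
    flank_window = 30L,
    min_flank_conserved = 5L,
    consensus_threshold = 0.8,
    exceptions = 0L,
    keep_unclassified = FALSE,
    reference = NULL,          # reference row id for coordinate anchoring
    bootstrap = 100L,
    seed = 42L,
    s_min = 0.4,
    m_min = 0.05,
    log_level = "info")
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    .stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  class(cfg) <- "run_config"
  cfg
}

.pipeline_log <- function(con, level, stage, msg, t0) {
  if (!is.null(con))
    writeLines(sprintf("[%s] %-8s %6.2fs  %s", level, stage,
                       as.numeric(Sys.time()) - t0, msg), con)
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; CSI scan (`calls.tsv`, `signatures/*.txt`);
#' gap-stripped JTT + NJ tree with bootstrap (`tree.nwk`, `monophyly.tsv`);
#' ATP-motif check; optional query classification (`assignments.tsv`,
#' `table1.tsv`); and a human-readable `summary.md`.  Deterministic for a
#' fixed configuration and seed (timestamps only in `pipeline.log`).
#'
#' @param cfg a `run_config` list (see [run_config()]).
#' @return invisibly, a list with the in-memory results (`calls`, `boot`,
#'   `monophyly_class`, `monophyly_isozyme`, `motif`, `assignments`,
#'   `matrix`, `out_dir`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  logcon <- file(file.path(cfg$out_dir, "pipeline.log"), "w")
  on.exit(close(logcon))

  aln <- if (inherits(cfg$alignment, "prot_aln")) cfg$alignment
  else read_alignment(cfg$alignment)
  scheme <- if (inherits(cfg$groups, "group_scheme")) cfg$groups
  else parse_group_table(cfg$groups)
  .pipeline_log(logcon, "info", "input",
                sprintf("%d sequences x %d columns", nrow(aln), ncol(aln)), t0)

  # --- scan ---------------------------------------------------------------
  calls <- csi_scan(aln, scheme, grouping = cfg$grouping,
                    window = cfg$flank_window,
                    min_conserved = cfg$min_flank_conserved,
                    threshold = cfg$consensus_threshold,
                    exceptions = cfg$exceptions,
                    keep_unclassified = cfg$keep_unclassified,
                    ref_id = cfg$reference)
  write_csi_calls(calls, file.path(cfg$out_dir, "calls.tsv"))
  sig_dir <- file.path(cfg$out_dir, "signatures")
  dir.create(sig_dir, showWarnings = FALSE)
  rmaps <- if (!is.null(cfg$reference)) list(map_reference(aln, cfg$reference))
  for (i in seq_len(nrow(calls))) {
    writeLines(render_signature(aln, calls[i, ], ref_maps = rmaps),
               file.path(sig_dir, sprintf("signature_%02d.txt", i)))
  }
  .pipeline_log(logcon, "info", "scan", sprintf("%d CSI call(s)", nrow(calls)), t0)

  # --- tree ---------------------------------------------------------------
  stripped <- strip_gap_columns(aln)
  boot <- bootstrap_supports(stripped$alignment, n_reps = cfg$bootstrap,
                             seed = cfg$seed)
  rooted <- midpoint_root(boot$tree)
  write_support_tree(rooted, file.path(cfg$out_dir, "tree.nwk"))
  writeLines(as.character(stripped$removed),
             file.path(cfg$out_dir, "removed_columns.txt"))
  mono_cl <- monophyly(boot$tree, scheme, "by_class")
  mono_iso <- monophyly(boot$tree, scheme, "by_isozyme")
  mono <- rbind(cbind(grouping = "by_class", mono_cl),
                cbind(grouping = "by_isozyme", mono_iso))
  utils::write.table(mono, file.path(cfg$out_dir, "monophyly.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .pipeline_log(logcon, "info", "tree",
                sprintf("%d gap-free columns, %d bootstrap replicates",
                        ncol(stripped$alignment), cfg$bootstrap), t0)

  # --- motif --------------------------------------------------------------
  motif <- check_atp_motif(aln, scheme)

  # --- classify (optional) ------------------------------------------------
  assignments <- NULL; mat <- NULL
  if (!is.null(cfg$queries) && !is.null(cfg$panel)) {
    queries <- if (is.data.frame(cfg$queries)) cfg$queries else read_fasta(cfg$queries)
    panel <- if (is.data.frame(cfg$panel)) cfg$panel else read_fasta(cfg$panel)
    assignments <- classify_queries(queries, panel, cfg$s_min, cfg$m_min)
    utils::write.table(assignments, file.path(cfg$out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mat <- build_matrix(assignments)
    write_presence_matrix(mat, file.path(cfg$out_dir, "table1.tsv"))
    .pipeline_log(logcon, "info", "classify",
                  sprintf("%d queries against %d panel members",
                          nrow(queries), nrow(panel)), t0)
  }

  # --- summary ------------------------------------------------------------
  .write_summary(cfg, calls, mono_cl, mono_iso, motif, assignments,
                 file.path(cfg$out_dir, "summary.md"))
  .pipeline_log(logcon, "info", "done", "pipeline complete", t0)
  invisible(list(calls = calls, boot = boot, rooted = rooted,
                 monophyly_class = mono_cl, monophyly_isozyme = mono_iso,
                 motif = motif, assignments = assignments, matrix = mat,
                 out_dir = cfg$out_dir))
}

.write_summary <- function(cfg, calls, mono_cl, mono_iso, motif,
                           assignments, path) {
  L <- c("# Conserved signature indel analysis", "",
         sprintf("Grouping: %s; flank window %d, min conserved %d, threshold %.2f, exceptions %d.",
                 cfg$grouping, cfg$flank_window, cfg$min_flank_conserved,
                 cfg$consensus_threshold, cfg$exceptions), "",
         "## CSI inventory", "",
         sprintf("%d conserved signature indel(s).  Indel polarity (insert/deletion)",
                 nrow(calls)),
         "is relative to the compared groups only; without an outgroup the",
         "ancestral state cannot be inferred.", "")
  if (nrow(calls)) {
    hdr <- "| locus | ref | verdict | groups | state | length |"
    sep <- "|---|---|---|---|---|---|"
    rows <- vapply(seq_len(nrow(calls)), function(i) {
      cl <- calls[i, ]
      len <- if (cl$len_min == cl$len_max) as.character(cl$len_min)
      else sprintf("%d-%d", cl$len_min, cl$len_max)
      sprintf("| %d-%d | %s | %s | %s | %s | %s |",
              cl$locus_start, cl$locus_end,
              if ("ref_anchor" %in% names(cl)) cl$ref_anchor else "",
              cl$verdict, cl$groups, cl$state, len)
    }, character(1))
    L <- c(L, hdr, sep, rows, "")
  }
  fmt_mono <- function(m) vapply(seq_len(nrow(m)), function(i)
    sprintf("| %s | %d | %s | %s |", m$label[[i]], m$n_tips[[i]],
            ifelse(m$monophyletic[[i]], "yes", "no"),
            ifelse(m$monophyletic[[i]],
                   ifelse(is.na(m$support[[i]]), "", as.character(m$support[[i]])),
                   m$offending[[i]])), character(1))
  L <- c(L, "## Monophyly (class grouping)", "",
         "| label | tips | monophyletic | support / offending |", "|---|---|---|---|",
         fmt_mono(mono_cl), "",
         "## Monophyly (isozyme grouping)", "",
         "| label | tips | monophyletic | support / offending |", "|---|---|---|---|",
         fmt_mono(mono_iso), "")
  if (!is.na(motif$window)) {
    L <- c(L, "## ATP-binding motif (G-X-G-X-X-G)", "",
           sprintf("Window starting at alignment column %d.", motif$window),
           "", "| isozyme | G1 | G3 | G6 | deviant |", "|---|---|---|---|---|",
           vapply(seq_len(nrow(motif$report)), function(i) {
             r <- motif$report[i, ]
             sprintf("| %s | %s | %s | %s | %s |", r$isozyme, r$g1, r$g3, r$g6,
                     ifelse(r$deviant, "yes", "no"))
           }, character(1)), "")
  }
  if (!is.null(assignments)) {
    L <- c(L, "## Isozyme assignments", "",
           sprintf("%d queries classified; %d confident, %d ambiguous, %d without hit.",
                   nrow(assignments), sum(assignments$verdict == "confident"),
                   sum(assignments$verdict == "ambiguous"),
                   sum(assignments$verdict == "no_hit")), "")
  }
  writeLines(L, path)
  invisible(path)
}
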