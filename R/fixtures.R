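# Seeded DGK-like benchmark fixtures.
#
# These emulate the study conditions of the vertebrate diacylglycerol kinase
# (DGK) catalytic-domain analysis: ten isozymes (alpha..kappa) in five
# classes, three vertebrate representatives each (mammal, bird, fish), with
# the published signature-indel inventory planted at known loci inside
# invariant flank masks, the ATP-binding motif G-X-G-X-X-G (with the kappa
# mammalian Gly->Ser substitution at its last position), a deliberately weak
# class I + class IV stem, and strongly diverged epsilon/theta clades so that
# midpoint rooting places them outermost.
#
# The "full" variant is a synthetic stand-in for an edited 364-column
# catalytic-domain alignment (no curated sequences are redistributed; all
# residues are simulated): it adds ragged terminal ends and non-clade-consistent
# decoy gap runs so that exactly 260 of its 364 columns are gap-free, and
# carries the full ten-locus signature inventory.  The "core" variant is the
# leaner scanner benchmark with the six-signature subset.

.dgk_tips <- function() {
  taxa <- c("mam1", "brd1", "fsh1")
  unlist(lapply(.isozyme_names, function(z) paste(z, taxa, sep = "_")))
}

.dgk_labels <- function() {
  ids <- .dgk_tips()
  parts <- strsplit(ids, "_")
  iso <- vapply(parts, `[[`, character(1), 1L)
  sp <- vapply(parts, `[[`, character(1), 2L)
  tg <- c(mam1 = "mammal", brd1 = "bird", fsh1 = "fish")[sp]
  data.frame(id = ids, isozyme = iso, taxon_group = unname(tg),
             species = sp, stringsAsFactors = FALSE)
}

.dgk_guide_tree <- function() {
  iso3 <- function(z, tip = 0.05, stem = 0.10)
    sprintf("(%s_mam1:%.3f,%s_brd1:%.3f,%s_fsh1:%.3f):%.3f",
            z, tip, z, tip, z, tip, stem)
  classI <- sprintf("(%s,(%s,%s):0.06):0.20",
                    iso3("alpha"), iso3("beta"), iso3("gamma"))
  # kappa split into two clusters (one with delta, one with eta): the
  # polyphyletic branching reported for this isozyme
  classII <- sprintf(
    "((%s,kappa_mam1:0.14):0.05,(%s,(kappa_brd1:0.05,kappa_fsh1:0.05):0.10):0.05):0.25",
    iso3("delta"), iso3("eta"))
  # zeta likewise split by the iota clade
  classIV <- sprintf(
    "(zeta_mam1:0.14,(%s,(zeta_brd1:0.05,zeta_fsh1:0.05):0.10):0.05):0.20",
    iso3("iota"))
  classIII <- sprintf("(epsilon_mam1:0.05,epsilon_brd1:0.05,epsilon_fsh1:0.05):0.70")
  classV <- sprintf("(theta_mam1:0.05,theta_brd1:0.05,theta_fsh1:0.05):0.45")
  # the class I + class IV stem is deliberately near-zero (one diagnostic
  # masked column plus ~0.5 expected substitutions): the association should
  # be recovered, but only with weak (~50%) bootstrap support
  sprintf("((%s,%s):0.002,%s,(%s,%s):0.10);",
          classI, classIV, classII, classIII, classV)
}

.dgk_clades <- function() {
  lab <- .dgk_labels()
  by_iso <- split(lab$id, lab$isozyme)
  cl <- split(lab$id, isozyme_class(lab$isozyme))
  c(cl, by_iso, list(I_IV = c(cl$I, cl$IV), III_V = c(cl$III, cl$V)))
}

# Planted signature inventory, anchors in core (pre-insert) coordinates.
# Lengths and clade assignments mirror the published DGK signature set:
# a 16-24 aa class I insert (longest in alpha, shortest in gamma), a 2/4 aa
# paired insert for classes I/IV, a 2 aa theta deletion, a 1 aa deletion
# shared by classes I+IV, a 1 aa theta deletion, 5 aa and 2 aa class I
# deletions, an 8 aa epsilon deletion, a 2 aa epsilon insert, and a 3/4 aa
# paired epsilon/theta insert.
.dgk_indels <- function(inventory = c("full", "core")) {
  inventory <- match.arg(inventory)
  full <- list(
    list(label = "sig9",  clade = "III",  anchor = 40,  length = 2,  kind = "insert", flank = 6L),
    list(label = "sig10", clade = "III_V", anchor = 85, length = c(III = 3, V = 4), kind = "insert", flank = 6L),
    list(label = "sig6a", clade = "I",    anchor = 110, length = 5,  kind = "delete", flank = 6L),
    list(label = "sig6b", clade = "I",    anchor = 135, length = 2,  kind = "delete", flank = 6L),
    list(label = "sig8",  clade = "III",  anchor = 160, length = 8,  kind = "delete", flank = 6L),
    list(label = "sig4",  clade = "I_IV", anchor = 190, length = 1,  kind = "delete", flank = 6L),
    list(label = "sig5",  clade = "V",    anchor = 210, length = 1,  kind = "delete", flank = 6L),
    list(label = "sig2",  clade = "I_IV", anchor = 235, length = c(I = 2, IV = 4), kind = "insert", flank = 6L),
    list(label = "sig3",  clade = "V",    anchor = 260, length = 2,  kind = "delete", flank = 6L),
    list(label = "sig1",  clade = "I",    anchor = 290,
         length = c(alpha = 24, beta = 20, gamma = 16), kind = "insert", flank = 6L))
  if (inventory == "full") return(full)
  keep <- c("sig9", "sig8", "sig4", "sig2", "sig3", "sig1")
  Filter(function(i) i$label %in% keep, full)
}

# Expected scanner calls (by_class grouping) for a planted inventory.
.dgk_expected_calls <- function(indels) {
  rows <- lapply(indels, function(ind) {
    state <- if (ind$kind == "insert") "insert_relative" else "deletion_relative"
    multi_group <- ind$clade %in% c("I_IV", "III_V")
    if (multi_group && length(unique(ind$length)) > 1L) {
      lens <- ind$length[order(names(ind$length))]
      verdict <- "paired_lengths"
      groups <- paste(sprintf("%s:%d", names(lens), lens), collapse = ";")
    } else if (multi_group) {
      verdict <- "shared_by_groups"
      groups <- gsub("_", "+", ind$clade)
    } else {
      verdict <- "group_specific"
      groups <- ind$clade
    }
    data.frame(label = ind$label, verdict = verdict, groups = groups,
               state = state, len_min = min(ind$length),
               len_max = max(ind$length), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.dgk_config <- function(seed, inventory = c("full", "core")) {
  inventory <- match.arg(inventory)
  indels <- .dgk_indels(inventory)
  clades <- .dgk_clades()
  lab <- .dgk_labels()
  # ATP-binding motif G-A-G-T-L-G at core columns 60-65 (kappa mammals carry
  # Ser in place of the last Gly)
  fixed <- c("60" = "G", "61" = "A", "62" = "G", "63" = "T", "64" = "L", "65" = "G")
  syn <- list(
    list(column = 150, clade = "I_IV", residue_in = "Q", residue_out = "E"),
    list(column = 65, clade = "kappa_mam", residue_in = "S", residue_out = "G"))
  clades$kappa_mam <- "kappa_mam1"
  cfg <- list(
    tree = .dgk_guide_tree(), root_length = 330L, seed = seed,
    clades = clades, indels = indels, fixed_columns = fixed,
    synapomorphies = syn, labels = lab)
  if (inventory == "full") {
    cfg$decoys <- list(
      list(rows = c("alpha_brd1", "epsilon_fsh1"), start = 25, length = 6),
      list(rows = c("delta_mam1", "theta_brd1", "iota_fsh1"), start = 50, length = 3),
      list(rows = c("beta_fsh1", "eta_mam1"), start = 72, length = 4),
      list(rows = c("gamma_brd1", "zeta_mam1", "epsilon_brd1"), start = 176, length = 4),
      list(rows = c("theta_fsh1", "delta_brd1"), start = 246, length = 4))
    cfg$ragged <- list(
      list(rows = c("alpha_fsh1", "beta_fsh1", "gamma_fsh1",
                    "delta_fsh1", "eta_fsh1", "kappa_fsh1"), n_start = 15),
      list(rows = c("zeta_fsh1", "iota_fsh1", "epsilon_fsh1",
                    "theta_fsh1"), n_end = 15))
  }
  cfg
}

#' DGK-like scanner benchmark fixture
#'
#' A 30-sequence, ~360-column family (ten isozymes in five classes, three
#' vertebrate representatives each) with the six-signature core inventory
#' planted: the 16-24 aa class I insert, the 2/4 aa paired class I/IV insert,
#' the 2 aa theta deletion, the 1 aa class I+IV shared deletion, the 8 aa
#' epsilon deletion and the 2 aa epsilon insert.  Regeneration with the same
#' seed is byte-identical.
#'
#' @param seed integer seed.
#' @return a list with `alignment`, `scheme`, `truth` (planted loci joined
#'   with the expected call verdicts), `tree`, `branch_subs`, `mask_final`.
#' @export
make_dgk_like_fixture <- function(seed = 42L) {
  .make_dgk_fixture(seed, "core")
}

#' Synthetic stand-in for the edited catalytic-domain alignment
#'
#' A 364-column variant of [make_dgk_like_fixture()] carrying the full
#' ten-locus signature inventory plus ragged terminal ends and
#' non-clade-consistent decoy gap runs, constructed so that exactly 260 of
#' its 364 columns are gap-free — the column bookkeeping of an edited
#' vertebrate DGK catalytic-domain alignment.  Synthetic: every residue is
#' simulated; no curated sequences are redistributed.
#'
#' @param seed integer seed.
#' @return same structure as [make_dgk_like_fixture()].
#' @export
make_full_domain_fixture <- function(seed = 42L) {
  .make_dgk_fixture(seed, "full")
}

.make_dgk_fixture <- function(seed, inventory) {
  cfg <- .dgk_config(seed, inventory)
  sim <- simulate_family(cfg)
  expected <- .dgk_expected_calls(cfg$indels)
  expected$len_min <- expected$len_max <- NULL   # already in the sim truth
  sim$truth <- merge(sim$truth, expected, by = "label", sort = FALSE)
  sim$truth <- sim$truth[order(sim$truth$start), , drop = FALSE]
  rownames(sim$truth) <- NULL
  sim$config <- cfg
  sim
}

#' Write a fixture bundle to disk
#'
#' Emits `alignment.fasta` (aligned FASTA), `groups.tsv`, `truth.tsv` and
#' `guide_tree.nwk` into `dir`.
#'
#' @param fixture output of [make_dgk_like_fixture()] / [make_full_domain_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(fixture$alignment, file.path(dir, "alignment.fasta"))
  utils::write.table(as.data.frame(fixture$scheme), file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(fixture$tree, file.path(dir, "guide_tree.nwk"))
  invisible(dir)
}

#' Score scanner calls against a planted truth table
#'
#' A call matches a truth locus when their column hulls agree within a
#' +-`tol` column shift (signature positions are only defined up to a few
#' residues) and verdict, groups, state and length range all agree.
#'
#' @param calls a `csi_calls` data frame.
#' @param truth a fixture truth table (with expected call columns).
#' @param tol allowed column shift (default 3).
#' @return list with `precision`, `recall`, `matched` (logical per call).
#' @export
score_calls <- function(calls, truth, tol = 3L) {
  if (nrow(truth) == 0L)
    return(list(precision = NA_real_, recall = NA_real_,
                matched = logical(nrow(calls))))
  matched_call <- logical(nrow(calls))
  matched_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (matched_truth[[j]]) next
      same_locus <- abs(calls$locus_start[[i]] - truth$start[[j]]) <= tol &&
        abs(calls$locus_end[[i]] - truth$end[[j]]) <= tol
      if (same_locus &&
          calls$verdict[[i]] == truth$verdict[[j]] &&
          calls$groups[[i]] == truth$groups[[j]] &&
          calls$state[[i]] == truth$state[[j]] &&
          calls$len_min[[i]] == truth$len_min[[j]] &&
          calls$len_max[[i]] == truth$len_max[[j]]) {
        matched_call[[i]] <- TRUE
        matched_truth[[j]] <- TRUE
        break
      }
    }
  }
  list(precision = if (nrow(calls)) mean(matched_call) else NA_real_,
       recall = mean(matched_truth), matched = matched_call)
}
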