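# Sequence-family simulator with planted clade-specific indels.
#
# Families are evolved along a known guide tree under the JTT model
# (exact stochastic simulation of the substitution process, so per-branch
# event counts are available), with optional invariant column masks, fixed
# motif columns, clade synapomorphies, and planted indels.  Indels are
# planted deterministically on the stem branch of their clade — every clade
# member and only clade members carry the event — because the scanner
# benchmark needs exact ground truth, not indel-model realism.
#
# Draw order (for seed stability): root states first (column order), then
# branch evolution in the guide tree's edge order (each branch: one
# vectorised pass of exponential waiting times and jump draws per round).

#' Simulate a protein family with planted indels
#'
#' @param cfg a list with components:
#'   \describe{
#'     \item{tree}{`phylo` or Newick string with branch lengths.}
#'     \item{root_length}{number of core (pre-insert) columns.}
#'     \item{seed}{integer seed governing all draws.}
#'     \item{clades}{named list mapping clade labels to tip-label vectors.}
#'     \item{indels}{list of planted indels; each a list with `label`,
#'       `clade`, `anchor` (core column; deletions start there, insertions
#'       open after it), `length` (scalar, or named vector over sub-clades
#'       for variable-length inserts), `kind` (`"insert"`/`"delete"`), and
#'       `flank` (half-width of the invariant flank mask).}
#'     \item{mask}{extra invariant core columns (optional).}
#'     \item{fixed_columns}{named character vector: core column -> residue
#'       forced at the root and masked (optional).}
#'     \item{synapomorphies}{list of lists `column`, `clade`, `residue_in`,
#'       `residue_out`: masked diagnostic columns (optional).}
#'     \item{decoys}{list of lists `rows`, `start`, `length`: gap runs that
#'       are not clade-consistent (optional).}
#'     \item{ragged}{list of lists `rows`, `n_start`, `n_end`: terminal
#'       truncation (optional).}
#'     \item{labels}{data frame with `id`, `isozyme`, `taxon_group`,
#'       `species` used to build the group scheme (optional).}
#'   }
#' @return a list with `alignment` (`prot_aln`), `scheme` (`group_scheme`),
#'   `truth` (planted-indel truth table in final alignment coordinates),
#'   `tree` (the guide `phylo`), `branch_subs` (per-edge substitution event
#'   counts), `mask_final` (invariant columns, final coordinates).
#' @export
simulate_family <- function(cfg) {
  tree <- cfg$tree
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n_core <- cfg$root_length
  stopifnot(is.numeric(n_core), n_core >= 1)
  clades <- cfg$clades
  indels <- cfg$indels %||% list()
  tips <- tree$tip.label

  for (nm in names(clades)) {
    miss <- setdiff(clades[[nm]], tips)
    if (length(miss))
      .stopf("clade '%s' references tip(s) absent from tree: %s",
             nm, paste(miss, collapse = ", "))
  }
  for (ind in indels) {
    if (!ind$clade %in% names(clades))
      .stopf("indel '%s' references unknown clade '%s'", ind$label, ind$clade)
  }
  .check_indel_layout(indels, n_core)

  model <- jtt_model()
  set.seed(cfg$seed)

  # --- column bookkeeping -------------------------------------------------
  ins <- Filter(function(i) i$kind == "insert", indels)
  ins <- ins[order(vapply(ins, function(i) i$anchor, numeric(1)))]
  ins_anchor <- vapply(ins, function(i) i$anchor, numeric(1))
  ins_len <- vapply(ins, function(i) max(i$length), numeric(1))
  n_final <- n_core + sum(ins_len)
  # final position of core column c: c + total insert length opened at or
  # before c-1 (inserts open after their anchor)
  core_to_final <- function(c) c + vapply(c, function(cc)
    sum(ins_len[ins_anchor < cc]), numeric(1))
  core_final <- core_to_final(seq_len(n_core))
  is_core <- logical(n_final); is_core[core_final] <- TRUE

  # --- masks and fixed residues (in final coordinates) --------------------
  mask_core <- as.integer(cfg$mask %||% integer(0))
  for (ind in indels) {
    a <- ind$anchor; fw <- ind$flank %||% 0L
    if (fw > 0L) {
      if (ind$kind == "delete") {
        L <- max(ind$length)
        mask_core <- c(mask_core, seq.int(max(1L, a - fw), a - 1L),
                       seq.int(a + L, min(n_core, a + L - 1L + fw)))
      } else {
        mask_core <- c(mask_core, seq.int(max(1L, a - fw + 1L), a),
                       seq.int(a + 1L, min(n_core, a + fw)))
      }
    }
  }
  mask_core <- sort(unique(mask_core))
  flank_mask_final <- core_final[mask_core]

  fixed <- cfg$fixed_columns %||% character(0)
  fixed_final <- if (length(fixed)) core_final[as.integer(names(fixed))] else integer(0)
  syn <- cfg$synapomorphies %||% list()
  syn_final <- if (length(syn))
    core_final[vapply(syn, function(s) as.integer(s$column), integer(1))] else integer(0)

  mask_final <- sort(unique(c(flank_mask_final, fixed_final, syn_final)))

  # --- root sequence ------------------------------------------------------
  root <- sample(.aa_alphabet, n_final, replace = TRUE, prob = model$pi)
  if (length(flank_mask_final)) {
    # flank-mask draws avoid glycine so the planted ATP motif window stays
    # unique (G marks the motif's diagnostic positions)
    nonG <- setdiff(.aa_alphabet, "G")
    pG <- model$pi[nonG] / sum(model$pi[nonG])
    root[flank_mask_final] <- sample(nonG, length(flank_mask_final),
                                     replace = TRUE, prob = pG)
  }
  if (length(fixed)) root[fixed_final] <- unname(fixed)
  for (s in syn) root[core_final[as.integer(s$column)]] <- s$residue_out

  # --- evolve along the tree ----------------------------------------------
  evolve_cols <- setdiff(seq_len(n_final), mask_final)
  states <- matrix(NA_character_, length(tips) + tree$Nnode, n_final)
  root_node <- length(tips) + 1L
  states[root_node, ] <- root
  branch_subs <- integer(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
    s <- states[par, ]
    ev <- .evolve_branch(s[evolve_cols], tree$edge.length[[e]], model)
    s[evolve_cols] <- ev$states
    states[chl, ] <- s
    branch_subs[[e]] <- ev$n_events
  }
  aln_mat <- states[seq_along(tips), , drop = FALSE]
  rownames(aln_mat) <- tips
  for (s in syn)
    aln_mat[clades[[s$clade]], core_final[as.integer(s$column)]] <- s$residue_in

  # --- plant indels -------------------------------------------------------
  truth <- list()
  for (ind in indels) {
    members <- clades[[ind$clade]]
    if (ind$kind == "delete") {
      L <- max(ind$length)
      colr <- core_final[seq.int(ind$anchor, ind$anchor + L - 1L)]
      aln_mat[members, colr] <- "-"
      start <- min(colr); end <- max(colr)
      lmin <- lmax <- L
    } else {
      hull <- max(ind$length)
      af <- core_to_final(ind$anchor)
      colr <- seq.int(af + 1L, af + hull)
      aln_mat[setdiff(tips, members), colr] <- "-"
      lens <- ind$length
      if (length(lens) > 1L || !is.null(names(lens))) {
        cover <- unlist(lapply(names(lens), function(nm) clades[[nm]]))
        miss <- setdiff(members, cover)
        if (length(miss))
          .stopf("indel '%s': sub-length spec does not cover tip(s) %s",
                 ind$label, paste(miss, collapse = ", "))
        for (nm in names(lens)) {
          li <- lens[[nm]]
          if (li < hull)
            aln_mat[intersect(clades[[nm]], members),
                    colr[seq.int(li + 1L, hull)]] <- "-"
        }
      }
      start <- min(colr); end <- max(colr)
      lmin <- min(ind$length); lmax <- max(ind$length)
    }
    truth[[length(truth) + 1L]] <- data.frame(
      label = ind$label, clade = ind$clade, kind = ind$kind,
      start = start, end = end, len_min = lmin, len_max = lmax,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(label = character(0), clade = character(0), kind = character(0),
               start = integer(0), end = integer(0), len_min = integer(0),
               len_max = integer(0), stringsAsFactors = FALSE)

  # --- decoys and ragged ends ---------------------------------------------
  for (d in cfg$decoys %||% list()) {
    colr <- core_final[seq.int(d$start, d$start + d$length - 1L)]
    aln_mat[d$rows, colr] <- "-"
  }
  for (rg in cfg$ragged %||% list()) {
    if ((rg$n_start %||% 0L) > 0L)
      aln_mat[rg$rows, seq_len(core_final[rg$n_start])] <- "-"
    if ((rg$n_end %||% 0L) > 0L)
      aln_mat[rg$rows, seq.int(n_final - core_final[rg$n_end] + 1L, n_final)] <- "-"
  }

  aln <- aln_mat
  class(aln) <- c("prot_aln", "matrix")
  scheme <- if (!is.null(cfg$labels))
    group_scheme(cfg$labels$id, cfg$labels$isozyme,
                 species = cfg$labels$species,
                 taxon_group = cfg$labels$taxon_group)
  else group_scheme(tips, rep("unknown", length(tips)))
  list(alignment = aln, scheme = scheme, truth = truth, tree = tree,
       branch_subs = branch_subs, mask_final = mask_final)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve a single sequence for a given divergence
#'
#' Applies the JTT substitution process to every residue of `residues` for
#' `t` expected substitutions per site.  Used to derive benchmark queries
#' from reference sequences.
#'
#' @param residues a residue string (no gaps).
#' @param t divergence in expected substitutions per site.
#' @param seed integer seed.
#' @return the evolved residue string.
#' @export
evolve_sequence <- function(residues, t, seed = 42L) {
  set.seed(seed)
  chars <- strsplit(toupper(residues), "")[[1L]]
  if (any(!chars %in% .aa_alphabet))
    .stopf("residues must be standard amino acids")
  ev <- .evolve_branch(chars, t, jtt_model())
  paste(ev$states, collapse = "")
}

.check_indel_layout <- function(indels, n_core) {
  if (!length(indels)) return(invisible())
  iv <- t(vapply(indels, function(i) {
    L <- if (i$kind == "delete") max(i$length) else 0L
    stopifnot(all(i$length >= 1L))
    if (i$anchor < 1L || i$anchor + L - 1L > n_core)
      .stopf("indel '%s' anchor outside sequence", i$label)
    c(i$anchor, i$anchor + max(L - 1L, 0L), i$flank %||% 0L)
  }, numeric(3)))
  ord <- order(iv[, 1L])
  iv <- iv[ord, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in seq_len(nrow(iv) - 1L)) {
    gap <- iv[k + 1L, 1L] - iv[k, 2L]
    minsep <- 2L * max(iv[k, 3L], iv[k + 1L, 3L])
    if (gap <= 0L)
      .stopf("planted loci overlap (anchors %d and %d)", iv[k, 1L], iv[k + 1L, 1L])
    if (gap <= minsep)
      .stopf("planted loci at anchors %d and %d closer than 2x flank half-width",
             iv[k, 1L], iv[k + 1L, 1L])
  }
  invisible()
}

# Exact stochastic simulation of the substitution process on one branch:
# vectorised over columns; each round draws exponential waiting times at the
# current states' rates and jumps the columns whose waiting time fits in the
# remaining branch length.  Endpoint distribution is exactly exp(Qt).
.evolve_branch <- function(states, t, model) {
  if (t <= 0 || length(states) == 0L)
    return(list(states = states, n_events = 0L))
  idx <- match(states, .aa_alphabet)
  rates <- -diag(model$Q)
  jump <- model$Q; diag(jump) <- 0
  jump <- jump / rowSums(jump)
  t_rem <- rep(t, length(idx))
  active <- seq_along(idx)
  n_events <- 0L
  while (length(active)) {
    dt <- stats::rexp(length(active), rates[idx[active]])
    hit <- dt < t_rem[active]
    if (any(hit)) {
      who <- active[hit]
      n_events <- n_events + length(who)
      u <- stats::runif(length(who))
      for (k in seq_along(who)) {
        p <- jump[idx[[who[[k]]]], ]
        idx[[who[[k]]]] <- findInterval(u[[k]], cumsum(p)) + 1L
      }
      t_rem[who] <- t_rem[who] - dt[hit]
    }
    active <- active[hit]
  }
  list(states = .aa_alphabet[idx], n_events = n_events)
}
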