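# Catalytic-domain phylogeny: JTT pairwise maximum-likelihood distances,
# neighbour joining, column bootstrap, midpoint rooting, and monophyly
# reporting.  Tree manipulation uses ape; the model arithmetic (rate matrix,
# transition probabilities, pairwise ML optimisation, pruning likelihood) is
# implemented here on the embedded JTT constants.

#' The JTT substitution model
#'
#' Builds the Jones-Taylor-Thornton rate matrix from the embedded published
#' exchangeabilities and equilibrium frequencies, normalised to one expected
#' substitution per site per unit time, with its symmetric eigendecomposition
#' cached for fast transition probabilities.
#'
#' @return a `subst_model` list: `name`, `Q` (20x20 rate matrix), `pi`
#'   (equilibrium frequencies), and eigendecomposition components.
#' @export
jtt_model <- function() {
  if (!is.null(.model_cache$jtt)) return(.model_cache$jtt)
  n <- 20L
  S <- matrix(0, n, n, dimnames = list(.aa_alphabet, .aa_alphabet))
  S[lower.tri(S)] <- .jtt_exchangeabilities
  S <- S + t(S)
  pi <- .jtt_frequencies
  names(pi) <- .aa_alphabet
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))          # expected substitutions per unit time
  Q <- Q / scale
  dimnames(Q) <- list(.aa_alphabet, .aa_alphabet)
  # symmetrise for a stable eigendecomposition: B = D Q D^-1 with D=diag(sqrt pi)
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  model <- list(name = "JTT", Q = Q, pi = pi,
                V = diag(1 / d) %*% e$vectors,       # P(t) = V exp(Lt) Vi
                Vi = t(e$vectors) %*% diag(d),
                lambda = e$values)
  .model_cache$jtt <- model
  model
}

.model_cache <- new.env(parent = emptyenv())

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `subst_model` from [jtt_model()].
#' @param t branch length (expected substitutions per site), `t >= 0`.
#' @return 20x20 stochastic matrix.
#' @export
transition_prob <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$V %*% (exp(model$lambda * t) * model$Vi)
  P[P < 0] <- 0                        # clip rounding noise
  dimnames(P) <- dimnames(model$Q)
  P
}

# 20x20 site-pattern count table for two gapped rows, pairwise gap deletion;
# ambiguity codes are treated as missing and dropped.
.pair_counts <- function(r1, r2) {
  ok <- r1 %in% .aa_alphabet & r2 %in% .aa_alphabet
  if (!any(ok)) return(NULL)
  f1 <- factor(r1[ok], levels = .aa_alphabet)
  f2 <- factor(r2[ok], levels = .aa_alphabet)
  table(f1, f2)
}

.pair_loglik <- function(C, model, t) {
  P <- transition_prob(model, t)
  L <- model$pi * P                    # joint probability pi_a P_ab(t)
  sum(C * log(pmax(L, 1e-300)))
}

#' Pairwise maximum-likelihood distance under the JTT model
#'
#' Maximises the pairwise likelihood `prod_cols pi_a P(a -> b | t)` over
#' `t >= 0` by bounded scalar optimisation, with pairwise gap deletion.
#' Saturated pairs are capped at `t_max` with a warning.
#'
#' @param row1,row2 gapped residue strings or character vectors.
#' @param model a `subst_model` (default [jtt_model()]).
#' @param t_max saturation cap (default 10).
#' @return the ML distance in substitutions per site.
#' @export
jtt_distance <- function(row1, row2, model = jtt_model(), t_max = 10) {
  tochar <- function(x) if (length(x) == 1L && nchar(x[[1L]]) > 1L)
    strsplit(toupper(x), "")[[1L]] else toupper(x)
  r1 <- tochar(row1); r2 <- tochar(row2)
  stopifnot(length(r1) == length(r2))
  both <- r1 != "-" & r2 != "-"
  if (!any(both)) .stopf("no shared non-gap columns between the two rows")
  C <- .pair_counts(r1[both], r2[both])
  if (is.null(C)) .stopf("no unambiguous shared columns between the two rows")
  if (sum(C) == sum(diag(C))) return(0)
  C <- (C + t(C)) / 2   # reversibility: symmetrising keeps the likelihood and
                        # makes the estimate exactly direction-independent
  opt <- stats::optimize(function(t) .pair_loglik(C, model, t),
                         interval = c(1e-8, t_max), maximum = TRUE,
                         tol = 1e-8)
  t_hat <- opt$maximum
  if (t_hat > t_max * 0.99) {
    .warnf("saturated pair: distance capped at %g", t_max)
    t_hat <- t_max
  }
  t_hat
}

#' All-pairs JTT distance matrix for an alignment
#'
#' @param aln a `prot_aln` (typically gap-stripped).
#' @param model a `subst_model`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
jtt_dist_matrix <- function(aln, model = jtt_model()) {
  m <- unclass(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    D[i, j] <- D[j, i] <- jtt_distance(m[i, ], m[j, ], model = model)
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via `ape::nj`), with negative branch lengths
#' clamped to zero.  Exact on additive matrices.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3L) .stopf("neighbour joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Canonical string keys for the non-trivial bipartitions of an unrooted tree:
# each internal edge splits the tips in two; the key is the sorted side NOT
# containing the first tip (so the representation is rooting-invariant).
.bipartitions <- function(phy, tips = NULL) {
  if (is.null(tips)) tips <- sort(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (s in pp) {
    side <- labs[s]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (tips[[1L]] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds the
#' JTT distance matrix and NJ tree per replicate, and reports for each
#' internal bipartition of the point-estimate tree the percentage of
#' replicates containing it.  Requires a gap-free alignment (run
#' [strip_gap_columns()] first, mirroring complete-column gap deletion).
#'
#' @param aln a gap-free `prot_aln`.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed RNG seed (all randomness in the resampling).
#' @param model a `subst_model`.
#' @return a `boot_phylo` list: `tree` (point NJ tree with `node.label`
#'   percent supports on internal nodes), `bip_freq` (named counts over all
#'   bipartitions seen in replicates), `n_reps`.
#' @export
bootstrap_supports <- function(aln, n_reps = 100L, seed = 42L,
                               model = jtt_model()) {
  if (n_reps < 1L) .stopf("n_reps must be >= 1")
  m <- unclass(aln)
  if (any(m == "-")) .stopf("alignment must be gap-free; run strip_gap_columns() first")
  set.seed(seed)
  point <- nj_tree(jtt_dist_matrix(aln, model))
  tips <- sort(rownames(m))
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- m[, cols, drop = FALSE]
    class(rep_aln) <- c("prot_aln", "matrix")
    rep_tree <- nj_tree(jtt_dist_matrix(rep_aln, model))
    for (k in .bipartitions(rep_tree, tips))
      assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L, counts)
  }
  bip_freq <- unlist(as.list(counts))
  if (is.null(bip_freq)) bip_freq <- integer(0)
  # attach supports of the point tree's bipartitions as node labels
  point <- .label_supports(point, bip_freq, n_reps, tips)
  structure(list(tree = point, bip_freq = bip_freq, n_reps = n_reps,
                 seed = seed),
            class = "boot_phylo")
}

.label_supports <- function(phy, bip_freq, n_reps, tips) {
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  labels <- rep("", n_node)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    if (tips[[1L]] %in% side) side <- setdiff(tips, side)
    k <- paste(sort(side), collapse = "|")
    cnt <- if (k %in% names(bip_freq)) bip_freq[[k]] else 0L
    labels[[i]] <- as.character(round(100 * cnt / n_reps))
  }
  phy$node.label <- labels
  phy
}

#' Bootstrap support for an arbitrary tip set
#'
#' Percentage of bootstrap replicates whose tree contains the bipartition
#' separating `tip_set` from the remaining tips (computable whether or not
#' the point-estimate tree contains that clade).
#'
#' @param boot a `boot_phylo` from [bootstrap_supports()].
#' @param tip_set character vector of tip labels.
#' @return support percentage in \[0, 100\].
#' @export
clade_support <- function(boot, tip_set) {
  tips <- sort(boot$tree$tip.label)
  side <- sort(tip_set)
  if (length(side) <= 1L || length(side) >= length(tips) - 1L)
    return(100)                        # trivial bipartitions are always present
  if (tips[[1L]] %in% side) side <- setdiff(tips, side)
  k <- paste(sort(side), collapse = "|")
  cnt <- if (k %in% names(boot$bip_freq)) boot$bip_freq[[k]] else 0L
  100 * cnt / boot$n_reps
}

#' @export
print.boot_phylo <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap supports: %d tips, %d replicates (seed %d)\n",
              length(x$tree$tip.label), x$n_reps, x$seed))
  invisible(x)
}

#' Midpoint-root an unrooted tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path.
#'
#' @param tree an unrooted `phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    .stopf("cannot midpoint-root a tree with all-zero branch lengths")
  phangorn::midpoint(tree)
}

#' Monophyly report for labelled tips
#'
#' A label is monophyletic when its tip set forms one side of a bipartition
#' of the tree (a single-tip label is trivially monophyletic).  For
#' non-monophyletic labels the offending leaves are the extra tips found
#' under the label's most recent common ancestor.
#'
#' @param tree a `phylo` (rooted or unrooted); node labels, when integer
#'   percentages, are read as bootstrap supports.
#' @param scheme a `group_scheme` covering the tips.
#' @param grouping `"by_class"` or `"by_isozyme"`.
#' @return data frame with `label`, `n_tips`, `monophyletic`, `support`
#'   (support of the defining edge when available), `offending` (semicolon
#'   list of intruding tips otherwise).
#' @export
monophyly <- function(tree, scheme, grouping = c("by_class", "by_isozyme")) {
  grouping <- match.arg(grouping)
  labs <- group_labels(scheme, tree$tip.label, grouping)
  if (any(labs == "unknown"))
    .stopf("unlabeled leaf/leaves: %s",
           paste(tree$tip.label[labs == "unknown"], collapse = ", "))
  tips <- sort(tree$tip.label)
  bips <- .bipartitions(tree, tips)
  out <- lapply(sort(unique(labs)), function(lab) {
    set <- tree$tip.label[labs == lab]
    mono <- length(set) == 1L || length(set) == length(tips)
    if (!mono) {
      side <- sort(set)
      if (tips[[1L]] %in% side) side <- setdiff(tips, side)
      mono <- paste(sort(side), collapse = "|") %in% bips
    }
    support <- NA_real_
    offending <- ""
    if (mono && length(set) > 1L && length(set) < length(tips) &&
        !is.null(tree$node.label)) {
      mrca <- ape::getMRCA(tree, set)
      lab_idx <- mrca - length(tree$tip.label)
      s <- suppressWarnings(as.numeric(tree$node.label[[lab_idx]]))
      support <- s
    }
    if (!mono) {
      mrca <- ape::getMRCA(tree, set)
      desc <- ape::extract.clade(tree, mrca)$tip.label
      offending <- paste(sort(setdiff(desc, set)), collapse = ";")
    }
    data.frame(label = lab, n_tips = length(set), monophyletic = mono,
               support = support, offending = offending,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log likelihood of an alignment on a fixed tree (Felsenstein pruning)
#'
#' Site-independent pruning likelihood under the given substitution model,
#' without rate heterogeneity.  Used for relative comparison of topologies
#' only.
#'
#' @param aln a gap-free `prot_aln`.
#' @param tree a `phylo` with branch lengths whose tips equal the alignment
#'   ids.
#' @param model a `subst_model`.
#' @return the log likelihood.
#' @export
tree_log_likelihood <- function(aln, tree, model = jtt_model()) {
  m <- unclass(aln)
  if (any(m == "-")) .stopf("alignment must be gap-free")
  if (!setequal(tree$tip.label, rownames(m)))
    .stopf("tree tips and alignment ids differ")
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # compress identical columns
  key <- apply(m, 2L, paste, collapse = "")
  uniq <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[uniq])))
  cols <- which(uniq)
  # per-edge transition matrices
  P <- lapply(tree$edge.length, function(t) transition_prob(model, t))
  total <- 0
  tip_idx <- match(tree$tip.label, rownames(m))
  for (ci in seq_along(cols)) {
    col <- m[, cols[[ci]]]
    L <- matrix(1, 20L, n_node)
    for (k in seq_len(n_tip)) {
      ch <- col[[tip_idx[[k]]]]
      v <- numeric(20L)
      if (ch %in% .aa_alphabet) v[[match(ch, .aa_alphabet)]] <- 1 else v[] <- 1
      L[, k] <- v
    }
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chl <- tree$edge[e, 2L]
      L[, par] <- L[, par] * as.numeric(P[[e]] %*% L[, chl])
    }
    root <- tree$edge[nrow(tree$edge), 1L]
    total <- total + w[[ci]] * log(sum(model$pi * L[, root]))
  }
  total
}

#' Write a tree in Newick with integer supports as node labels
#'
#' @param boot a `boot_phylo` or a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(boot, path) {
  tr <- if (inherits(boot, "boot_phylo")) boot$tree else boot
  ape::write.tree(tr, file = path, digits = 6)
  invisible(path)
}
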