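# JTT model arithmetic, distances, NJ, bootstrap, rooting, monophyly,
# pruning likelihood.

test_that("the JTT rate matrix is a proper reversible generator at unit rate", {
  m <- jtt_model()
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_equal(max(abs(rowSums(m$Q))), 0, tolerance = 1e-12)
  # detailed balance pi_i Q_ij = pi_j Q_ji
  bal <- diag(m$pi) %*% m$Q
  expect_equal(bal, t(bal), tolerance = 1e-12, ignore_attr = TRUE)
  # normalised to one expected substitution per unit time
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  # P(t) rows are distributions; P(0) = I
  P <- transition_prob(m, 0.3)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(transition_prob(m, 0), diag(20), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("jtt_distance is zero for identical rows, symmetric, and matches a grid oracle", {
  m <- jtt_model()
  row <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  expect_equal(jtt_distance(row, row), 0)

  set.seed(3)
  fx <- simulate_family(list(tree = "(a:0.08,b:0.07);", root_length = 300L,
                             seed = 3L, clades = list()))
  r1 <- unclass(fx$alignment)["a", ]; r2 <- unclass(fx$alignment)["b", ]
  d12 <- jtt_distance(r1, r2)
  expect_equal(d12, jtt_distance(r2, r1))
  # independent route: series expm + grid search (grid pitch 1e-3)
  expect_equal(d12, jtt_grid_oracle(r1, r2, m), tolerance = 1e-2)
})

test_that("jtt_distance agrees with phangorn's pairwise ML distances", {
  fx <- simulate_family(list(tree = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);",
                             root_length = 400L, seed = 9L, clades = list()))
  D <- jtt_dist_matrix(fx$alignment)
  pd <- phangorn::phyDat(unclass(fx$alignment), type = "AA")
  Dp <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  expect_equal(D[rownames(Dp), colnames(Dp)], Dp, tolerance = 2e-3,
               ignore_attr = TRUE)
})

test_that("jtt_distance recovers the simulating divergence (consistency)", {
  errs1e3 <- errs1e4 <- numeric(0)
  for (s in 1:5) {
    for (len in c(1000L, 10000L)) {
      fx <- simulate_family(list(tree = "(a:0.05,b:0.05);", root_length = len,
                                 seed = s, clades = list()))
      d <- jtt_distance(unclass(fx$alignment)["a", ], unclass(fx$alignment)["b", ])
      if (len == 1000L) errs1e3 <- c(errs1e3, abs(d - 0.1))
      else errs1e4 <- c(errs1e4, abs(d - 0.1))
    }
  }
  expect_lt(max(errs1e4), 0.02)
  expect_lt(mean(errs1e4), mean(errs1e3) + 0.005)   # bias/spread shrinks with length
})

test_that("NJ is exact on additive matrices and errors below 3 taxa", {
  D <- additive4()
  expect_true(is_split_ab_cd(D))
  tr <- nj_tree(D)
  # the recovered topology must be the (unique) additive one: AB|CD
  expect_equal(
    ape::dist.topo(ape::unroot(tr),
                   ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4));"))),
    0, ignore_attr = TRUE)
  # exact branch lengths
  cd <- ape::cophenetic.phylo(tr)
  expect_equal(cd[rownames(D), colnames(D)], D, tolerance = 1e-10,
               ignore_attr = TRUE)
  # brute force: of the three possible splits only AB|CD is additive
  perm <- list(c("A", "C", "B", "D"), c("A", "D", "C", "B"))
  for (p in perm) {
    Dp <- D[p, p]; dimnames(Dp) <- list(LETTERS[1:4], LETTERS[1:4])
    expect_false(is_split_ab_cd(Dp))
  }
  # 3 taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  cd3 <- ape::cophenetic.phylo(tr3)
  expect_equal(cd3[rownames(D3), colnames(D3)], D3, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("bootstrap supports are reproducible and saturate on duplicated columns", {
  # alignment = strongly structured columns duplicated many times: every
  # defined bipartition should be recovered in every replicate
  base <- c(a = "AAACGWKL", b = "AAACGWKL", c = "CCGAGWKL", d = "CCGAGWKL")
  rows <- vapply(base, function(x) paste(rep(x, 15), collapse = ""), character(1))
  aln <- prot_aln(rows)
  b1 <- bootstrap_supports(aln, n_reps = 30L, seed = 5L)
  b2 <- bootstrap_supports(aln, n_reps = 30L, seed = 5L)
  expect_identical(b1$bip_freq, b2$bip_freq)
  sup <- suppressWarnings(as.numeric(b1$tree$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 100))
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_supports(aln, n_reps = 0L), "n_reps")
  gappy <- prot_aln(c(a = "A-", b = "AA", c = "CA"))
  expect_error(bootstrap_supports(gappy), "gap-free")
})

test_that("strong clade signal yields high bootstrap supports for all clades", {
  for (s in 1:3) {
    fx <- simulate_family(list(
      tree = "((a1:0.02,a2:0.02):0.4,(b1:0.02,b2:0.02):0.4,(c1:0.02,c2:0.02):0.4);",
      root_length = 400L, seed = s, clades = list()))
    boot <- bootstrap_supports(fx$alignment, n_reps = 50L, seed = s)
    for (cl in list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2")))
      expect_gte(clade_support(boot, cl), 90)
  }
})

test_that("midpoint rooting halves the longest leaf-to-leaf path", {
  tr <- ape::read.tree(text = "(a:1.5,b:0.5);")
  r <- midpoint_root(tr)
  depths <- ape::node.depth.edgelength(r)[1:2]
  expect_equal(depths, c(1, 1))
  # property: max root-to-leaf depth equals half the tree diameter, the
  # minimum achievable over all rootings (exhaustive closed form)
  set.seed(23)
  for (rep in 1:10) {
    tr <- ape::rtree(10)
    r <- midpoint_root(tr)
    maxdepth <- max(ape::node.depth.edgelength(r)[1:10])
    diam <- max(ape::cophenetic.phylo(tr))
    expect_equal(maxdepth, diam / 2, tolerance = 1e-8)
  }
  zero <- ape::read.tree(text = "(a:0,b:0,(c:0,d:0):0);")
  expect_error(midpoint_root(zero), "all-zero")
})

test_that("monophyly reports clades, polyphyly and offending leaves", {
  scheme <- group_scheme(c("a1", "a2", "b1", "b2"),
                         c("alpha", "alpha", "beta", "beta"))
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep1 <- monophyly(good, scheme, "by_isozyme")
  expect_true(all(rep1$monophyletic))
  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- monophyly(bad, scheme, "by_isozyme")
  expect_false(any(rep2$monophyletic))
  expect_true(nzchar(rep2$offending[rep2$label == "alpha"]))
  # unlabeled leaf errors
  s2 <- group_scheme(c("a1", "a2", "b1", "b2"),
                     c("alpha", "alpha", "beta", "unknown"))
  expect_error(monophyly(good, s2, "by_isozyme"), "nlabeled")
})

test_that("pruning likelihood matches direct state summation on 3-leaf toys", {
  m <- jtt_model()
  set.seed(31)
  for (rep in 1:4) {
    n <- 12L
    cols <- replicate(3, sample(names(m$pi), n, replace = TRUE))
    aln <- prot_aln(rbind(a = cols[, 1], b = cols[, 2], c = cols[, 3]))
    ta <- round(stats::runif(1, 0.02, 0.6), 6)
    tb <- round(stats::runif(1, 0.02, 0.6), 6)
    tc <- round(stats::runif(1, 0.02, 0.6), 6)
    tree <- ape::read.tree(text = sprintf("(a:%f,b:%f,c:%f);", ta, tb, tc))
    expect_equal(tree_log_likelihood(aln, tree, m),
                 loglik3_oracle(cols[, 1], cols[, 2], cols[, 3], ta, tb, tc, m),
                 tolerance = 1e-10)
  }
})

test_that("near-zero branches with identical residues reduce to log equilibrium", {
  m <- jtt_model()
  aln <- prot_aln(c(a = "W", b = "W"))
  tree <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  expect_equal(tree_log_likelihood(aln, tree, m), log(m$pi[["W"]]),
               tolerance = 1e-6)
})

test_that("the generating topology outscores leaf-permuted topologies", {
  fx <- simulate_family(list(
    tree = "((a:0.05,b:0.05):0.3,(c:0.05,d:0.05):0.3,(e:0.05,f:0.05):0.3);",
    root_length = 200L, seed = 13L, clades = list()))
  m <- jtt_model()
  true_tree <- fx$tree
  ll_true <- tree_log_likelihood(fx$alignment, true_tree, m)
  set.seed(13)
  worse <- 0L
  for (k in 1:10) {
    pt <- true_tree
    pt$tip.label <- sample(pt$tip.label)
    if (ape::dist.topo(pt, true_tree) == 0 &&
        identical(sort(ape::cophenetic.phylo(pt)["a", ]),
                  sort(ape::cophenetic.phylo(true_tree)["a", ]))) next
    ll <- tree_log_likelihood(fx$alignment, pt, m)
    expect_lte(ll, ll_true)
    worse <- worse + 1L
  }
  expect_gte(worse, 5L)
})

test_that("Newick write/read round-trips topology, lengths and supports", {
  fx <- make_dgk_like_fixture(2)
  st <- strip_gap_columns(fx$alignment)$alignment
  small <- unclass(st)[1:8, , drop = FALSE]
  class(small) <- c("prot_aln", "matrix")
  boot <- bootstrap_supports(small, n_reps = 20L, seed = 2L)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(boot, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(back, boot$tree), 0, ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), sort(boot$tree$tip.label))
  ord <- match(back$tip.label, boot$tree$tip.label)
  expect_equal(sort(round(back$edge.length, 6)),
               sort(round(boot$tree$edge.length, 6)), tolerance = 1e-6)
  keep <- function(x) sort(x[!is.na(x) & nzchar(x)])
  expect_equal(keep(back$node.label), keep(boot$tree$node.label))
})
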