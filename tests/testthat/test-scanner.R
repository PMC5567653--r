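# CSI scanner: gap runs, locus clustering, flank rule, specificity verdicts.

test_that("find_gap_runs extracts maximal runs and flags terminal runs", {
  aln <- toy_aln(s1 = "ACDEF", s2 = "AC--F", s3 = "--DEF")
  runs <- find_gap_runs(aln)
  expect_equal(nrow(runs), 2L)
  r2 <- runs[runs$id == "s2", ]
  expect_equal(c(r2$start, r2$end, r2$length), c(3L, 4L, 2L))
  expect_false(r2$touches_terminus)
  expect_true(runs$touches_terminus[runs$id == "s3"])
  expect_equal(nrow(find_gap_runs(toy_aln(s1 = "ACDEF"))), 0L)
})

test_that("gap runs reconstruct the gap mask exactly (random masks)", {
  set.seed(19)
  for (rep in 1:5) {
    mask <- matrix(stats::runif(50 * 200) < 0.08, 50, 200,
                   dimnames = list(paste0("s", 1:50), NULL))
    m <- matrix("A", 50, 200)
    m[mask] <- "-"
    rownames(m) <- paste0("s", 1:50)
    runs <- find_gap_runs(prot_aln(m))
    rebuilt <- matrix(FALSE, 50, 200, dimnames = list(rownames(m), NULL))
    for (i in seq_len(nrow(runs)))
      rebuilt[runs$id[[i]], runs$start[[i]]:runs$end[[i]]] <- TRUE
    expect_identical(unname(rebuilt), unname(mask))
    # per-row maximality: neighbours of each run are non-gap
    for (i in seq_len(nrow(runs))) {
      s <- runs$start[[i]]; e <- runs$end[[i]]
      if (s > 1) expect_false(mask[runs$id[[i]], s - 1])
      if (e < 200) expect_false(mask[runs$id[[i]], e + 1])
    }
  }
})

test_that("cluster_loci merges overlapping runs into hulls and drops terminal runs", {
  runs <- data.frame(id = c("a", "b", "c", "d"),
                     start = c(3L, 3L, 10L, 1L), end = c(4L, 6L, 11L, 2L),
                     length = c(2L, 4L, 2L, 2L),
                     touches_terminus = c(FALSE, FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  loci <- cluster_loci(runs)
  expect_length(loci, 2L)
  expect_equal(c(loci[[1L]]$start, loci[[1L]]$end), c(3L, 6L))
  expect_equal(sort(loci[[1L]]$runs$length), c(2L, 4L))
  expect_equal(c(loci[[2L]]$start, loci[[2L]]$end), c(10L, 11L))
})

test_that("assess_flanks counts conserved columns and enforces the 5-of-30 rule", {
  # 6 invariant columns on each side of a 2-column gap locus in s3/s4
  rows <- c(a1 = "ACDEFGMKACDEFG", a2 = "ACDEFGMKACDEFG",
            b1 = "ACDEFG--ACDEFG", b2 = "ACDEFG--ACDEFG")
  aln <- prot_aln(rows)
  locus <- list(start = 7L, end = 8L)
  fl <- assess_flanks(aln, locus, window = 10L, min_conserved = 5L)
  expect_equal(fl$left_conserved, 6L)
  expect_equal(fl$right_conserved, 6L)
  expect_true(fl$pass)
  # only 4 conserved columns on the left -> fail
  rows2 <- c(a1 = "WWYYACDEMKACDEFG", a2 = "YYWWACDEMKACDEFG",
             b1 = "WYWYACDE--ACDEFG", b2 = "YWYWACDE--ACDEFG")
  aln2 <- prot_aln(rows2)
  fl2 <- assess_flanks(aln2, list(start = 9L, end = 10L), window = 10L,
                       min_conserved = 5L)
  expect_equal(fl2$left_conserved, 4L)
  expect_false(fl2$pass)
  expect_error(assess_flanks(aln, list(start = 0L, end = 2L)), "outside")
})

test_that("classify_specificity issues the four verdicts correctly", {
  iso <- c(rep("alpha", 2), rep("delta", 2), rep("epsilon", 2), rep("zeta", 2),
           rep("theta", 2))
  ids <- sprintf("%s%d", rep(c("a", "d", "e", "z", "t"), each = 2), 1:2)
  scheme <- group_scheme(ids, iso)

  mk <- function(centres) {
    pat <- as.list(centres); names(pat) <- ids
    flanked_aln(pat)
  }
  W <- 20L  # flank width on each side of the centre

  # class III rows all gapped 8 columns, others ungapped -> deletion, length 8
  centres <- c(rep("MKLVNWYH", 4), rep("--------", 2), rep("MKLVNWYH", 4))
  aln <- mk(centres)
  locus <- list(start = W + 1L, end = W + 8L)
  call <- classify_specificity(aln, locus, scheme)
  expect_equal(call$verdict, "group_specific")
  expect_equal(call$groups, "III")
  expect_equal(call$state, "deletion_relative")
  expect_equal(c(call$len_min, call$len_max), c(8L, 8L))

  # class I insert 2, class IV insert 4 at one locus -> paired lengths
  centres <- c(rep("MK--", 2), rep("----", 2), rep("----", 2),
               rep("MKLV", 2), rep("----", 2))
  call <- classify_specificity(mk(centres), list(start = W + 1L, end = W + 4L),
                               scheme)
  expect_equal(call$verdict, "paired_lengths")
  expect_equal(call$groups, "I:2;IV:4")
  expect_equal(call$state, "insert_relative")

  # shared 1-aa deletion in classes I and IV
  centres <- c(rep("-", 2), rep("M", 2), rep("K", 2), rep("-", 2), rep("V", 2))
  call <- classify_specificity(mk(centres), list(start = W + 1L, end = W + 1L),
                               scheme)
  expect_equal(call$verdict, "shared_by_groups")
  expect_equal(call$groups, "I+IV")
  expect_equal(call$state, "deletion_relative")

  # one class II row also gapped at a class III locus: unclassified at
  # exceptions = 0, recovered as group_specific at exceptions = 1
  centres <- c(rep("MKLVNWYH", 3), "--------", rep("--------", 2),
               rep("MKLVNWYH", 4))
  aln <- mk(centres)
  locus <- list(start = W + 1L, end = W + 8L)
  expect_equal(classify_specificity(aln, locus, scheme)$verdict, "unclassified")
  call <- classify_specificity(aln, locus, scheme, exceptions = 1L)
  expect_equal(call$verdict, "group_specific")
  expect_equal(call$groups, "III")
  expect_equal(call$exceptions, 1L)

  # fewer than two known groups is an error
  one <- group_scheme(ids, rep("alpha", 10))
  expect_error(classify_specificity(aln, locus, one, "by_isozyme"),
               "fewer than 2 groups")
})

test_that("csi_scan returns nothing on gap-free alignments", {
  iso <- rep(c("alpha", "epsilon"), each = 2)
  scheme <- group_scheme(c("a1", "a2", "e1", "e2"), iso)
  aln <- flanked_aln(list(a1 = "MK", a2 = "MK", e1 = "MK", e2 = "MK"))
  expect_equal(nrow(csi_scan(aln, scheme)), 0L)
})

test_that("csi_scan recovers planted signatures with exact truth agreement", {
  for (s in c(5, 17)) {
    fx <- make_dgk_like_fixture(s)
    calls <- csi_scan(fx$alignment, fx$scheme)
    sc <- score_calls(calls, fx$truth)
    expect_equal(sc$precision, 1)
    expect_equal(sc$recall, 1)
    expect_equal(nrow(calls), nrow(fx$truth))
  }
})

test_that("every call's locus is residue-filled in at least one sequence", {
  # a CSI is a difference, not a universally gapped region: some compared
  # sequence spans the whole locus without gaps (for fixed-length calls a
  # whole group does; for variable-length inserts the longest members do)
  fx <- make_full_domain_fixture(8)
  calls <- csi_scan(fx$alignment, fx$scheme)
  m <- unclass(fx$alignment)
  cls <- group_labels(fx$scheme, rownames(m))
  for (i in seq_len(nrow(calls))) {
    seg <- m[, calls$locus_start[[i]]:calls$locus_end[[i]], drop = FALSE]
    expect_true(any(rowSums(seg == "-") == 0L))
    if (calls$len_min[[i]] == calls$len_max[[i]]) {
      gapfree_by_group <- vapply(unique(cls), function(g)
        all(seg[cls == g, , drop = FALSE] != "-"), logical(1))
      expect_true(any(gapfree_by_group))
    }
  }
})

test_that("raising the flank requirements never increases the number of calls", {
  fx <- make_full_domain_fixture(4)
  n <- vapply(c(3L, 5L, 7L, 9L), function(k)
    nrow(csi_scan(fx$alignment, fx$scheme, min_conserved = k)), integer(1))
  expect_true(all(diff(n) <= 0))
  n_th <- vapply(c(0.7, 0.8, 0.9, 1), function(th)
    nrow(csi_scan(fx$alignment, fx$scheme, threshold = th)), integer(1))
  expect_true(all(diff(n_th) <= 0))
})

test_that("calls are invariant under row permutation of the alignment", {
  fx <- make_dgk_like_fixture(9)
  aln <- fx$alignment
  set.seed(1)
  perm <- sample(nrow(aln))
  aln2 <- unclass(aln)[perm, , drop = FALSE]
  class(aln2) <- c("prot_aln", "matrix")
  c1 <- as.data.frame(csi_scan(aln, fx$scheme))
  c2 <- as.data.frame(csi_scan(aln2, fx$scheme))
  expect_equal(c1, c2)
})

test_that("render_signature marks identity with '-', gaps with '.', and inverts", {
  aln <- toy_aln(top = "GKGACDEF", o1 = "GKGACDEF", o2 = "GRG-CDEF")
  call <- data.frame(locus_start = 4L, locus_end = 4L, verdict = "group_specific",
                     groups = "x", state = "deletion_relative",
                     stringsAsFactors = FALSE)
  block <- render_signature(aln, call, context = 10L)
  expect_length(block, 4L)            # header + 3 rows
  body <- sub("^\\S+\\s+", "", block[-1L])
  expect_equal(body[[2L]], "--------")
  expect_equal(body[[3L]], "-R-.----")
  # inverse transform: '-' copies top, '.' is a gap, letters stand
  top <- strsplit(body[[1L]], "")[[1L]]
  dec <- function(line) {
    ch <- strsplit(line, "")[[1L]]
    paste(ifelse(ch == "-", top, ifelse(ch == ".", "-", ch)), collapse = "")
  }
  expect_equal(dec(body[[3L]]), "GRG-CDEF")
})

test_that("the ATP motif check finds G-X-G-X-X-G and flags deviants only", {
  ids <- c("a1", "a2", "k1", "k2")
  scheme <- group_scheme(ids, c("alpha", "alpha", "kappa", "kappa"))
  aln <- prot_aln(c(a1 = "MKGAGTLGWY", a2 = "MKGAGTLGWY",
                    k1 = "MKGAGTLSWY", k2 = "MKGAGTLGWY"))
  rep <- check_atp_motif(aln, scheme)
  expect_equal(rep$window, 3L)
  expect_false(rep$report$deviant[rep$report$isozyme == "alpha"])
  expect_true(rep$report$deviant[rep$report$isozyme == "kappa"])
  expect_match(rep$report$g6[rep$report$isozyme == "kappa"], "S")
  # no motif anywhere -> warning and empty report
  none <- prot_aln(c(a1 = "MKYAYTLYWY", a2 = "MKYAYTLYWY",
                     k1 = "MKYAYTLYWY", k2 = "MKYAYTLYWY"))
  expect_warning(rep2 <- check_atp_motif(none, scheme), "not found")
  expect_equal(nrow(rep2$report), 0L)
})
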