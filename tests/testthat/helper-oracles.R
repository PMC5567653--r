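# Independent brute-force oracles and tiny fixture builders used across the
# suite.  These deliberately avoid the code paths they are used to check.

# --- alignment builders ------------------------------------------------------

toy_aln <- function(...) prot_aln(c(...))

# an alignment whose flanks are invariant and whose centre carries a planted
# group pattern; `pattern` is a named list id -> centre string
flanked_aln <- function(pattern, flank = "ACDEFGHIKLMNPQRSTVWY") {
  rows <- vapply(pattern, function(p) paste0(flank, p, flank), character(1))
  names(rows) <- names(pattern)
  prot_aln(rows)
}

# --- Smith-Waterman exhaustive oracle ---------------------------------------
# Best local alignment score under affine gaps (gap of length L costs
# open + L * ext), by exhaustive recursion over all global alignments of all
# substring pairs.  Only usable for very short strings.

sw_oracle <- function(q, r, open = 11, ext = 1) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  B <- BLOSUM62
  qc <- strsplit(q, "")[[1L]]
  rc <- strsplit(r, "")[[1L]]
  glob <- function(qs, rs) {
    memo <- new.env(parent = emptyenv())   # over (i, k, previous op)
    rec <- function(i, k, prev) {
      if (i > length(qs) && k > length(rs)) return(0)
      key <- paste(i, k, prev)
      if (!is.null(memo[[key]])) return(memo[[key]])
      best <- -Inf
      if (i <= length(qs) && k <= length(rs))
        best <- max(best, B[qs[[i]], rs[[k]]] + rec(i + 1L, k + 1L, "M"))
      if (i <= length(qs))
        best <- max(best, -(if (prev == "I") ext else open + ext) +
                      rec(i + 1L, k, "I"))
      if (k <= length(rs))
        best <- max(best, -(if (prev == "D") ext else open + ext) +
                      rec(i, k + 1L, "D"))
      memo[[key]] <- best
      best
    }
    rec(1L, 1L, "start")
  }
  best <- 0
  for (i1 in seq_along(qc)) for (j1 in i1:length(qc))
    for (i2 in seq_along(rc)) for (j2 in i2:length(rc))
      best <- max(best, glob(qc[i1:j1], rc[i2:j2]))
  best
}

# --- 3-leaf likelihood by direct state summation ----------------------------
# Unrooted 3-leaf tree (a:ta, b:tb, c:tc): sum over the internal state.

loglik3_oracle <- function(cols_a, cols_b, cols_c, ta, tb, tc, model) {
  Pa <- transition_prob(model, ta)
  Pb <- transition_prob(model, tb)
  Pc <- transition_prob(model, tc)
  aa <- match(cols_a, names(model$pi))
  bb <- match(cols_b, names(model$pi))
  cc <- match(cols_c, names(model$pi))
  total <- 0
  for (s in seq_along(aa)) {
    lik <- sum(model$pi * Pa[, aa[[s]]] * Pb[, bb[[s]]] * Pc[, cc[[s]]])
    total <- total + log(lik)
  }
  total
}

# --- pairwise ML distance by grid search ------------------------------------
# Independent likelihood route: transition matrix by scaling-and-squaring
# series (Matrix-free Taylor with scaling), then a plain grid maximisation.

expm_taylor <- function(M) {
  s <- max(1L, ceiling(log2(max(1, norm(M, "I")))))
  A <- M / 2^s
  P <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in 1:20) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

jtt_grid_oracle <- function(r1, r2, model, grid = seq(0.005, 1, by = 0.001)) {
  ll <- vapply(grid, function(t) {
    P <- expm_taylor(model$Q * t)
    l <- 0
    for (i in seq_along(r1)) {
      a <- match(r1[[i]], names(model$pi)); b <- match(r2[[i]], names(model$pi))
      l <- l + log(model$pi[[a]] * P[a, b])
    }
    l
  }, numeric(1))
  grid[[which.max(ll)]]
}

# --- additive 4-taxon matrices ----------------------------------------------

additive4 <- function() {
  # tree ((A:1,B:2):1,(C:3,D:4)); internal edge 1
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# four-point-condition check that a matrix is additive with split AB|CD
is_split_ab_cd <- function(D) {
  s1 <- D["A", "B"] + D["C", "D"]
  s2 <- D["A", "C"] + D["B", "D"]
  s3 <- D["A", "D"] + D["B", "C"]
  s1 < s2 && abs(s2 - s3) < 1e-9
}
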