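# Exhaustive local-alignment oracle for short peptides.
#
# A local alignment with positive gap penalties always starts and ends on
# an aligned residue pair, so it is fully described by matched index sets
# i1<...<ik / j1<...<jk; the score is the sum of substitution scores
# minus affine costs for index runs skipped between consecutive matched
# columns (open + len * ext per run, on either sequence). Enumerating all
# C(m,k)*C(n,k) index-set pairs for k = 1..min(m,n) covers every local
# alignment of sequences up to length 8 (sum_k C(8,k)^2 = 12869).

brute_local_align <- function(q, s, scheme = scoring_scheme()) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  alpha <- rownames(scheme$matrix)
  qi <- match(qc, alpha); si <- match(sc, alpha)
  gapcost <- function(d) {
    g <- d - 1L
    ifelse(g > 0, scheme$gap_open + g * scheme$gap_ext, 0)
  }
  best <- 0
  for (k in seq_len(min(m, n))) {
    qs <- utils::combn(m, k)
    ss <- utils::combn(n, k)
    if (k == 1) { qs <- matrix(qs, nrow = 1); ss <- matrix(ss, nrow = 1) }
    nA <- ncol(qs); nB <- ncol(ss)
    # M[a, b] = substitution total for index-set pair (a, b)
    M <- matrix(0, nA, nB)
    for (t in seq_len(k))
      M <- M + scheme$matrix[qi[qs[t, ]], si[ss[t, ]], drop = FALSE]
    gq <- if (k > 1) colSums(matrix(gapcost(apply(qs, 2, diff)), k - 1))
          else numeric(nA)
    gs <- if (k > 1) colSums(matrix(gapcost(apply(ss, 2, diff)), k - 1))
          else numeric(nB)
    best <- max(best, max(M - outer(gq, gs, "+")))
  }
  best
}

# direct-summation hypergeometric upper tail, independent of phyper
brute_hyper_tail <- function(k, n1, n2, N) {
  i <- k:min(n1, n2)
  sum(exp(lchoose(n1, i) + lchoose(N - n1, n2 - i) - lchoose(N, n2)))
}

# exhaustive scan for the longest terminal repeat (direct or inverted)
# at perfect identity -- an independent check of the detector
brute_terminal_repeat <- function(seq, min_len = 20) {
  L <- nchar(seq)
  revcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  best <- list(kind = "none", len = 0L)
  for (t in seq(min_len, min(2000L, L %/% 2L))) {
    pre <- substr(seq, 1, t)
    suf <- substr(seq, L - t + 1, L)
    if (pre == revcomp(suf)) best <- list(kind = "inverted", len = t)
  }
  if (best$kind == "none") {
    for (t in seq(min_len, min(2000L, L %/% 2L))) {
      if (substr(seq, 1, t) == substr(seq, L - t + 1, L))
        best <- list(kind = "direct", len = t)
    }
  }
  best
}

random_aa_panel <- function(n_pairs, max_len = 8, seed = 1) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  lapply(seq_len(n_pairs), function(i) {
    list(q = paste(sample(aa, sample(1:max_len, 1), TRUE), collapse = ""),
         s = paste(sample(aa, sample(1:max_len, 1), TRUE), collapse = ""))
  })
}
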