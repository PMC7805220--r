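#' Protein scoring scheme with Karlin-Altschul statistics
#'
#' Bundles a substitution matrix, affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_ext`), and the Karlin-Altschul `lambda`/`K`
#' parameters used to turn raw local-alignment scores into bit scores and
#' E-values. Defaults correspond to gapped BLASTP with BLOSUM62 and gap
#' penalties 11/1 (`lambda = 0.267`, `K = 0.041`). The `X` residue is
#' neutral (score 0 against everything).
#'
#' @param matrix 24x24 integer substitution matrix (rows/cols named by the
#'   amino-acid alphabet). Default: BLOSUM62 with the `X` row/column zeroed.
#' @param gap_open,gap_ext positive gap penalties.
#' @param lambda,K Karlin-Altschul parameters for the chosen scheme.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_ext = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62_neutral_x()
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)),
            gap_open > 0, gap_ext > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# BLOSUM62 from Biostrings, with X made score-neutral.
blosum62_neutral_x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "scoring_scheme: %dx%d matrix, gap %d/%d, lambda=%.3f K=%.3f\n",
    nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_ext, x$lambda, x$K))
  invisible(x)
}

# Encode peptides as 0-based indices into the scheme alphabet; residues
# outside the alphabet map to X.
encode_peptides <- function(seqs, scheme) {
  alpha <- rownames(scheme$matrix)
  xi <- match("X", alpha)
  lapply(seqs, function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], alpha)
    idx[is.na(idx)] <- xi
    as.integer(idx - 1L)
  })
}

#' Bit score from a raw alignment score
#'
#' `bits = (lambda * S - ln K) / ln 2`.
#'
#' @param score raw alignment score(s).
#' @param scheme a [scoring_scheme()].
#' @return numeric bit score(s).
#' @export
bitscore <- function(score, scheme = scoring_scheme()) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

#' E-value from a bit score
#'
#' `E = m * n * 2^(-bits)`, with `m` the query length and `n` the
#' effective database length in residues.
#'
#' @param bits bit score(s).
#' @param m query length (residues), `>= 1`.
#' @param n database length (residues), `>= 1`.
#' @return numeric E-value(s).
#' @export
evalue <- function(bits, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  m * n * 2^(-bits)
}
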