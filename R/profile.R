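#' Build a position-specific scoring profile from an alignment
#'
#' Constructs a log-odds profile (one score vector per alignment column
#' over the 20 standard residues) from a gapped multiple alignment, the
#' sensitivity device this pipeline uses where a BLASTP search against
#' single sequences fails on diverged capsid genes. Columns with more
#' than 50% gap characters are masked (dropped). Scores are natural-log
#' odds of pseudocount-smoothed column frequencies against the background:
#' `s = log((c_a + alpha * b_a) / (n + alpha) / b_a)`.
#'
#' This is a position-specific scoring model with affine gap states, not
#' a full Plan-7 HMM; its contract — recovering family members that
#' single-sequence search misses — is what the test suite pins down.
#'
#' @param msa character vector (or `AAStringSet`) of >= 2 aligned peptides
#'   of equal length; gaps as `-` or `.`.
#' @param alpha pseudocount weight (> 0 recommended; small alpha sharpens
#'   the profile toward the observed residues).
#' @param background residue background frequencies over the 20 standard
#'   amino acids (named, sums to 1); default uniform.
#' @return An object of class `profile_model` with elements `scores`
#'   (ncols x 24 matrix, neutral for B/Z/X/*), `ncols`, `background`,
#'   `alpha`, `nseq`, `kept_columns`.
#' @export
build_profile <- function(msa, alpha = 1,
                          background = NULL) {
  msa <- as_peptide_vector(msa)
  if (length(msa) < 2) stop("build_profile: need >= 2 aligned sequences")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) stop("build_profile: ragged alignment")
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  if (is.null(background)) background <- setNames(rep(1 / 20, 20), aa20)
  stopifnot(abs(sum(background) - 1) < 1e-6, all(aa20 %in% names(background)))
  bg <- background[aa20]
  chars <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  is_gap <- chars == "-" | chars == "."
  keep <- colMeans(is_gap) <= 0.5
  if (!any(keep)) stop("build_profile: all columns masked")
  chars <- chars[, keep, drop = FALSE]
  ncols <- ncol(chars)
  scores20 <- matrix(0, nrow = ncols, ncol = 20, dimnames = list(NULL, aa20))
  floor_score <- log(1e-4)  # cap for residues unseen at alpha -> 0
  for (j in seq_len(ncols)) {
    col <- chars[, j]
    col <- col[col %in% aa20]
    n <- length(col)
    cnt <- table(factor(col, levels = aa20))
    f <- (as.numeric(cnt) + alpha * bg) / (n + alpha)
    s <- log(f / bg)
    scores20[j, ] <- pmax(s, floor_score)
  }
  # extended alphabet (BLOSUM62 order) with neutral scores for B/Z/X/*
  full_alpha <- rownames(blosum62_neutral_x())
  scores <- matrix(0, nrow = ncols, ncol = length(full_alpha),
                   dimnames = list(NULL, full_alpha))
  scores[, aa20] <- scores20
  structure(list(scores = scores, ncols = ncols, background = bg,
                 alpha = alpha, nseq = length(msa),
                 kept_columns = which(keep)),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model: %d columns from %d sequences (alpha=%g)\n",
              x$ncols, x$nseq, x$alpha))
  invisible(x)
}

#' Search a protein database with a profile model
#'
#' Local profile-to-sequence alignment with affine gaps. Profile scores
#' are natural-log odds, so the Karlin-Altschul E-value uses `lambda = 1`
#' with the scheme's `K` left uncalibrated — E-values from profile
#' searches are ranked thresholds, not calibrated significance (see the
#' methods vignette).
#'
#' @param profile a [build_profile()] model.
#' @param db named peptides (character vector or `AAStringSet`).
#' @param e_cutoff keep hits with `evalue <= e_cutoff` (default `1e-5`,
#'   matching the profile-search cutoff used throughout the pipeline).
#' @param gap_open,gap_ext gap penalties in nats.
#' @param K Karlin-Altschul K reused from the default scheme.
#' @param seed_k prefilter: only sequences sharing an exact `seed_k`-mer
#'   with the profile consensus enter the dynamic programming (0
#'   disables; use 0 when probing very remote homology).
#' @return data.frame with `subject_id`, `score`, `bitscore`, `evalue`,
#'   `p_start`, `p_end`, `s_start`, `s_end` (0-based half-open), ordered
#'   by ascending E-value then subject id.
#' @export
profile_search <- function(profile, db, e_cutoff = 1e-5,
                           gap_open = 3, gap_ext = 0.3, K = 0.041,
                           seed_k = 5) {
  stopifnot(inherits(profile, "profile_model"))
  db <- as_peptide_vector(db)
  empty <- data.frame(subject_id = character(0), score = numeric(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      p_start = integer(0), p_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      stringsAsFactors = FALSE)
  if (length(db) == 0) return(empty)
  n_total <- sum(nchar(db))
  cand <- seq_along(db)
  if (seed_k > 0) {
    cons <- profile_consensus(profile)
    hit <- seed_candidate_pairs(setNames(cons, "consensus"), db, seed_k)
    cand <- sort(unique(hit$si))
    if (!length(cand)) return(empty)
  }
  scheme <- scoring_scheme()  # only for residue encoding order
  enc <- encode_peptides(db[cand], scheme)
  res <- t(vapply(enc, function(s) {
    profile_align_cpp(profile$scores, s, gap_open, gap_ext)
  }, numeric(5)))
  bits <- (res[, 1] - log(K)) / log(2)  # lambda = 1 on nat-scale scores
  ev <- evalue(pmax(bits, 0), profile$ncols, n_total)
  keep <- ev <= e_cutoff
  if (!any(keep)) return(empty)
  out <- data.frame(subject_id = names(db)[cand][keep],
                    score = res[keep, 1], bitscore = bits[keep],
                    evalue = ev[keep],
                    p_start = as.integer(res[keep, 2]),
                    p_end = as.integer(res[keep, 3]),
                    s_start = as.integer(res[keep, 4]),
                    s_end = as.integer(res[keep, 5]),
                    stringsAsFactors = FALSE)
  out[order(out$evalue, out$subject_id), , drop = FALSE]
}

#' Consensus sequence of a profile (highest-scoring residue per column)
#' @param profile a `profile_model`.
#' @return a peptide string of length `ncols`.
#' @export
profile_consensus <- function(profile) {
  aa20 <- names(profile$background)
  sc <- profile$scores[, aa20, drop = FALSE]
  paste(aa20[max.col(sc, ties.method = "first")], collapse = "")
}

#' Serialize a profile model to a text file
#'
#' Plain-text format: header lines (`# plvscout profile`, ncols, nseq,
#' alpha), one background line, then one whitespace-separated score row
#' per column over the 24-letter alphabet.
#'
#' @param profile a `profile_model`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# plvscout profile v1",
               sprintf("ncols\t%d", profile$ncols),
               sprintf("nseq\t%d", profile$nseq),
               sprintf("alpha\t%g", profile$alpha),
               paste(c("background", sprintf("%.8g", profile$background)),
                     collapse = "\t"),
               paste(c("alphabet", colnames(profile$scores)),
                     collapse = "\t")), con)
  write.table(format(profile$scores, digits = 8), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a serialized profile model
#' @param path file written by [write_profile()].
#' @return a `profile_model`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# plvscout profile"))
    stop("read_profile: not a plvscout profile file")
  fld <- function(key) strsplit(grep(paste0("^", key, "\t"), lines,
                                     value = TRUE)[1], "\t")[[1]][-1]
  ncols <- as.integer(fld("ncols"))
  nseq <- as.integer(fld("nseq"))
  alpha <- as.numeric(fld("alpha"))
  bg <- as.numeric(fld("background"))
  alphabet <- fld("alphabet")
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  names(bg) <- aa20
  body <- lines[(grep("^alphabet\t", lines)[1] + 1):length(lines)]
  scores <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"),
                                  as.numeric))
  colnames(scores) <- alphabet
  structure(list(scores = scores, ncols = ncols, background = bg,
                 alpha = alpha, nseq = nseq, kept_columns = NA),
            class = "profile_model")
}
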