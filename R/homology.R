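#' Optimal local alignment of two peptides
#'
#' Smith-Waterman local alignment with affine gaps under a
#' [scoring_scheme()]. Coordinates are 0-based half-open on both
#' sequences. Traceback ties are resolved deterministically
#' (diagonal > gap-in-subject > gap-in-query; anchor at the first maximal
#' cell in row-major order).
#'
#' @param query,subject peptide strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id identifiers carried into the hit record.
#' @param db_size effective database length for the E-value; defaults to
#'   `nchar(subject)`.
#' @return One-row data.frame with columns `query_id`, `subject_id`,
#'   `score`, `bitscore`, `evalue`, `pct_identity`, `aln_len`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        db_size = NULL) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1, length(subject) == 1)
  if (nchar(query) == 0 || nchar(subject) == 0)
    stop("local_align: empty sequence")
  enc <- encode_peptides(c(query, subject), scheme)
  v <- sw_align_pair_cpp(enc[[1]], enc[[2]], scheme$matrix,
                         scheme$gap_open, scheme$gap_ext)
  if (is.null(db_size)) db_size <- nchar(subject)
  bits <- bitscore(v[1], scheme)
  data.frame(
    query_id = query_id, subject_id = subject_id,
    score = v[1], bitscore = bits,
    evalue = evalue(bits, nchar(query), db_size),
    pct_identity = if (v[7] > 0) 100 * v[6] / v[7] else 0,
    aln_len = v[7], gap_opens = v[8],
    q_start = v[2], q_end = v[3], s_start = v[4], s_end = v[5],
    stringsAsFactors = FALSE)
}

# k-mer seed prefilter: candidate (query, subject) index pairs sharing at
# least one exact k-mer. Drastically cuts all-vs-all work; related
# proteins at the divergences this pipeline targets share many 4-mers.
seed_candidate_pairs <- function(queries, subjects, k) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- lapply(queries, kmers_of)
  sk <- lapply(subjects, kmers_of)
  qdf <- data.frame(kmer = unlist(qk, use.names = FALSE),
                    qi = rep.int(seq_along(qk), lengths(qk)))
  sdf <- data.frame(kmer = unlist(sk, use.names = FALSE),
                    si = rep.int(seq_along(sk), lengths(sk)))
  m <- merge(qdf, sdf, by = "kmer")
  unique(m[, c("qi", "si")])
}

#' Search a protein database with a set of queries
#'
#' All-vs-all local alignment (BLASTP-style) with an E-value cutoff.
#' A shared-k-mer seed prefilter skips hopeless pairs; set `seed_k = 0`
#' to force full dynamic programming on every pair. E-values use the
#' summed database length as `n`.
#'
#' @param queries,db named character vectors (or `AAStringSet`) of
#'   peptides; `db` must be non-empty.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff keep hits with `evalue <= e_cutoff`.
#' @param seed_k k-mer length for the seed prefilter (0 disables).
#' @param db_size effective database length (residues) for E-values;
#'   defaults to the summed length of `db` (override when searching a
#'   database in increments).
#' @param coords compute alignment coordinates and identities via a full
#'   traceback (default). `FALSE` skips the traceback pass -- scores and
#'   E-values only -- which is markedly faster for large all-vs-all
#'   searches where only significance matters.
#' @return data.frame of hits ordered by query, ascending E-value, then
#'   subject id; columns as in [local_align()].
#' @export
search_db <- function(queries, db, scheme = scoring_scheme(),
                      e_cutoff = 1e-5, seed_k = 4, db_size = NULL,
                      coords = TRUE) {
  queries <- as_peptide_vector(queries)
  db <- as_peptide_vector(db)
  stopifnot(length(db) >= 1)
  empty <- empty_hits()
  if (length(queries) == 0 || e_cutoff <= 0) return(empty)
  if (seed_k > 0) {
    pairs <- seed_candidate_pairs(queries, db, seed_k)
  } else {
    pairs <- expand.grid(qi = seq_along(queries), si = seq_along(db))
  }
  if (nrow(pairs) == 0) return(empty)
  enc_q <- encode_peptides(queries, scheme)
  enc_s <- encode_peptides(db, scheme)
  # fast score-only pass, then full traceback for surviving pairs only
  sc <- sw_score_batch_cpp(enc_q, enc_s, pairs$qi, pairs$si,
                           scheme$matrix, scheme$gap_open, scheme$gap_ext)
  n_db <- if (is.null(db_size)) sum(nchar(db)) else db_size
  ev <- evalue(bitscore(sc, scheme), nchar(queries)[pairs$qi], n_db)
  keep <- which(ev <= e_cutoff)
  if (!length(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  if (coords) {
    m <- sw_align_batch_cpp(enc_q, enc_s, pairs$qi, pairs$si,
                            scheme$matrix, scheme$gap_open, scheme$gap_ext)
  } else {
    m <- cbind(sc[keep], NA_integer_, NA_integer_, NA_integer_,
               NA_integer_, NA_integer_, NA_integer_, NA_integer_)
  }
  bits <- bitscore(m[, 1], scheme)
  hits <- data.frame(
    query_id = names(queries)[pairs$qi],
    subject_id = names(db)[pairs$si],
    score = m[, 1], bitscore = bits,
    evalue = evalue(bits, nchar(queries)[pairs$qi], n_db),
    pct_identity = ifelse(m[, 7] > 0, 100 * m[, 6] / m[, 7], NA_real_),
    aln_len = m[, 7], gap_opens = m[, 8],
    q_start = m[, 2], q_end = m[, 3],
    s_start = m[, 4], s_end = m[, 5],
    stringsAsFactors = FALSE)
  hits[order(hits$query_id, hits$evalue, hits$subject_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             score = numeric(0), bitscore = numeric(0), evalue = numeric(0),
             pct_identity = numeric(0), aln_len = integer(0),
             gap_opens = integer(0), q_start = integer(0),
             q_end = integer(0), s_start = integer(0), s_end = integer(0),
             stringsAsFactors = FALSE)
}

as_peptide_vector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    v <- as.character(x)
  } else {
    v <- as.character(x)
    names(v) <- names(x)
  }
  if (length(v) > 0 && is.null(names(v)))
    names(v) <- paste0("seq", seq_along(v))
  v
}

#' Write hits as BLAST outfmt-6 compatible TSV
#'
#' Standard 12 columns: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. Coordinates are converted to
#' the 1-based inclusive convention BLAST tabular output uses.
#'
#' @param hits hit data.frame from [search_db()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.3f", hits$pct_identity), length = hits$aln_len,
    mismatch = hits$aln_len - hits$gap_opens -
      round(hits$pct_identity * hits$aln_len / 100),
    gapopen = hits$gap_opens,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = sprintf("%.1f", hits$bitscore))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code; stop codons are rendered as `*`, ambiguous
#' codons as `X`.
#'
#' @param nt a nucleotide string (length >= 3) or `DNAString`.
#' @return Named character vector of 6 peptides, frames `+1 +2 +3 -1 -2 -3`.
#'   Frame `-k` starts at offset `k-1` on the reverse complement.
#' @export
translate_six_frames <- function(nt) {
  s <- Biostrings::DNAString(toupper(as.character(nt)))
  if (length(s) < 3) stop("translate_six_frames: sequence shorter than 3 nt")
  rc <- Biostrings::reverseComplement(s)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1, width = n),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  res <- c(one(s, 0), one(s, 1), one(s, 2), one(rc, 0), one(rc, 1), one(rc, 2))
  names(res) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  res
}
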