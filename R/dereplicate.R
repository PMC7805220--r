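# Nucleotide identity estimation by exact k-mer seeding and diagonal
# chaining -- a megablast-style sketch, not a full alignment. Identity is
# recovered from k-mer containment within the best co-linear chain:
# under independent substitutions a k-mer survives with probability
# id^k, so id ~ containment^(1/k).

kmer_positions <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(data.frame(kmer = character(0), pos = integer(0)))
  data.frame(kmer = substring(s, 1:(n - k + 1), k:n), pos = 0:(n - k),
             stringsAsFactors = FALSE)
}

#' Estimate nucleotide identity between two sequences
#'
#' Shared `k`-mers are chained on their best diagonal band; identity
#' within the chained region is `containment^(1/k)`, and a global
#' identity (CD-HIT's `-G 1` semantics) rescales by the fraction of the
#' shorter sequence the chain covers. With `circular = TRUE` the second
#' sequence is doubled so rotations of a circular genome match end to
#' end.
#'
#' @param query,ref DNA strings.
#' @param k k-mer size (default 12).
#' @param circular compare against the doubled reference.
#' @param band diagonal band half-width (bp) for chaining.
#' @return list: `local_identity`, `global_identity`,
#'   `coverage_longer` (chain span / longer sequence length), `n_seeds`.
#' @export
estimate_nt_identity <- function(query, ref, k = 12, circular = FALSE,
                                 band = 150) {
  query <- toupper(as.character(query)); ref <- toupper(as.character(ref))
  lq <- nchar(query); lr <- nchar(ref)
  ref2 <- if (circular) paste0(ref, ref) else ref
  none <- list(local_identity = 0, global_identity = 0,
               coverage_longer = 0, n_seeds = 0L)
  kq <- kmer_positions(query, k)
  kr <- kmer_positions(ref2, k)
  m <- merge(kq, kr, by = "kmer", suffixes = c("_q", "_r"))
  if (nrow(m) == 0) return(none)
  if (circular) m$pos_r <- m$pos_r %% lr
  diag <- m$pos_r - m$pos_q
  if (circular) diag <- diag %% lr
  bin <- round(diag / band)
  best_bin <- as.integer(names(which.max(table(bin))))
  keep <- abs(bin - best_bin) <= 1
  ch <- m[keep, , drop = FALSE]
  qpos <- unique(ch$pos_q)
  span <- max(qpos) - min(qpos) + k
  containment <- length(qpos) / max(1, span - k + 1)
  local_id <- min(1, containment)^(1 / k)
  shorter <- min(lq, lr)
  global_id <- local_id * min(1, span / shorter)
  list(local_identity = local_id, global_identity = global_id,
       coverage_longer = span / max(lq, lr), n_seeds = nrow(ch))
}

#' Greedy dereplication of genomes
#'
#' CD-HIT-style greedy clustering: genomes sorted by descending length
#' (ties by id) are compared to existing representatives and join the
#' first one meeting the round's identity rule; otherwise they found a
#' new cluster. Each round clusters the previous round's
#' representatives, so a two-round scheme (e.g. 0.9 local with 20%
#' coverage of the longer, then 0.7 global) mirrors the two-pass
#' dereplication used for public-database scaffolds. Defaults to a
#' single circular-aware global round at 70% identity.
#'
#' @param genomes named `DNAStringSet` or character vector.
#' @param rounds list of rounds; each a list with `identity` (0-1),
#'   `global` (TRUE: identity over the shorter sequence; FALSE: local
#'   identity plus `coverage` of the longer), `coverage` (required when
#'   `global = FALSE`), `circular` (rotation-aware comparison).
#' @param k seed k-mer size.
#' @return data.frame `contig_id, representative, cluster_id`; cluster
#'   ids are `CL_0001...` ordered by representative length descending.
#' @export
dereplicate <- function(genomes,
                        rounds = list(list(identity = 0.7, global = TRUE,
                                           coverage = NULL,
                                           circular = TRUE)),
                        k = 12) {
  seqs <- if (is.character(genomes)) genomes else as.character(genomes)
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  rep_of <- setNames(names(seqs), names(seqs))
  current <- names(seqs)
  for (round in rounds) {
    ord <- current[order(-nchar(seqs[current]), current)]
    reps <- character(0)
    for (id in ord) {
      joined <- FALSE
      for (r in reps) {
        est <- estimate_nt_identity(seqs[[id]], seqs[[r]], k = k,
                                    circular = isTRUE(round$circular))
        ok <- if (isTRUE(round$global)) {
          est$global_identity >= round$identity
        } else {
          est$local_identity >= round$identity &&
            est$coverage_longer >= round$coverage
        }
        if (ok) {
          rep_of[rep_of == id] <- r
          joined <- TRUE
          break
        }
      }
      if (!joined) reps <- c(reps, id)
    }
    current <- reps
  }
  reps_sorted <- current[order(-nchar(seqs[current]), current)]
  cl_ids <- setNames(sprintf("CL_%04d", seq_along(reps_sorted)), reps_sorted)
  data.frame(contig_id = names(rep_of),
             representative = unname(rep_of),
             cluster_id = unname(cl_ids[rep_of]),
             stringsAsFactors = FALSE, row.names = NULL)
}
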