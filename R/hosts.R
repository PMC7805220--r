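#' Call open reading frames on a contig
#'
#' All maximal ORFs (first in-frame ATG after the previous stop, through
#' the stop codon) of at least `min_aa` codons, on both strands,
#' longest first. Coordinates are reported on the forward axis, 0-based
#' half-open, spanning start codon through stop codon.
#'
#' @param contig DNA sequence (character or `DNAString`).
#' @param contig_id identifier for the gene calls.
#' @param min_aa minimum peptide length (codons, excluding the stop).
#' @return list: `genes` (canonical gene-table columns), `peptides`
#'   (named character, no stop character).
#' @export
call_orfs <- function(contig, contig_id = "contig", min_aa = 100) {
  s <- toupper(as.character(contig))
  L <- nchar(s)
  frames <- translate_six_frames(s)
  res <- list()
  for (fn in names(frames)) {
    pep <- frames[[fn]]
    if (nchar(pep) == 0) next
    off <- as.integer(substr(fn, 2, 2)) - 1L
    minus <- startsWith(fn, "-")
    ch <- strsplit(pep, "", fixed = TRUE)[[1]]
    stops <- c(0L, which(ch == "*"), length(ch) + 1L)
    for (i in seq_len(length(stops) - 1)) {
      lo <- stops[i] + 1L; hi <- stops[i + 1L]
      if (hi > length(ch)) next  # ORF must end in a stop codon
      seg <- ch[lo:(hi - 1L)]
      m <- which(seg == "M")[1]
      if (is.na(m)) next
      aa_start <- lo + m - 1L   # 1-based codon index of ATG in frame
      aa_len <- hi - aa_start   # codons incl. stop? no: hi is stop index
      if (aa_len - 0L < min_aa) next
      # frame coords (0-based nt on the translated strand), incl. stop
      nt_start <- off + 3L * (aa_start - 1L)
      nt_end <- off + 3L * hi
      if (minus) {
        g_start <- L - nt_end; g_end <- L - nt_start; strand <- "-"
      } else {
        g_start <- nt_start; g_end <- nt_end; strand <- "+"
      }
      res[[length(res) + 1]] <- list(
        start = g_start, end = g_end, strand = strand,
        pep = paste(ch[aa_start:(hi - 1L)], collapse = ""))
    }
  }
  if (!length(res)) {
    return(list(genes = data.frame(gene_id = character(0),
                                   contig_id = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0)),
                peptides = setNames(character(0), character(0))))
  }
  res <- res[order(-vapply(res, function(r) nchar(r$pep), integer(1)))]
  ids <- sprintf("%s_orf%02d", contig_id, seq_along(res))
  list(genes = data.frame(
    gene_id = ids, contig_id = contig_id,
    start = vapply(res, `[[`, integer(1), "start"),
    end = vapply(res, `[[`, integer(1), "end"),
    strand = vapply(res, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE),
    peptides = setNames(vapply(res, `[[`, character(1), "pep"), ids))
}

#' Screen transcriptome contigs for PLV capsid genes
#'
#' BLASTX-style search: each transcript is translated in all six frames
#' and aligned against the MCP database; the best hit per transcript is
#' kept if it reaches `e_cutoff` and covers at least `min_aa` aligned
#' residues (the length rule dominates: a short strong hit is rejected).
#' Accepted links carry the subject MCP's group label.
#'
#' @param transcripts `DNAStringSet` of transcriptome contigs.
#' @param mcp_db named MCP peptides (non-empty).
#' @param group_map named character: MCP id -> group label (optional).
#' @param e_cutoff E-value threshold (default `1e-10`).
#' @param min_aa minimum aligned length in residues (default 200).
#' @param scheme a [scoring_scheme()].
#' @return data.frame of host links: `transcript_id, mcp_subject_id,
#'   aligned_aa, evalue, bitscore, frame, assigned_group`.
#' @export
transcriptome_search <- function(transcripts, mcp_db, group_map = NULL,
                                 e_cutoff = 1e-10, min_aa = 200,
                                 scheme = scoring_scheme()) {
  mcp_db <- as_peptide_vector(mcp_db)
  stopifnot(length(mcp_db) > 0)
  links <- list()
  for (tid in names(transcripts)) {
    frames <- translate_six_frames(as.character(transcripts[[tid]]))
    frames <- frames[nchar(frames) > 0]
    hits <- search_db(frames, mcp_db, scheme, e_cutoff = Inf)
    hits <- hits[hits$evalue <= e_cutoff & hits$aln_len >= min_aa, ,
                 drop = FALSE]
    if (nrow(hits) == 0) next
    best <- hits[which.min(hits$evalue), ]
    grp <- if (!is.null(group_map)) group_map[[best$subject_id]]
           else NA_character_
    links[[length(links) + 1]] <- data.frame(
      transcript_id = tid, mcp_subject_id = best$subject_id,
      aligned_aa = best$aln_len, evalue = best$evalue,
      bitscore = best$bitscore, frame = best$query_id,
      assigned_group = if (is.null(grp)) NA_character_ else grp,
      stringsAsFactors = FALSE)
  }
  if (!length(links)) {
    return(data.frame(transcript_id = character(0),
                      mcp_subject_id = character(0),
                      aligned_aa = integer(0), evalue = numeric(0),
                      bitscore = numeric(0), frame = character(0),
                      assigned_group = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, links)
}
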