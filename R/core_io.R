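#' Read a FASTA file of contigs or proteins
#'
#' Identifiers are truncated at the first whitespace and sequences are
#' uppercased on read. All coordinates elsewhere in the package are
#' 0-based half-open.
#'
#' @param path FASTA file.
#' @param type `"dna"`, `"protein"`, or `"auto"` (guess from residue
#'   content of the first record).
#' @return A `DNAStringSet` or `AAStringSet`, in file order.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0)
    return(if (type == "protein") Biostrings::AAStringSet()
           else Biostrings::DNAStringSet())
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(nchar(seqs) == 0))
    stop("read_fasta: empty sequence at record ",
         which(nchar(seqs) == 0)[1], " (", ids[which(nchar(seqs) == 0)[1]], ")")
  if (anyDuplicated(ids))
    stop("read_fasta: duplicated id: ", ids[anyDuplicated(ids)])
  if (type == "auto") {
    probe <- paste(utils::head(seqs, 5), collapse = "")
    frac_nt <- mean(strsplit(probe, "")[[1]] %in% c("A", "C", "G", "T", "N"))
    type <- if (frac_nt > 0.95) "dna" else "protein"
  }
  out <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#' @param seqs named `XStringSet` or character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

gene_table_cols <- c("gene_id", "contig_id", "start", "end", "strand")

#' Write a gene table as TSV
#'
#' Columns `gene_id, contig_id, start, end, strand`; coordinates 0-based
#' half-open. Peptides travel separately in a protein FASTA keyed by
#' `gene_id`.
#'
#' @param genes data.frame of gene calls (may be empty).
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  stopifnot(all(gene_table_cols %in% names(genes)) || nrow(genes) == 0)
  if (nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
  }
  write.table(genes[, gene_table_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene table written by [write_gene_table()]
#' @param path TSV file.
#' @return data.frame with the canonical columns.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(gene_id = "character",
                                 contig_id = "character",
                                 start = "integer", end = "integer",
                                 strand = "character"))
  bad <- which(!(g$start >= 0 & g$start < g$end))
  if (length(bad))
    stop("read_gene_table: invalid coordinates at row ", bad[1])
  g
}

alignment_cols <- c("read_id", "mate_index", "contig_id", "start", "end",
                    "strand", "mate_contig_id", "mate_start", "proper_pair",
                    "sample")

#' Read alignment records
#'
#' Two dialects: the pipeline's 10-column truth TSV (as emitted by the
#' synthetic community generator) and plain-text SAM. Unmapped records
#' are skipped; SAM's 1-based closed coordinates are converted to 0-based
#' half-open at this boundary, with the reference span derived from the
#' CIGAR string (M/D/N/=/X operations).
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"sam"`.
#' @param sample fraction label attached to SAM records (`tsv` carries its
#'   own `sample` column).
#' @param contig_lengths optional named vector; records extending beyond
#'   the contig raise an error naming the offending line.
#' @return data.frame with columns
#'   `read_id, mate_index, contig_id, start, end, strand, mate_contig_id,
#'   mate_start, proper_pair, sample`.
#' @export
read_alignments <- function(path, dialect = c("tsv", "sam"),
                            sample = NA_character_, contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  aln <- if (dialect == "tsv") read_alignments_tsv(path)
         else read_alignments_sam(path, sample)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[aln$contig_id]
    bad <- which(is.na(lim) | aln$end > lim)
    if (length(bad))
      stop("read_alignments: record ", bad[1], " (read ",
           aln$read_id[bad[1]], ") extends beyond contig ",
           aln$contig_id[bad[1]])
  }
  aln
}

read_alignments_tsv <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(alignment_cols, names(a))
  if (length(missing))
    stop("read_alignments: truth TSV lacks columns: ",
         paste(missing, collapse = ", "))
  a$proper_pair <- as.logical(a$proper_pair)
  a[, alignment_cols]
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

read_alignments_sam <- function(path, sample) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(data.frame(read_id = character(0), mate_index = integer(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mate_contig_id = character(0), mate_start = integer(0),
                      proper_pair = logical(0), sample = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop("read_alignments: SAM line ", which(nf < 11)[1],
         " has fewer than 11 fields")
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  f <- f[mapped]; flag <- flag[mapped]
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  cig <- vapply(f, function(x) x[6], character(1))
  rnext <- vapply(f, function(x) x[7], character(1))
  rname <- vapply(f, function(x) x[3], character(1))
  span <- cigar_ref_span(cig)
  data.frame(
    read_id = vapply(f, function(x) x[1], character(1)),
    mate_index = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                        ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)),
    contig_id = rname,
    start = pos - 1L,
    end = pos - 1L + span,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mate_contig_id = ifelse(rnext == "=", rname,
                            ifelse(rnext == "*", NA_character_, rnext)),
    mate_start = ifelse(bitwAnd(flag, 8L) > 0L, NA_integer_,
                        vapply(f, function(x) as.integer(x[8]),
                               integer(1)) - 1L),
    proper_pair = bitwAnd(flag, 2L) > 0L,
    sample = sample,
    stringsAsFactors = FALSE)
}

#' Write alignment records in the truth TSV dialect
#' @param aln alignment data.frame.
#' @param path output file.
#' @export
write_alignments <- function(aln, path) {
  stopifnot(all(alignment_cols %in% names(aln)))
  write.table(aln[, alignment_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
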