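#' Mean read coverage of a contig
#'
#' Sum of aligned bases divided by contig length (reads per base).
#'
#' @param aln alignment records for this contig (truth-TSV columns).
#' @param contig_length contig length in bp (> 0).
#' @return numeric coverage depth.
#' @export
mean_coverage <- function(aln, contig_length) {
  if (contig_length <= 0) stop("mean_coverage: zero-length contig")
  if (is.null(aln) || nrow(aln) == 0) return(0)
  sum(aln$end - aln$start) / contig_length
}

#' Detect a circular genome (or terminal repeat) from read mappings
#'
#' Applies the completeness rule for contigs over `min_len`: collect
#' non-proper pairs with one mate inside the first `window` bp and the
#' other inside the last `window` bp. If the coverage depth of those
#' end-linking mates within the two terminal windows exceeds (strictly)
#' `depth_frac` times the mean contig coverage, the contig is flagged:
#' `circular` when the pair orientations are wrap-around (the 5'-window
#' mate on `-`, the 3'-window mate on `+`, i.e. the innie pair a mapper
#' reports for a fragment crossing the origin), `terminal_repeat` when
#' the evidence pairs are in same-layout orientation instead.
#'
#' @param contig_id contig to examine.
#' @param contig_length its length (bp).
#' @param aln alignment records (any contigs; filtered internally).
#' @param window terminal window size (bp).
#' @param depth_frac threshold as a fraction of mean coverage (strict >).
#' @param min_len rule applies to contigs of at least this length.
#' @return One-row data.frame: `contig_id, status, repeat_kind,
#'   support_pairs, support_depth, mean_coverage, reason`.
#' @export
detect_circular <- function(contig_id, contig_length, aln,
                            window = 1000, depth_frac = 0.10,
                            min_len = 10000) {
  a <- aln[aln$contig_id == contig_id, , drop = FALSE]
  mc <- mean_coverage(a, contig_length)
  call <- function(status, kind, pairs, depth, reason) {
    data.frame(contig_id = contig_id, status = status, repeat_kind = kind,
               support_pairs = pairs, support_depth = depth,
               mean_coverage = mc, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (contig_length < min_len)
    return(call("linear", "none", 0L, 0, "below_min_len"))
  disc <- a[!a$proper_pair, , drop = FALSE]
  if (nrow(disc) == 0)
    return(call("linear", "none", 0L, 0, "no_discordant_pairs"))
  in_start <- disc$start < window
  in_end <- disc$end > contig_length - window
  # pair up mates by read id; keep pairs linking opposite ends
  by_read <- split(seq_len(nrow(disc)), disc$read_id)
  link <- vapply(by_read, function(ix) {
    any(in_start[ix] & !in_end[ix]) && any(in_end[ix] & !in_start[ix])
  }, logical(1))
  ix <- unlist(by_read[link], use.names = FALSE)
  n_pairs <- sum(link)
  if (n_pairs == 0)
    return(call("linear", "none", 0L, 0, "no_end_linking_pairs"))
  ev <- disc[ix, , drop = FALSE]
  depth <- sum(ev$end - ev$start) / (2 * window)
  if (!(depth > depth_frac * mc))
    return(call("linear", "none", n_pairs, depth, "below_depth_threshold"))
  # orientation vote: wrap-around = 5'-window mate '-', 3'-window mate '+'
  ev_start <- ev$start < window
  ev_end <- ev$end > contig_length - window
  wrapish <- sum(ev$strand[ev_start & !ev_end] == "-") +
    sum(ev$strand[ev_end & !ev_start] == "+")
  samish <- sum(ev$strand[ev_start & !ev_end] == "+") +
    sum(ev$strand[ev_end & !ev_start] == "-")
  if (wrapish >= samish)
    call("circular", "none", n_pairs, depth, "wrap_orientation")
  else
    call("terminal_repeat", "direct", n_pairs, depth, "same_orientation")
}

#' Detect terminal direct or inverted repeats by sequence self-comparison
#'
#' Compares the first `T` bp of a contig against the last `T` bp
#' (`T = min(2000, length/2)`), both directly and against the reverse
#' complement, and reports the longest terminal repeat of at least
#' `min_len` bp at `min_identity` percent identity or better. Inverted
#' repeats win ties (they are the expected signature of complete
#' Polinton-like elements).
#'
#' @param contig sequence (character or `DNAString`).
#' @param contig_id identifier for the report.
#' @param min_len minimum repeat length (bp).
#' @param min_identity minimum percent identity of the repeat.
#' @return One-row data.frame: `contig_id, repeat_kind`
#'   (`inverted`/`direct`/`none`), `repeat_len, repeat_identity,
#'   left_start, left_end, right_start, right_end` (0-based half-open).
#' @export
detect_terminal_repeats <- function(contig, contig_id = "contig",
                                    min_len = 20, min_identity = 95) {
  s <- toupper(as.character(contig))
  L <- nchar(s)
  if (L < 2 * min_len)
    stop("detect_terminal_repeats: contig shorter than 2*min_len")
  T <- min(2000L, L %/% 2L)
  pre <- strsplit(substr(s, 1, T), "")[[1]]
  none <- data.frame(contig_id = contig_id, repeat_kind = "none",
                     repeat_len = 0L, repeat_identity = NA_real_,
                     left_start = NA_integer_, left_end = NA_integer_,
                     right_start = NA_integer_, right_end = NA_integer_,
                     stringsAsFactors = FALSE)

  # inverted: a TIR of length t means prefix[i] == complement(s[L+1-i]),
  # i.e. prefix aligns position-wise with revcomp(s)[1..t]. Among lengths
  # meeting the identity floor, take the score-maximal boundary
  # (match +1 / mismatch -9, break-even at 90% identity) so the call
  # does not drift past the repeat end on chance matches.
  rc_head <- strsplit(substr(revcomp_chr(s), 1, T), "")[[1]]
  eq <- pre == rc_head
  cum_id <- cumsum(eq) / seq_len(T)
  score <- cumsum(ifelse(eq, 1L, -9L))
  ok <- which(eq & cum_id >= min_identity / 100 & seq_len(T) >= min_len)
  inv_len <- if (length(ok)) ok[which.max(score[ok])] else 0L
  inv_id <- if (inv_len > 0) 100 * cum_id[inv_len] else NA_real_

  # direct: prefix_t == suffix_t; the alignment offset depends on t, so
  # seed with the first 12 bp of the prefix and verify each occurrence
  dir_len <- 0L; dir_id <- NA_real_
  seed_w <- min(12L, min_len)
  tailreg <- substr(s, L - T + 1, L)
  mp <- Biostrings::matchPattern(substr(s, 1, seed_w),
                                 Biostrings::DNAString(tailreg))
  for (p in BiocGenerics::start(mp)) {
    t_cand <- T - p + 1L  # repeat length if suffix starts here
    if (t_cand < min_len || t_cand <= dir_len) next
    suf <- strsplit(substr(s, L - t_cand + 1, L), "")[[1]]
    eqd <- pre[seq_len(t_cand)] == suf
    idd <- mean(eqd)
    if (idd >= min_identity / 100 && eqd[t_cand]) {
      dir_len <- t_cand; dir_id <- 100 * idd
    }
  }

  if (inv_len == 0 && dir_len == 0) return(none)
  if (inv_len >= dir_len) {
    data.frame(contig_id = contig_id, repeat_kind = "inverted",
               repeat_len = inv_len, repeat_identity = inv_id,
               left_start = 0L, left_end = inv_len,
               right_start = L - inv_len, right_end = L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(contig_id = contig_id, repeat_kind = "direct",
               repeat_len = dir_len, repeat_identity = dir_id,
               left_start = 0L, left_end = dir_len,
               right_start = L - dir_len, right_end = L,
               stringsAsFactors = FALSE)
  }
}

#' Detect a target-site duplication flanking an insertion
#'
#' Returns the longest exact duplication of the host motif immediately
#' left of the insertion start and immediately right of the insertion
#' end, scanning lengths from `len_range[2]` down to `len_range[1]`
#' (longest first). Matching is exact: at 5-7 bp, mismatch tolerance
#' would be meaningless.
#'
#' @param host host contig sequence (character or `DNAString`).
#' @param ins_start,ins_end 0-based half-open insertion interval, interior
#'   to the host with flanks of at least `len_range[2]` bp.
#' @param len_range TSD length bounds (default 5-7 bp).
#' @return the duplicated motif, or `NA_character_` if none.
#' @export
detect_tsd <- function(host, ins_start, ins_end, len_range = c(5, 7)) {
  s <- toupper(as.character(host))
  L <- nchar(s)
  kmax <- len_range[2]
  if (ins_start < kmax || ins_end + kmax > L)
    stop("detect_tsd: insertion too close to contig edge")
  for (k in seq(len_range[2], len_range[1])) {
    left <- substr(s, ins_start - k + 1, ins_start)
    right <- substr(s, ins_end + 1, ins_end + k)
    if (left == right) return(left)
  }
  NA_character_
}

#' Completeness calls for a whole assembly
#'
#' Runs [detect_circular()] and [detect_terminal_repeats()] on every
#' contig and combines them: wrap-orientation read evidence wins
#' (`circular`), otherwise a sequence-level terminal repeat (or
#' same-orientation read evidence) yields `terminal_repeat`, else
#' `linear`.
#'
#' @param contigs `DNAStringSet` of contigs.
#' @param aln alignment records.
#' @param window,depth_frac,min_len passed to [detect_circular()].
#' @param repeat_min_len,repeat_min_identity passed to
#'   [detect_terminal_repeats()].
#' @return data.frame, one row per contig: circularity call merged with
#'   repeat detection (`status`, `repeat_kind`, coordinates, support).
#' @export
call_completeness <- function(contigs, aln, window = 1000,
                              depth_frac = 0.10, min_len = 10000,
                              repeat_min_len = 20,
                              repeat_min_identity = 95) {
  lens <- Biostrings::width(contigs)
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    cid <- names(contigs)[i]
    circ <- detect_circular(cid, lens[i], aln, window, depth_frac, min_len)
    rep <- detect_terminal_repeats(as.character(contigs[[i]]), cid,
                                   repeat_min_len, repeat_min_identity)
    status <- circ$status
    kind <- rep$repeat_kind
    if (status != "circular" && kind != "none") status <- "terminal_repeat"
    out[[i]] <- data.frame(
      contig_id = cid, status = status, repeat_kind = kind,
      repeat_len = rep$repeat_len, repeat_identity = rep$repeat_identity,
      left_start = rep$left_start, left_end = rep$left_end,
      right_start = rep$right_start, right_end = rep$right_end,
      support_pairs = circ$support_pairs,
      support_depth = circ$support_depth,
      mean_coverage = circ$mean_coverage,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
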