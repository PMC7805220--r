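#' Normalized coverage of a contig in one metagenome
#'
#' Mean coverage depth divided by the metagenome size in Gb
#' ("coverage per Gb"), the normalization that makes recruitment
#' comparable across metagenomes of different sizes.
#'
#' @param aln alignment records of one fraction, restricted to the contig.
#' @param contig_length bp.
#' @param metagenome_gb total size of that fraction's metagenome (Gb, > 0).
#' @return coverage per Gb.
#' @export
normalized_coverage <- function(aln, contig_length, metagenome_gb) {
  stopifnot(metagenome_gb > 0)
  mean_coverage(aln, contig_length) / metagenome_gb
}

#' Per-contig viral/microbial enrichment profiles
#'
#' For every contig: normalized coverage in each size fraction, fold
#' enrichment `cov_viral / cov_microbial` (flagged `viral_only` when the
#' microbial coverage is zero), the share of normalized recruitment from
#' the viral fraction, and recruited Mb per Gb per fraction. Contigs with
#' zero coverage in both fractions have undefined fold and share.
#'
#' @param aln alignment records with a `sample` column
#'   (`viral`/`microbial`).
#' @param contig_lengths named vector.
#' @param fraction_gb named vector (`viral`, `microbial`) of metagenome
#'   sizes in Gb.
#' @return data.frame, one row per contig: `contig_id, cov_per_gb_viral,
#'   cov_per_gb_microbial, fold_enrichment, viral_only, viral_read_share,
#'   mb_per_gb_viral, mb_per_gb_microbial`.
#' @export
fold_enrichment <- function(aln, contig_lengths, fraction_gb) {
  ids <- names(contig_lengths)
  ab <- function(fraction) {
    a <- aln[aln$sample == fraction, , drop = FALSE]
    v <- tapply(a$end - a$start, factor(a$contig_id, levels = ids), sum)
    v[is.na(v)] <- 0
    v
  }
  bases_v <- ab("viral"); bases_m <- ab("microbial")
  cov_v <- (bases_v / contig_lengths) / fraction_gb[["viral"]]
  cov_m <- (bases_m / contig_lengths) / fraction_gb[["microbial"]]
  viral_only <- cov_m == 0 & cov_v > 0
  fold <- ifelse(cov_m > 0, cov_v / cov_m, NA_real_)
  share <- ifelse(cov_v + cov_m > 0, cov_v / (cov_v + cov_m), NA_real_)
  data.frame(contig_id = ids,
             cov_per_gb_viral = unname(cov_v),
             cov_per_gb_microbial = unname(cov_m),
             fold_enrichment = unname(fold),
             viral_only = unname(viral_only),
             viral_read_share = unname(share),
             mb_per_gb_viral = unname(bases_v / 1e6 / fraction_gb[["viral"]]),
             mb_per_gb_microbial =
               unname(bases_m / 1e6 / fraction_gb[["microbial"]]),
             stringsAsFactors = FALSE)
}

#' Population summary of enrichment profiles
#'
#' Median and range of defined fold enrichments (viral-only contigs are
#' counted separately, not ranked), and the percentage of contigs
#' recruiting at least `share_threshold` of their normalized reads from
#' the viral fraction.
#'
#' @param profiles output of [fold_enrichment()].
#' @param share_threshold viral-read-share threshold (default 0.95).
#' @return list: `n`, `median_fold`, `fold_range`, `n_viral_only`,
#'   `pct_share_ge_threshold`, `total_mb_per_gb_viral`,
#'   `total_mb_per_gb_microbial`.
#' @export
summarize_enrichment <- function(profiles, share_threshold = 0.95) {
  stopifnot(nrow(profiles) >= 1)
  folds <- profiles$fold_enrichment[!is.na(profiles$fold_enrichment)]
  share <- profiles$viral_read_share
  list(n = nrow(profiles),
       median_fold = if (length(folds)) median(folds) else NA_real_,
       fold_range = if (length(folds)) range(folds) else c(NA_real_, NA_real_),
       n_viral_only = sum(profiles$viral_only),
       pct_share_ge_threshold =
         100 * mean(share >= share_threshold, na.rm = TRUE),
       total_mb_per_gb_viral = sum(profiles$mb_per_gb_viral),
       total_mb_per_gb_microbial = sum(profiles$mb_per_gb_microbial))
}

#' Group-level recruitment in Mb per Gb
#'
#' Total aligned bases across the group's members, in Mb, per Gb of
#' metagenome. Additive over disjoint member sets.
#'
#' @param members contig ids of the group (non-empty).
#' @param aln alignment records of one fraction.
#' @param metagenome_gb fraction size (Gb).
#' @return Mb recruited per Gb.
#' @export
group_recruitment <- function(members, aln, metagenome_gb) {
  stopifnot(length(members) > 0, metagenome_gb > 0)
  a <- aln[aln$contig_id %in% members, , drop = FALSE]
  sum(a$end - a$start) / 1e6 / metagenome_gb
}
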