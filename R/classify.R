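#' Configuration of the PLV/virophage decision procedure
#'
#' Thresholds of the three-criterion flagging and confirmation rules:
#' a putative PLV requires (1) at least `hit_fraction` of the contig's
#' predicted genes hitting the virophage bait database at
#' `blast_e`, (2) contig length within `putative_len` (inclusive), and
#' (3) no virophage MCP detected. Confirmation additionally requires
#' length within `confirmed_len` and an MCP gene identified (a profile
#' hit at `profile_e`, the package's stand-in for remote-homology
#' annotation). The hit fraction counts distinct genes with at least one
#' hit, not hit multiplicity.
#'
#' @param hit_fraction minimum fraction of genes hitting the bait db.
#' @param putative_len,confirmed_len inclusive length windows (bp);
#'   `confirmed_len` must lie within `putative_len`.
#' @param blast_e,profile_e E-value cutoffs for sequence and profile
#'   searches.
#' @param max_iterations bait-expansion iteration cap.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(hit_fraction = 0.20,
                              putative_len = c(10000, 45000),
                              confirmed_len = c(10000, 41000),
                              blast_e = 1e-5, profile_e = 1e-5,
                              max_iterations = 5) {
  stopifnot(hit_fraction > 0, hit_fraction <= 1,
            putative_len[1] <= putative_len[2],
            confirmed_len[1] <= confirmed_len[2],
            confirmed_len[1] >= putative_len[1],
            confirmed_len[2] <= putative_len[2],
            blast_e > 0, profile_e > 0, max_iterations >= 1)
  structure(as.list(environment()), class = "classifier_config")
}

#' Does a contig carry a virophage MCP?
#'
#' TRUE iff at least one of the contig's genes hits the virophage MCP
#' database (hits already filtered at the configured E cutoff).
#'
#' @param gene_ids genes predicted on the contig.
#' @param vmcp_hits hit table of all genes vs the virophage MCP database.
#' @return logical scalar.
#' @export
flag_virophage <- function(gene_ids, vmcp_hits) {
  any(gene_ids %in% vmcp_hits$query_id)
}

#' Apply the three-criterion putative-PLV rule to one contig
#'
#' @param contig_id contig identifier.
#' @param length contig length (bp).
#' @param gene_ids genes predicted on the contig (may be empty).
#' @param bait_hits hit table (all genes vs bait db, at `cfg$blast_e`).
#' @param virophage_mcp_found result of [flag_virophage()].
#' @param cfg a [classifier_config()].
#' @return one-row data.frame (`classification_result` columns): label is
#'   `putative_PLV`, `virophage`, or `rejected` with the failing
#'   criterion in `reason`.
#' @export
flag_putative_plv <- function(contig_id, length, gene_ids, bait_hits,
                              virophage_mcp_found, cfg = classifier_config()) {
  n_genes <- length(gene_ids)
  n_hit <- length(intersect(gene_ids, unique(bait_hits$query_id)))
  frac <- if (n_genes > 0) n_hit / n_genes else NA_real_
  row <- data.frame(
    contig_id = contig_id, label = "rejected",
    hit_fraction_observed = frac, n_genes = n_genes, n_hit_genes = n_hit,
    mcp_gene_id = NA_character_, mcp_method = "none",
    fallback_core = FALSE, iteration_found = NA_integer_,
    reason = NA_character_, stringsAsFactors = FALSE)
  if (virophage_mcp_found) {
    row$label <- "virophage"; row$reason <- "virophage_mcp_present"
    return(row)
  }
  if (n_genes == 0) { row$reason <- "no_genes"; return(row) }
  if (frac < cfg$hit_fraction) { row$reason <- "hit_fraction"; return(row) }
  if (length < cfg$putative_len[1] || length > cfg$putative_len[2]) {
    row$reason <- "length"; return(row)
  }
  row$label <- "putative_PLV"
  row
}

#' Confirm a putative PLV
#'
#' Confirmation requires the putative hit fraction, length within the
#' confirmed window (10-41 kb by default), and an identified MCP gene:
#' a direct hit to a known PLV MCP (`mcp_method = "blast"`) or a profile
#' hit at `cfg$profile_e` (`mcp_method = "profile"`). A putative contig
#' with ATPase and minor-capsid evidence but no MCP is retained as
#' putative with `fallback_core = TRUE`, never confirmed.
#'
#' @param result a one-row putative result from [flag_putative_plv()].
#' @param length contig length (bp).
#' @param mcp_blast_hits hits of the contig's genes vs known PLV MCPs
#'   (may be empty).
#' @param mcp_profile_hits data.frame with `subject_id` = gene ids hit by
#'   any MCP profile at `cfg$profile_e` (may be empty).
#' @param core_hits list with elements `ATPase` and `mCP`, each a hit
#'   table of genes vs the respective core-gene database.
#' @param gene_ids genes on the contig.
#' @param cfg a [classifier_config()].
#' @return the updated one-row result (label `confirmed_PLV` or
#'   `putative_PLV`).
#' @export
confirm_plv <- function(result, length, mcp_blast_hits, mcp_profile_hits,
                        core_hits, gene_ids, cfg = classifier_config()) {
  stopifnot(result$label == "putative_PLV")
  mcp_gene <- NA_character_; method <- "none"
  bl <- mcp_blast_hits[mcp_blast_hits$query_id %in% gene_ids, , drop = FALSE]
  if (nrow(bl) > 0) {
    mcp_gene <- bl$query_id[which.min(bl$evalue)]; method <- "blast"
  } else {
    pr <- mcp_profile_hits[mcp_profile_hits$subject_id %in% gene_ids, ,
                           drop = FALSE]
    if (nrow(pr) > 0) {
      mcp_gene <- pr$subject_id[which.min(pr$evalue)]; method <- "profile"
    }
  }
  result$mcp_gene_id <- mcp_gene
  result$mcp_method <- method
  len_ok <- length >= cfg$confirmed_len[1] && length <= cfg$confirmed_len[2]
  if (!is.na(mcp_gene) && len_ok) {
    result$label <- "confirmed_PLV"
  } else if (is.na(mcp_gene)) {
    has_atp <- any(gene_ids %in% core_hits$ATPase$query_id)
    has_mcp_minor <- any(gene_ids %in% core_hits$mCP$query_id)
    result$fallback_core <- has_atp && has_mcp_minor
    result$reason <- "no_mcp"
  } else {
    result$reason <- "length_confirmed"
  }
  result
}

#' Classify every contig of an assembly against a fixed bait database
#'
#' One pass of the decision procedure: search all proteins against the
#' virophage MCP database, the bait database, known PLV MCPs, the core
#' databases, and the MCP profile library, then apply the putative and
#' confirmation rules per contig. Pure function of its inputs; input
#' order never changes labels.
#'
#' @param contigs `DNAStringSet`.
#' @param genes gene table (canonical columns).
#' @param proteins named peptides (names = gene ids).
#' @param bait_db named peptides of the bait database.
#' @param reference list with `vmcp_db`, `plv_mcp_db`, `core_dbs`
#'   (list `ATPase`, `mCP`), `mcp_profiles` (list of profile models), as
#'   produced by [generate_community()] (or assembled from real data).
#' @param cfg a [classifier_config()].
#' @param scheme a [scoring_scheme()].
#' @param static_hits precomputed bait-independent searches (internal
#'   reuse across bait-expansion iterations); `NULL` computes them.
#' @param bait_hits precomputed hits vs `bait_db`; `NULL` computes them.
#' @return data.frame of classification results, one row per contig.
#' @export
classify_contigs <- function(contigs, genes, proteins, bait_db, reference,
                             cfg = classifier_config(),
                             scheme = scoring_scheme(),
                             static_hits = NULL, bait_hits = NULL) {
  if (is.null(static_hits))
    static_hits <- reference_searches(proteins, reference, cfg, scheme)
  if (is.null(bait_hits))
    bait_hits <- search_db(proteins, bait_db, scheme, cfg$blast_e,
                           coords = FALSE)
  lens <- setNames(Biostrings::width(contigs), names(contigs))
  out <- lapply(names(contigs), function(cid) {
    gid <- genes$gene_id[genes$contig_id == cid]
    vf <- flag_virophage(gid, static_hits$vmcp)
    row <- flag_putative_plv(cid, lens[[cid]], gid, bait_hits, vf, cfg)
    if (row$label == "putative_PLV")
      row <- confirm_plv(row, lens[[cid]], static_hits$mcp_blast,
                         static_hits$profile, static_hits$core, gid, cfg)
    row
  })
  do.call(rbind, out)
}

# bait-independent searches of the decision procedure, computed once
reference_searches <- function(proteins, reference, cfg, scheme) {
  prof <- do.call(rbind, lapply(reference$mcp_profiles, function(p)
    profile_search(p, proteins, e_cutoff = cfg$profile_e)))
  if (is.null(prof))
    prof <- data.frame(subject_id = character(0), evalue = numeric(0))
  list(vmcp = search_db(proteins, reference$vmcp_db, scheme, cfg$blast_e,
                        coords = FALSE),
       mcp_blast = search_db(proteins, reference$plv_mcp_db, scheme,
                             cfg$blast_e, coords = FALSE),
       core = lapply(reference$core_dbs, function(db)
         search_db(proteins, db, scheme, cfg$blast_e, coords = FALSE)),
       profile = prof)
}

#' Iterative bait expansion
#'
#' The discovery loop: classify against the current bait database, append
#' the genes of newly confirmed contigs to the bait, and repeat until no
#' new contig is confirmed (fixed point) or `cfg$max_iterations`. Results
#' record the iteration of first confirmation; the confirmed set never
#' shrinks across iterations and the fixed point does not depend on
#' contig order.
#'
#' @inheritParams classify_contigs
#' @param seed_db the initial bait database (non-empty, named peptides).
#' @return list with `results` (classification data.frame, one row per
#'   contig, `iteration_found` set for confirmed contigs), `bait_db`
#'   (final bait database), `iterations` (number executed), `converged`.
#' @export
bait_expand <- function(contigs, genes, proteins, seed_db, reference,
                        cfg = classifier_config(),
                        scheme = scoring_scheme()) {
  stopifnot(length(seed_db) > 0)
  if (length(contigs) == 0)
    return(list(results = NULL, bait_db = seed_db, iterations = 0L,
                converged = TRUE))
  bait <- seed_db
  confirmed <- character(0)
  results <- NULL
  it <- 0L
  converged <- FALSE
  iter_found <- integer(0)
  static_hits <- reference_searches(proteins, reference, cfg, scheme)
  # the bait only grows, so each iteration searches the new portion and
  # accumulates the hit table
  bait_hits <- empty_hits()
  new_bait <- bait
  while (it < cfg$max_iterations) {
    it <- it + 1L
    if (length(new_bait) > 0)
      bait_hits <- rbind(bait_hits,
                         search_db(proteins, new_bait, scheme, cfg$blast_e,
                                   db_size = sum(nchar(bait)),
                                   coords = FALSE))
    results <- classify_contigs(contigs, genes, proteins, bait, reference,
                                cfg, scheme, static_hits, bait_hits)
    now <- results$contig_id[results$label == "confirmed_PLV"]
    new <- setdiff(now, confirmed)
    iter_found[new] <- it
    confirmed <- union(confirmed, now)
    if (length(new) == 0) { converged <- TRUE; break }
    add <- proteins[genes$gene_id[genes$contig_id %in% new]]
    new_bait <- add[!names(add) %in% names(bait)]
    bait <- c(bait, new_bait)
    # nothing new to search with: already at the fixed point
    if (length(new_bait) == 0) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bait_expand: no fixed point after ", cfg$max_iterations,
            " iterations; returning partial results")
  results$iteration_found <- unname(iter_found[results$contig_id])
  list(results = results, bait_db = bait, iterations = it,
       converged = converged)
}
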