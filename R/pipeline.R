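#' Run the detection stage on a community
#'
#' Composes the discovery procedure end to end: iterative bait expansion
#' from the seed database ([bait_expand()]), then completeness calls for
#' every contig ([call_completeness()]) and target-site-duplication
#' checks at known integration coordinates.
#'
#' @param community a [generate_community()] result (or an equivalent
#'   list assembled from files via the `core_io` readers).
#' @param cfg a [classifier_config()].
#' @param scheme a [scoring_scheme()].
#' @return list: `classification` (with truth-independent labels),
#'   `completeness`, `tsd` (per planted integration, if coordinates are
#'   known), `bait_db`, `iterations`.
#' @export
run_detection <- function(community, cfg = classifier_config(),
                          scheme = scoring_scheme()) {
  bx <- bait_expand(community$contigs, community$genes, community$proteins,
                    community$reference$seed_db, community$reference,
                    cfg, scheme)
  comp <- call_completeness(community$contigs, community$alignments)
  tsd <- NULL
  intr <- community$truth$integrations
  if (!is.null(intr)) {
    tsd <- intr
    tsd$tsd_detected <- vapply(seq_len(nrow(intr)), function(i)
      detect_tsd(as.character(community$contigs[[intr$host_id[i]]]),
                 intr$ins_start[i], intr$ins_end[i]), character(1))
  }
  list(classification = bx$results, completeness = comp, tsd = tsd,
       bait_db = bx$bait_db, iterations = bx$iterations)
}

#' Run the enrichment stage on a community
#'
#' Per-contig fraction profiles plus the population summary.
#'
#' @param community a `community`.
#' @param share_threshold passed to [summarize_enrichment()].
#' @return list: `profiles`, `summary`.
#' @export
run_enrichment <- function(community, share_threshold = 0.95) {
  lens <- setNames(Biostrings::width(community$contigs),
                   names(community$contigs))
  prof <- fold_enrichment(community$alignments, lens, community$fraction_gb)
  list(profiles = prof, summary = summarize_enrichment(prof, share_threshold))
}

#' Run the gene-sharing network stage on a community
#'
#' All-vs-all protein search at `e_cutoff`, protein clusters, virus
#' clusters, and MCP-based group assignment (using the classification's
#' MCP gene calls when supplied).
#'
#' @param community a `community`.
#' @param classification optional classification table (for MCP genes).
#' @param e_cutoff protein-clustering stringency.
#' @param weight_threshold virus-cluster edge threshold.
#' @param genome_ids genomes to include (default: all contigs classified
#'   as viruses by truth-independent labels if `classification` given,
#'   else all contigs).
#' @param scheme a [scoring_scheme()].
#' @return list: `pcs`, `vc` (clusters + edges), `mcp_groups`, `hits`.
#' @export
run_network <- function(community, classification = NULL, e_cutoff = 1e-4,
                        weight_threshold = NULL, genome_ids = NULL,
                        scheme = scoring_scheme()) {
  if (is.null(genome_ids)) {
    genome_ids <- if (!is.null(classification)) {
      classification$contig_id[classification$label %in%
                                 c("confirmed_PLV", "putative_PLV",
                                   "virophage")]
    } else names(community$contigs)
  }
  genes <- community$genes[community$genes$contig_id %in% genome_ids, ]
  prots <- community$proteins[genes$gene_id]
  hits <- search_db(prots, prots, scheme, e_cutoff = e_cutoff,
                    coords = FALSE)
  pcs <- cluster_proteins(hits, names(prots), e_cutoff)
  profiles <- pc_profiles(pcs, genes)
  vc <- make_virus_clusters(profiles, genome_ids,
                            weight_threshold = weight_threshold)
  mcp_groups <- NULL
  if (!is.null(classification)) {
    mm <- classification[classification$contig_id %in% genome_ids,
                         c("contig_id", "mcp_gene_id")]
    names(mm)[2] <- "mcp_gene_id"
    mcp_groups <- assign_mcp_group(mm, pcs)
  }
  list(pcs = pcs, vc = vc, mcp_groups = mcp_groups, hits = hits)
}

#' Run the host-linkage stage
#'
#' Screens transcriptome contigs for PLV MCP genes and maps accepted
#' links to virus groups.
#'
#' @param transcripts `DNAStringSet`.
#' @param mcp_db named MCP peptides.
#' @param group_map named MCP id -> group label.
#' @param ... passed to [transcriptome_search()].
#' @return host-link data.frame.
#' @export
run_hosts <- function(transcripts, mcp_db, group_map = NULL, ...) {
  transcriptome_search(transcripts, mcp_db, group_map, ...)
}

#' Aggregate a full run into one report
#'
#' Cross-checked summary of the stage outputs: classification counts,
#' completeness counts, enrichment summary, and virus-cluster census.
#' Totals are recomputed from the tables they summarize.
#'
#' @param detection [run_detection()] output.
#' @param enrichment [run_enrichment()] output.
#' @param network [run_network()] output.
#' @return list suitable for JSON serialization.
#' @export
run_report <- function(detection = NULL, enrichment = NULL, network = NULL) {
  rep <- list()
  if (!is.null(detection)) {
    cl <- detection$classification
    rep$classification <- as.list(table(cl$label))
    rep$completeness <- as.list(table(detection$completeness$status))
    if (!is.null(detection$tsd))
      rep$tsd_recovered <- sum(detection$tsd$tsd_detected ==
                                 detection$tsd$tsd, na.rm = TRUE)
  }
  if (!is.null(enrichment)) rep$enrichment <- enrichment$summary
  if (!is.null(network)) {
    rep$virus_clusters <- as.list(table(network$vc$clusters$category))
    rep$n_protein_clusters <- length(unique(network$pcs$pc_id))
  }
  rep
}

#' Write a run report as JSON
#' @param report [run_report()] output.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
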