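#' Protein clusters from all-vs-all similarity
#'
#' Genes are nodes; edges connect pairs hitting at `E <= e_cutoff`
#' (self-hits removed); protein clusters (PCs) are connected components.
#' PC ids (`PC_0001`, ...) are assigned by descending cluster size, ties
#' by lexicographically smallest member, so ids are stable for a fixed
#' input regardless of input order.
#'
#' @param hits all-vs-all hit table from [search_db()].
#' @param protein_ids all gene ids (components of size one are kept as
#'   singleton PCs).
#' @param e_cutoff clustering stringency (default `1e-4`; a stricter
#'   value can only split clusters, never merge them).
#' @return data.frame `gene_id, pc_id, pc_size`.
#' @export
cluster_proteins <- function(hits, protein_ids, e_cutoff = 1e-4) {
  h <- hits[hits$evalue <= e_cutoff &
              hits$query_id != hits$subject_id, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    h[, c("query_id", "subject_id")], directed = FALSE,
    vertices = data.frame(name = protein_ids))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-lengths(members),
               vapply(members, function(m) min(m), character(1)))
  members <- members[ord]
  pc_ids <- sprintf("PC_%04d", seq_along(members))
  data.frame(
    gene_id = unlist(members, use.names = FALSE),
    pc_id = rep(pc_ids, lengths(members)),
    pc_size = rep(lengths(members), lengths(members)),
    stringsAsFactors = FALSE)
}

#' Significance weight of a genome-genome edge
#'
#' The weight is `-log10` of the hypergeometric upper-tail probability of
#' sharing at least `k` protein clusters, given profiles of sizes `n1`
#' and `n2` drawn from a universe of `universe` PCs. Zero shared PCs give
#' weight 0. Monotone increasing in `k`.
#'
#' @param k shared PC count.
#' @param n1,n2 PC profile sizes of the two genomes.
#' @param universe total number of PCs.
#' @return non-negative weight.
#' @export
genome_edge_weight <- function(k, n1, n2, universe) {
  stopifnot(universe >= n1, universe >= n2, k >= 0)
  if (k == 0) return(0)
  p <- phyper(k - 1, n1, universe - n1, n2, lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}

# incidence of genomes x PCs from a gene->PC map and a gene->genome map
pc_profiles <- function(pcs, genes) {
  m <- merge(pcs, genes[, c("gene_id", "contig_id")], by = "gene_id")
  unique(m[, c("contig_id", "pc_id")])
}

#' Virus clusters from shared protein clusters
#'
#' Builds the genome graph: for every genome pair sharing at least one
#' PC, the edge weight is the hypergeometric significance of the overlap
#' ([genome_edge_weight()]); edges at `weight >= weight_threshold` are
#' kept and connected components define the clusters. Components of
#' size >= 3 are virus clusters (VCs), size 2 are pairs; genomes that
#' share PCs but have no supra-threshold edge are outliers; genomes
#' sharing no PC with anyone are singletons. Within-genome paralogs do
#' not contribute (profiles are PC sets).
#'
#' @param profiles data.frame `contig_id, pc_id` (one row per genome-PC
#'   membership, e.g. from PC assignments merged with the gene table).
#' @param genome_ids all genome ids to categorize.
#' @param universe total PC count (defaults to the number of distinct PCs
#'   in `profiles`).
#' @param weight_threshold minimum edge weight. The default (`NULL`)
#'   applies a Bonferroni-corrected significance level of 0.05 over the
#'   number of evaluated genome pairs, i.e.
#'   `-log10(0.05 / n_pairs)` -- with single-linkage components a fixed
#'   lenient threshold lets chance overlaps between unrelated genomes
#'   chain distinct groups together, so the threshold must scale with
#'   the number of pairs tested.
#' @return list: `clusters` (data.frame `contig_id, vc_id, category`),
#'   `edges` (data.frame `g1, g2, shared, weight`).
#' @export
make_virus_clusters <- function(profiles, genome_ids,
                                universe = length(unique(profiles$pc_id)),
                                weight_threshold = NULL) {
  prof <- split(profiles$pc_id, profiles$contig_id)
  with_pc <- names(prof)
  sizes <- lengths(prof)
  pairs <- NULL
  if (length(with_pc) >= 2) {
    cmb <- utils::combn(sort(with_pc), 2)
    shared <- vapply(seq_len(ncol(cmb)), function(i)
      length(intersect(prof[[cmb[1, i]]], prof[[cmb[2, i]]])), integer(1))
    keep <- shared > 0
    if (any(keep)) {
      cmb <- cmb[, keep, drop = FALSE]; shared <- shared[keep]
      w <- vapply(seq_len(ncol(cmb)), function(i)
        genome_edge_weight(shared[i], sizes[[cmb[1, i]]],
                           sizes[[cmb[2, i]]], universe), numeric(1))
      pairs <- data.frame(g1 = cmb[1, ], g2 = cmb[2, ], shared = shared,
                          weight = w, stringsAsFactors = FALSE)
    }
  }
  shares_any <- unique(c(pairs$g1, pairs$g2))
  if (is.null(weight_threshold))
    weight_threshold <- -log10(0.05 / max(1, NROW(pairs)))
  strong <- if (is.null(pairs)) NULL
            else pairs[pairs$weight >= weight_threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    if (is.null(strong) || nrow(strong) == 0)
      data.frame(g1 = character(0), g2 = character(0))
    else strong[, c("g1", "g2")],
    directed = FALSE, vertices = data.frame(name = genome_ids))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- members[order(-lengths(members),
                           vapply(members, min, character(1)))]
  out <- data.frame(contig_id = genome_ids, vc_id = NA_character_,
                    category = NA_character_, stringsAsFactors = FALSE)
  vc_n <- 0L
  for (m in members) {
    if (length(m) >= 2) {
      vc_n <- vc_n + 1L
      out$vc_id[out$contig_id %in% m] <- sprintf("VC_%03d", vc_n)
      out$category[out$contig_id %in% m] <-
        if (length(m) >= 3) "VC" else "pair"
    }
  }
  loners <- is.na(out$category)
  out$category[loners & out$contig_id %in% shares_any] <- "outlier"
  out$category[loners & !out$contig_id %in% shares_any] <- "singleton"
  list(clusters = out, edges = if (is.null(pairs))
    data.frame(g1 = character(0), g2 = character(0), shared = integer(0),
               weight = numeric(0)) else pairs)
}

#' Assign genomes to groups by the PC of their major capsid gene
#'
#' The large-scale virus groups are defined by which protein cluster the
#' genome's MCP falls into; genomes without an identified MCP are
#' `unassigned`.
#'
#' @param mcp_map data.frame `contig_id, mcp_gene_id` (NA allowed).
#' @param pcs PC assignment from [cluster_proteins()].
#' @return data.frame `contig_id, mcp_gene_id, group` (group = MCP's
#'   `pc_id` or `"unassigned"`).
#' @export
assign_mcp_group <- function(mcp_map, pcs) {
  m <- merge(mcp_map, pcs, by.x = "mcp_gene_id", by.y = "gene_id",
             all.x = TRUE)
  m$group <- ifelse(is.na(m$pc_id), "unassigned", m$pc_id)
  m[order(m$contig_id), c("contig_id", "mcp_gene_id", "group")]
}

#' Export the genome network as GraphML
#' @param vc result of [make_virus_clusters()].
#' @param path output file.
#' @export
write_network_graphml <- function(vc, path) {
  g <- igraph::graph_from_data_frame(
    vc$edges[, c("g1", "g2")], directed = FALSE,
    vertices = vc$clusters[, "contig_id", drop = FALSE])
  if (nrow(vc$edges)) {
    igraph::E(g)$weight <- vc$edges$weight
    igraph::E(g)$shared <- vc$edges$shared
  }
  igraph::V(g)$category <- vc$clusters$category
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
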