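test_that("protein clustering groups by connectivity, ids by size", {
  set.seed(90)
  anc1 <- plvscout:::random_peptide(150)
  anc2 <- plvscout:::random_peptide(150)
  famA <- setNames(vapply(1:3, function(i) mutate_peptide(anc1, 0.1),
                          character(1)), paste0("a", 1:3))
  famB <- setNames(vapply(1:2, function(i) mutate_peptide(anc2, 0.1),
                          character(1)), paste0("b", 1:2))
  lone <- c(z = plvscout:::random_peptide(150))
  prots <- c(famA, famB, lone)
  hits <- search_db(prots, prots, e_cutoff = 1e-4)
  pcs <- cluster_proteins(hits, names(prots))
  m <- setNames(pcs$pc_id, pcs$gene_id)
  expect_equal(unname(m["a1"]), "PC_0001")     # largest family first
  expect_length(unique(m[paste0("a", 1:3)]), 1)
  expect_length(unique(m[paste0("b", 1:2)]), 1)
  expect_false(m[["z"]] %in% m[c("a1", "b1")])
  expect_equal(sum(pcs$pc_size == 1), 1)
})

test_that("stricter clustering cutoffs only refine, never merge", {
  comm <- small_comm()
  tc <- comm$truth$contigs
  vir <- tc$contig_id[tc$class %in% c("PLV", "virophage")]
  genes <- comm$genes[comm$genes$contig_id %in% vir, ]
  prots <- comm$proteins[genes$gene_id]
  hits <- search_db(prots, prots, e_cutoff = 1e-4, coords = FALSE)
  loose <- cluster_proteins(hits, names(prots), 1e-4)
  strict <- cluster_proteins(hits, names(prots), 1e-9)
  key <- merge(loose, strict, by = "gene_id")
  # each strict PC maps into exactly one loose PC
  split_map <- tapply(key$pc_id.x, key$pc_id.y,
                      function(x) length(unique(x)))
  expect_true(all(split_map == 1))
})

test_that("edge weights match the direct-summation hypergeometric tail", {
  cases <- rbind(c(10, 10, 10, 1000), c(3, 15, 20, 200),
                 c(1, 5, 5, 10000), c(7, 12, 9, 50), c(2, 30, 40, 9999))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n1 <- cases[i, 2]; n2 <- cases[i, 3]; N <- cases[i, 4]
    w <- genome_edge_weight(k, n1, n2, N)
    w_oracle <- -log10(brute_hyper_tail(k, n1, n2, N))
    expect_equal(w, w_oracle, tolerance = 1e-9)
  }
  expect_equal(genome_edge_weight(0, 10, 10, 100), 0)
  # monotone in shared count
  ws <- vapply(1:9, function(k) genome_edge_weight(k, 10, 10, 1000),
               numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_error(genome_edge_weight(2, 20, 5, 10))
})

test_that("virus cluster categories partition the genomes", {
  profiles <- data.frame(
    contig_id = c(rep("g1", 5), rep("g2", 5), rep("g3", 5), "g4",
                  rep("g5", 2), rep("g6", 2)),
    pc_id = c(paste0("P", 1:5), paste0("P", 1:5), paste0("P", 1:5), "P9",
              c("Pq", "Pr"), c("Pq", "Pr")))
  vc <- make_virus_clusters(profiles, paste0("g", 1:7),
                            universe = 100, weight_threshold = 1)
  cl <- setNames(vc$clusters$category, vc$clusters$contig_id)
  expect_equal(unname(cl[c("g1", "g2", "g3")]), rep("VC", 3))
  expect_equal(unname(cl[c("g5", "g6")]), rep("pair", 2))
  expect_equal(unname(cl["g4"]), "singleton")   # shares no PC
  expect_equal(unname(cl["g7"]), "singleton")   # no PCs at all
  expect_length(unique(vc$clusters$vc_id[c(1, 2, 3)]), 1)
  # infinite threshold: everyone sharing PCs becomes an outlier
  vc_inf <- make_virus_clusters(profiles, paste0("g", 1:7),
                                universe = 100, weight_threshold = Inf)
  cli <- setNames(vc_inf$clusters$category, vc_inf$clusters$contig_id)
  expect_true(all(cli[c("g1", "g2", "g3", "g5", "g6")] == "outlier"))
})

test_that("MCP protein clusters define virus groups", {
  pcs <- data.frame(gene_id = c("m1", "m2", "m3"),
                    pc_id = c("PC_0001", "PC_0001", "PC_0002"),
                    pc_size = c(2, 2, 1))
  mcp_map <- data.frame(contig_id = c("g1", "g2", "g3", "g4"),
                        mcp_gene_id = c("m1", "m2", "m3", NA))
  grp <- assign_mcp_group(mcp_map, pcs)
  g <- setNames(grp$group, grp$contig_id)
  expect_equal(unname(g[c("g1", "g2")]), rep("PC_0001", 2))
  expect_equal(unname(g["g3"]), "PC_0002")
  expect_equal(unname(g["g4"]), "unassigned")
})

test_that("clustering results do not depend on protein input order", {
  set.seed(91)
  anc <- plvscout:::random_peptide(150)
  prots <- setNames(c(vapply(1:4, function(i) mutate_peptide(anc, 0.1),
                             character(1)),
                      vapply(1:3, function(i) plvscout:::random_peptide(150),
                             character(1))),
                    paste0("p", 1:7))
  h1 <- search_db(prots, prots, e_cutoff = 1e-4)
  pcs1 <- cluster_proteins(h1, names(prots))
  perm <- c(5, 3, 7, 1, 6, 2, 4)
  h2 <- search_db(prots[perm], prots[perm], e_cutoff = 1e-4)
  pcs2 <- cluster_proteins(h2, names(prots)[perm])
  m1 <- setNames(pcs1$pc_id, pcs1$gene_id)
  m2 <- setNames(pcs2$pc_id, pcs2$gene_id)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
})
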