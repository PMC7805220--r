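test_that("one seed, one byte stream", {
  c1 <- generate_community(small_spec())
  c2 <- generate_community(small_spec())
  expect_identical(as.character(c1$contigs), as.character(c2$contigs))
  expect_identical(c1$alignments, c2$alignments)
  expect_identical(c1$proteins, c2$proteins)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_community(small_spec(), d1)
  emit_community(small_spec(), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  c3 <- generate_community(small_spec(seed = 8))
  expect_false(identical(as.character(c1$contigs),
                         as.character(c3$contigs)))
})

test_that("capsid families realize the requested pairwise divergence", {
  set.seed(30)
  spec <- community_spec(n_groups = 1, genomes_per_group = 5,
                         mcp_divergence = 0.3)
  pools <- community_pools(spec)
  mcps <- vapply(1:5, function(i)
    plvscout:::family_member(pools$mcp[["G01"]], 0.3), character(1))
  pid <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  ids <- utils::combn(5, 2)
  mean_id <- mean(vapply(seq_len(ncol(ids)), function(j)
    pid(mcps[ids[1, j]], mcps[ids[2, j]]), numeric(1)))
  expect_gt(mean_id, 0.65)
  expect_lt(mean_id, 0.75)
  # zero divergence: identical members
  expect_equal(plvscout:::family_member(pools$mcp[["G01"]], 0),
               pools$mcp[["G01"]])
  expect_error(community_spec(mcp_divergence = 0.96), "0.95")
})

test_that("genomes carry core genes plus accessories within length bounds", {
  comm <- small_comm()
  tc <- comm$truth$contigs
  fam <- comm$truth$gene_families
  for (cid in tc$contig_id[tc$class == "PLV"]) {
    fams <- fam$family[fam$contig_id == cid]
    expect_true(any(grepl("^MCP_", fams)))
    expect_true(all(c("mCP", "ATPase") %in% fams))
    expect_gte(length(fams), 3 + 5)
    L <- tc$length[tc$contig_id == cid]
    expect_gte(L, comm$spec$genome_length_range[1])
    expect_lte(L, comm$spec$genome_length_range[2])
  }
  # gene coordinates valid and peptides consistent with spans
  g <- comm$genes
  lens <- setNames(tc$length, tc$contig_id)
  expect_true(all(g$start >= 0 & g$start < g$end &
                    g$end <= lens[g$contig_id]))
  expect_equal(nchar(comm$proteins[g$gene_id]),
               setNames((g$end - g$start) %/% 3, g$gene_id))
})

test_that("integration plants TSD-flanked elements and excision inverts", {
  set.seed(41)
  host <- plvscout:::random_dna(30000)
  virus <- plvscout:::random_dna(5000)
  pl <- plant_integration(host, virus, tsd_length = 6)
  s <- pl$seq
  # the 6 bp left of the insertion equal the 6 bp right of it
  expect_equal(substr(s, pl$ins_start - 5, pl$ins_start),
               substr(s, pl$ins_end + 1, pl$ins_end + 6))
  expect_equal(nchar(s), 30000 + 5000 + 6)
  # removing insert plus one TSD copy reconstructs the host
  excised <- paste0(substr(s, 1, pl$ins_start),
                    substr(s, pl$ins_end + 6 + 1, nchar(s)))
  expect_equal(excised, host)
  expect_error(plant_integration(substr(host, 1, 5000), virus, 6),
               "too short")
})

test_that("fragment counts follow copy numbers and wrap the origin", {
  comm <- small_comm()
  ab <- comm$truth$abundance
  fr <- comm$fragments
  # conservation: 2 records per fragment, per fraction
  expect_equal(nrow(comm$alignments), 2 * nrow(fr))
  # per-genome realized coverage tracks planted copies (Poisson bounds)
  tc <- comm$truth$contigs
  for (cid in tc$contig_id[tc$class == "PLV"]) {
    nf <- sum(fr$contig_id == cid & fr$sample == "viral")
    lam <- ab$viral_copies[ab$contig_id == cid] *
      tc$length[tc$contig_id == cid] / (2 * comm$spec$read_length)
    expect_lt(abs(nf - lam) / sqrt(lam), 5)
  }
  # circular genomes wrap: expected wrap fraction ~ insert_mean / length
  circ <- tc$contig_id[tc$topology == "circular" & tc$class != "background"]
  for (cid in circ) {
    fc <- fr[fr$contig_id == cid, ]
    p_wrap <- mean(fc$wrap)
    expected <- mean(fc$insert) / tc$length[tc$contig_id == cid]
    expect_lt(abs(p_wrap - expected),
              5 * sqrt(expected / nrow(fc)) + 0.003)
    # wrapped fragments are emitted as discordant mate placements
    w <- comm$alignments[comm$alignments$contig_id == cid &
                           !comm$alignments$proper_pair, ]
    expect_equal(nrow(w), 2 * sum(fc$wrap))
  }
  # linear genomes never wrap
  lin <- tc$contig_id[tc$topology != "circular"]
  expect_true(all(!fr$wrap[fr$contig_id %in% lin]))
  # zero copies in a fraction -> zero records
  spec0 <- community_spec(n_groups = 1, genomes_per_group = 1,
                          n_virophages = 0, n_background = 0,
                          n_integrations = 0, fold_values = 1e12,
                          seed = 3)
  comm0 <- generate_community(spec0)
  expect_equal(sum(comm0$alignments$sample == "microbial"), 0)
})

test_that("community bookkeeping: one truth row per contig", {
  comm <- small_comm()
  expect_setequal(comm$truth$contigs$contig_id, names(comm$contigs))
  expect_equal(anyDuplicated(comm$truth$contigs$contig_id), 0)
  expect_equal(nrow(comm$truth$contigs), 2 * 2 + 2 + 3 + 2)
  expect_equal(sum(comm$truth$contigs$class == "integrated_host"), 2)
  expect_true(all(nchar(comm$truth$integrations$tsd) %in% 5:7))
})
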