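# direct rule application with fabricated hit tables ------------------

test_that("putative and confirmation rules honor documented boundaries", {
  cases <- rbind(
    # hit fraction boundary (length and MCP qualifying)
    data.frame(hit = 19, n = 100, len = 20000, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),
    data.frame(hit = 20, n = 100, len = 20000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"),
    data.frame(hit = 21, n = 100, len = 20000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"),
    data.frame(hit = 4, n = 21, len = 20000, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),      # 0.190 < 0.20
    data.frame(hit = 5, n = 20, len = 20000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"), # 0.25
    # length boundaries: putative [10000, 45000], confirmed [10000, 41000]
    data.frame(hit = 50, n = 100, len = 9999, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),
    data.frame(hit = 50, n = 100, len = 10000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"),
    data.frame(hit = 50, n = 100, len = 41000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"),
    data.frame(hit = 50, n = 100, len = 41001, vmcp = FALSE, mcp = TRUE,
               want = "putative_PLV"),  # putative window only
    data.frame(hit = 50, n = 100, len = 45000, vmcp = FALSE, mcp = TRUE,
               want = "putative_PLV"),
    data.frame(hit = 50, n = 100, len = 45001, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),
    # virophage MCP presence always wins
    data.frame(hit = 50, n = 100, len = 20000, vmcp = TRUE, mcp = TRUE,
               want = "virophage"),
    data.frame(hit = 0, n = 100, len = 20000, vmcp = TRUE, mcp = FALSE,
               want = "virophage"),
    # MCP absence blocks confirmation
    data.frame(hit = 50, n = 100, len = 20000, vmcp = FALSE, mcp = FALSE,
               want = "putative_PLV"),
    data.frame(hit = 20, n = 100, len = 10000, vmcp = FALSE, mcp = FALSE,
               want = "putative_PLV"),
    # joint boundaries
    data.frame(hit = 20, n = 100, len = 41000, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"),
    data.frame(hit = 19, n = 100, len = 41000, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),
    data.frame(hit = 20, n = 100, len = 45001, vmcp = FALSE, mcp = TRUE,
               want = "rejected"),
    data.frame(hit = 100, n = 100, len = 44000, vmcp = FALSE, mcp = TRUE,
               want = "putative_PLV"),
    data.frame(hit = 100, n = 100, len = 40999, vmcp = FALSE, mcp = TRUE,
               want = "confirmed_PLV"))
  expect_gte(nrow(cases), 20)
  for (i in seq_len(nrow(cases))) {
    got <- apply_rules(cases$hit[i], cases$n[i], cases$len[i],
                       cases$vmcp[i], cases$mcp[i])
    expect_equal(got, cases$want[i],
                 info = paste("case", i, paste(cases[i, ], collapse = "/")))
  }
})

test_that("contigs without genes are rejected, never divide by zero", {
  r <- flag_putative_plv("empty", 20000, character(0),
                         fake_hits(character(0)), FALSE)
  expect_equal(r$label, "rejected")
  expect_equal(r$reason, "no_genes")
  expect_true(is.na(r$hit_fraction_observed))
})

test_that("ATPase plus mCP evidence marks fallback, never confirms", {
  gid <- sprintf("g%02d", 1:10)
  row <- flag_putative_plv("c", 20000, gid, fake_hits(gid[1:5]), FALSE)
  no_prof <- data.frame(subject_id = character(0), evalue = numeric(0))
  r <- confirm_plv(row, 20000, plvscout:::empty_hits(), no_prof,
                   list(ATPase = fake_hits("g01"), mCP = fake_hits("g02")),
                   gid)
  expect_equal(r$label, "putative_PLV")
  expect_true(r$fallback_core)
  # missing either core gene: no fallback
  r2 <- confirm_plv(row, 20000, plvscout:::empty_hits(), no_prof,
                    list(ATPase = fake_hits("g01"),
                         mCP = fake_hits(character(0))), gid)
  expect_false(r2$fallback_core)
})

# bait expansion ------------------------------------------------------

test_that("bait expansion finds a two-hop group at the second iteration", {
  set.seed(77)
  rp <- plvscout:::random_peptide
  fm <- plvscout:::family_member
  # families: seed-known pool S (4), A-private pool P (4), MCPs per group
  S <- setNames(lapply(1:4, function(i) rp(180)), paste0("S", 1:4))
  P <- setNames(lapply(1:4, function(i) rp(180)), paste0("P", 1:4))
  mcpA <- rp(300); mcpB <- rp(300)
  mk_contig <- function(cid, fams) {
    peps <- vapply(fams, function(f) fm(f, 0.2), character(1))
    names(peps) <- sprintf("%s_g%02d", cid, seq_along(peps))
    list(genes = data.frame(gene_id = names(peps), contig_id = cid,
                            start = 100 + 400 * (seq_along(peps) - 1),
                            end = 100 + 400 * (seq_along(peps) - 1) + 300,
                            strand = "+", stringsAsFactors = FALSE),
         peps = peps)
  }
  # A: MCP_A + 4 seed-family genes + 4 private-family genes + 2 unique
  a <- mk_contig("A", c(list(mcpA), S, P, list(rp(150), rp(150))))
  # B: MCP_B + 4 genes from A's private families + 6 unique genes
  b <- mk_contig("B", c(list(mcpB), P, lapply(1:6, function(i) rp(150))))
  genes <- rbind(a$genes, b$genes)
  proteins <- c(a$peps, b$peps)
  contigs <- Biostrings::DNAStringSet(c(A = strrep("A", 15000),
                                        B = strrep("A", 15000)))
  reference <- list(
    vmcp_db = c(ref_vmcp = rp(300)),
    plv_mcp_db = c(ref_none = rp(300)),
    core_dbs = list(ATPase = c(ref_atp = rp(250)),
                    mCP = c(ref_mcp2 = rp(200))),
    mcp_profiles = list(
      A = build_profile(vapply(1:3, function(i) fm(mcpA, 0.2),
                               character(1))),
      B = build_profile(vapply(1:3, function(i) fm(mcpB, 0.2),
                               character(1)))))
  seed_db <- setNames(vapply(S, function(x) fm(x, 0.2), character(1)),
                      paste0("seed_", names(S)))
  bx <- bait_expand(contigs, genes, proteins, seed_db, reference)
  res <- bx$results
  expect_true(bx$converged)
  expect_equal(res$label[res$contig_id == "A"], "confirmed_PLV")
  expect_equal(res$label[res$contig_id == "B"], "confirmed_PLV")
  expect_equal(res$iteration_found[res$contig_id == "A"], 1L)
  expect_equal(res$iteration_found[res$contig_id == "B"], 2L)
  # rerun with the final bait: fixed point at iteration 1
  bx2 <- bait_expand(contigs, genes, proteins, bx$bait_db, reference)
  expect_equal(bx2$iterations, 1L)
  expect_setequal(
    bx2$results$contig_id[bx2$results$label == "confirmed_PLV"],
    c("A", "B"))
  # empty assemblies
  bx0 <- bait_expand(Biostrings::DNAStringSet(), genes[0, ],
                     proteins[0], seed_db, reference)
  expect_null(bx0$results)
})

test_that("classification labels ignore contig input order", {
  comm <- small_comm()
  ref <- comm$reference
  r1 <- classify_contigs(comm$contigs, comm$genes, comm$proteins,
                         ref$seed_db, ref)
  perm <- sample(length(comm$contigs))
  r2 <- classify_contigs(comm$contigs[perm], comm$genes, comm$proteins,
                         ref$seed_db, ref)
  r2 <- r2[match(r1$contig_id, r2$contig_id), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

# dereplication -------------------------------------------------------

test_that("exact duplicates collapse with the longer as representative", {
  set.seed(81)
  g1 <- plvscout:::random_dna(12000)
  g2 <- plvscout:::random_dna(9000)
  res <- dereplicate(c(a = g1, a_copy = g1, b = g2))
  expect_equal(sort(unique(res$cluster_id)), c("CL_0001", "CL_0002"))
  expect_equal(res$representative[res$contig_id == "a_copy"], "a")
  expect_equal(res$representative[res$contig_id == "b"], "b")
})

test_that("circular rotations merge only under circular-aware clustering", {
  set.seed(82)
  g <- plvscout:::random_dna(12000)
  rot <- paste0(substr(g, 5001, 12000), substr(g, 1, 5000))
  rounds_circ <- list(list(identity = 0.7, global = TRUE, circular = TRUE))
  rounds_lin <- list(list(identity = 0.7, global = TRUE, circular = FALSE))
  res_c <- dereplicate(c(g = g, g_rot = rot), rounds_circ)
  expect_equal(length(unique(res_c$cluster_id)), 1)
  res_l <- dereplicate(c(g = g, g_rot = rot), rounds_lin)
  expect_equal(length(unique(res_l$cluster_id)), 2)
})

test_that("80%-identity mutants merge at 0.7 and split at 0.9", {
  set.seed(83)
  g <- plvscout:::random_dna(15000)
  mut <- mutate_dna(g, 0.2)
  est <- estimate_nt_identity(mut, g)
  expect_lt(abs(est$global_identity - 0.8), 0.03)
  r07 <- dereplicate(c(g = g, mut = mut),
                     list(list(identity = 0.7, global = TRUE,
                               circular = TRUE)))
  expect_equal(length(unique(r07$cluster_id)), 1)
  r09 <- dereplicate(c(g = g, mut = mut),
                     list(list(identity = 0.9, global = TRUE,
                               circular = TRUE)))
  expect_equal(length(unique(r09$cluster_id)), 2)
})

test_that("two-round scheme mirrors the coarse-then-global procedure", {
  set.seed(84)
  g <- plvscout:::random_dna(20000)
  # a chimeric scaffold: half matches g, half is novel sequence. The
  # local round (high identity, 20% coverage of the longer) absorbs it;
  # global identity over the shorter sequence (0.5) does not.
  chim <- paste0(substr(g, 1, 6000), plvscout:::random_dna(6000))
  rounds <- list(list(identity = 0.9, global = FALSE, coverage = 0.2,
                      circular = TRUE),
                 list(identity = 0.7, global = TRUE, circular = TRUE))
  res <- dereplicate(c(g = g, chim = chim), rounds)
  expect_equal(length(unique(res$cluster_id)), 1)
  res_g <- dereplicate(c(g = g, chim = chim),
                       list(list(identity = 0.7, global = TRUE,
                                 circular = TRUE)))
  expect_equal(length(unique(res_g$cluster_id)), 2)
  # a perfect contained fragment joins under shorter-sequence global
  # identity too (it is wholly redundant)
  frag <- substr(g, 2000, 8000)
  res_f <- dereplicate(c(g = g, frag = frag),
                       list(list(identity = 0.7, global = TRUE,
                                 circular = TRUE)))
  expect_equal(length(unique(res_f$cluster_id)), 1)
})
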