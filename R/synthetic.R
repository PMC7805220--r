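AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson & Robinson background frequencies; random peptides drawn from
# a realistic composition keep chance alignment scores consistent with
# the BLOSUM62 Karlin-Altschul parameters.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Specification of a synthetic virus community
#'
#' Describes a planted community of Polinton-like virus (PLV) and
#' virophage genomes, background contigs, host contigs with integrated
#' elements, and paired 2 x 150 bp reads from a virus-enriched (< 0.2 um)
#' and a microbial (> 0.2 um) size fraction. Every downstream pipeline
#' stage can be validated against the ground truth the generator plants.
#'
#' Defaults mirror the study conditions this pipeline targets: genomes of
#' 10-41 kb carrying the three core genes (group-specific major capsid
#' protein, minor capsid protein, packaging ATPase) plus 5-20 accessory
#' genes, capsid families at 30% within-group divergence, paired-end
#' inserts bounded at 800 bp, target-site duplications of 5-7 bp at
#' integrations, and per-genome viral:microbial fold enrichments drawn
#' log-normally around a median of 190 (virophages: 108), clipped to
#' 1-2816.
#'
#' @param n_groups number of PLV groups, each with its own capsid family.
#' @param genomes_per_group free PLV genomes per group.
#' @param n_virophages virophage genomes (one shared virophage MCP family).
#' @param n_background background contigs (no viral genes).
#' @param n_integrations host contigs carrying an integrated element with
#'   terminal inverted repeats and a target-site duplication.
#' @param genome_length_range virus genome length bounds (bp).
#' @param background_length_range background contig length bounds (bp).
#' @param mcp_divergence expected pairwise fraction of substituted
#'   residues within a group's MCP family (must be < 0.95).
#' @param accessory_divergence pairwise divergence of all other families.
#' @param n_accessory_range accessory genes per genome.
#' @param shared_gene_prob probability an accessory gene is drawn from the
#'   pool shared with virophages (gives the gene-sharing signal the
#'   classifier and network stages rely on).
#' @param tir_length terminal-inverted-repeat length for `linear_TIR`
#'   genomes (bp; 0 disables).
#' @param tsd_length target-site duplication lengths, each in 5..7;
#'   recycled across integrations.
#' @param topology_probs sampling weights for genome topology.
#' @param viral_copies expected fold-coverage of each virus genome in the
#'   viral fraction.
#' @param fold_values optional explicit per-genome fold enrichments
#'   (recycled); overrides the log-normal draw.
#' @param fold_median,fold_sdlog,fold_range log-normal fold-enrichment
#'   model per class.
#' @param background_copies fold-coverage of background/host contigs per
#'   fraction.
#' @param read_length,insert_mean,insert_sd,max_insert read geometry (bp).
#' @param error_rate per-base substitution rate applied when read
#'   sequences are emitted (truth alignments are error-free placements).
#' @param seed integer RNG seed; one seed, one byte stream.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_groups = 8, genomes_per_group = 5,
                           n_virophages = 5, n_background = 20,
                           n_integrations = 3,
                           genome_length_range = c(10000, 41000),
                           background_length_range = c(8000, 45000),
                           mcp_divergence = 0.3,
                           accessory_divergence = 0.2,
                           n_accessory_range = c(5, 20),
                           shared_gene_prob = 0.4,
                           tir_length = 300,
                           tsd_length = c(5, 6, 7),
                           topology_probs = c(circular = 0.5,
                                              linear_TIR = 0.3,
                                              linear = 0.2),
                           viral_copies = 30,
                           fold_values = NULL,
                           fold_median = c(PLV = 190, virophage = 108),
                           fold_sdlog = 1.3,
                           fold_range = c(1, 2816),
                           background_copies = c(viral = 0.5, microbial = 20),
                           read_length = 150, insert_mean = 450,
                           insert_sd = 80, max_insert = 800,
                           error_rate = 0.001, seed = 42) {
  stopifnot(n_groups >= 0, genomes_per_group >= 0, n_virophages >= 0,
            n_background >= 0, n_integrations >= 0,
            all(tsd_length >= 5 & tsd_length <= 7),
            max_insert >= insert_mean,
            genome_length_range[1] >= 1000, genome_length_range[2] <= 1e6,
            genome_length_range[1] <= genome_length_range[2],
            read_length > 0, insert_mean >= 2 * read_length,
            error_rate >= 0, error_rate < 1)
  if (mcp_divergence >= 0.95)
    stop("community_spec: mcp_divergence >= 0.95 would make family ",
         "structure unrecoverable")
  spec <- as.list(environment())
  structure(spec, class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "community_spec: %d groups x %d PLVs, %d virophages, %d background,\n",
    "  %d integrations, genomes %d-%d bp, MCP divergence %.2f, seed %d\n"),
    x$n_groups, x$genomes_per_group, x$n_virophages, x$n_background,
    x$n_integrations, x$genome_length_range[1], x$genome_length_range[2],
    x$mcp_divergence, x$seed))
  invisible(x)
}

# -- sequence-level primitives -------------------------------------------

random_peptide <- function(n, start_met = FALSE) {
  p <- sample(AA20, n, replace = TRUE, prob = AA_BACKGROUND)
  if (start_met) p[1] <- "M"
  paste(p, collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-sequence substitution rate r such that two independent mutants of a
# common ancestor show expected pairwise divergence d:
# (1-r)^2 + r^2/19 = 1 - d  (second term: both substituted, same residue).
per_seq_rate <- function(d) {
  stopifnot(d >= 0, d < 0.95)
  (19 / 20) * (1 - sqrt(1 - 20 * d / 19))
}

#' Substitute residues of a peptide at a fixed per-site rate
#' @param pep peptide string.
#' @param rate per-site substitution probability; substitutions always
#'   change the residue.
#' @return mutated peptide string.
#' @export
mutate_peptide <- function(pep, rate) {
  ch <- strsplit(pep, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Substitute bases of a DNA sequence at a fixed per-site rate
#' @param seq DNA string.
#' @param rate per-site substitution probability.
#' @return mutated DNA string.
#' @export
mutate_dna <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Draw a family member at target pairwise divergence from its ancestor.
family_member <- function(ancestor, pairwise_divergence) {
  mutate_peptide(ancestor, per_seq_rate(pairwise_divergence))
}

rev_translate <- function(pep) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  ch <- strsplit(pep, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) sample(by_aa[[a]], 1), character(1)),
        collapse = "")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# -- gene pools -----------------------------------------------------------

SHARED_FAMILY_NAMES <- c(
  "lipase", "phospholipase", "endonuclease", "tyrosine_recombinase",
  "cysteine_protease", "DNA_methyltransferase", "helicase_primase",
  "E3_ubiquitin_ligase", "chitinase", "restriction_enzyme",
  "glycosyltransferase", "thioredoxin", "nuclease_2", "kinase", "terminase")

#' Build the ancestral gene pools for a community
#'
#' Creates the ancestor peptide of every gene family: one MCP family per
#' PLV group, the single virophage MCP family, the shared minor capsid
#' protein and packaging ATPase families, a pool of accessory families
#' shared between virophages and PLVs (lipase, protease, ...), and
#' group-private accessory pools. Consumes the current RNG stream.
#'
#' @param spec a [community_spec()].
#' @return list of ancestor pools used by [generate_genome()].
#' @export
community_pools <- function(spec) {
  groups <- sprintf("G%02d", seq_len(spec$n_groups))
  pools <- list(
    groups = groups,
    vmcp = random_peptide(300),
    mcp = setNames(lapply(groups, function(g) random_peptide(300)), groups),
    mcp_minor = random_peptide(200),
    atpase = random_peptide(250),
    shared = setNames(
      lapply(SHARED_FAMILY_NAMES, function(x)
        random_peptide(sample(100:250, 1))),
      paste0("shared_", SHARED_FAMILY_NAMES)),
    group_acc = setNames(lapply(groups, function(g) {
      n <- 20
      setNames(lapply(seq_len(n), function(i)
        random_peptide(sample(80:220, 1))),
        sprintf("acc_%s_%02d", g, seq_len(n)))
    }), groups),
    vir_acc = setNames(lapply(1:15, function(i)
      random_peptide(sample(80:220, 1))), sprintf("acc_vir_%02d", 1:15)))
  pools
}

# -- genome construction --------------------------------------------------

#' Generate one virus genome with its gene calls
#'
#' Assembles a genome of the spec's length range: core genes (MCP of the
#' group's capsid family, minor capsid protein, ATPase) plus accessory
#' genes drawn from the group-private and shared pools, separated by
#' random intergenic spacers, on random strands. `linear_TIR` genomes are
#' flanked by terminal inverted repeats. Consumes the current RNG stream;
#' wrap in `set.seed()` for reproducibility (as [generate_community()]
#' does).
#'
#' @param group group label (e.g. `"G01"`) or `"virophage"`.
#' @param spec a [community_spec()].
#' @param pools output of [community_pools()].
#' @param contig_id identifier for the emitted contig.
#' @param topology `"circular"`, `"linear_TIR"`, `"linear"`, or `NA` to
#'   sample from `spec$topology_probs`.
#' @return list with `seq` (character), `genes` (data.frame with
#'   `gene_id, contig_id, start, end, strand, family`), `peptides`
#'   (named character), `topology`, `group`.
#' @export
generate_genome <- function(group, spec, pools, contig_id = "contig",
                            topology = NA) {
  virophage <- identical(group, "virophage")
  if (is.na(topology))
    topology <- sample(names(spec$topology_probs), 1,
                       prob = spec$topology_probs)
  if (topology == "linear_TIR" && spec$tir_length == 0) topology <- "linear"
  target <- sample(spec$genome_length_range[1]:spec$genome_length_range[2], 1)
  tir <- if (topology == "linear_TIR") spec$tir_length else 0L

  mcp_anc <- if (virophage) pools$vmcp else pools$mcp[[group]]
  fams <- c(if (virophage) "VMCP" else paste0("MCP_", group), "mCP", "ATPase")
  peps <- c(family_member(mcp_anc, spec$mcp_divergence),
            family_member(pools$mcp_minor, 0.3),
            family_member(pools$atpase, 0.3))
  n_acc <- sample(spec$n_accessory_range[1]:spec$n_accessory_range[2], 1)
  own_pool <- if (virophage) pools$vir_acc else pools$group_acc[[group]]
  for (i in seq_len(n_acc)) {
    pool <- if (runif(1) < spec$shared_gene_prob) pools$shared else own_pool
    fam <- sample(names(pool), 1)
    fams <- c(fams, fam)
    peps <- c(peps, family_member(pool[[fam]], spec$accessory_divergence))
  }
  # trim accessories that do not fit the target length
  repeat {
    coding <- sum(3 * nchar(peps))
    if (coding + 30 * (length(peps) + 1) + 2 * tir <= target ||
        length(peps) <= 3) break
    fams <- fams[-length(fams)]
    peps <- peps[-length(peps)]
  }
  ord <- sample(seq_along(peps))
  fams <- fams[ord]; peps <- peps[ord]
  body_target <- target - 2 * tir
  coding <- sum(3 * nchar(peps))
  spare <- body_target - coding
  # spacers: 10 bp minimum each, remainder split at random, exact total
  ns <- length(peps) + 1
  w <- runif(ns)
  extra <- spare - 10 * ns
  spacers <- 10L + floor(extra * w / sum(w))
  spacers[ns] <- spacers[ns] + (spare - sum(spacers))

  parts <- character(0)
  starts <- integer(length(peps)); ends <- integer(length(peps))
  strands <- sample(c("+", "-"), length(peps), replace = TRUE)
  pos <- 0L
  for (i in seq_along(peps)) {
    sp <- random_dna(spacers[i])
    parts <- c(parts, sp); pos <- pos + spacers[i]
    nt <- rev_translate(peps[i])
    if (strands[i] == "-") nt <- revcomp_chr(nt)
    starts[i] <- pos; ends[i] <- pos + nchar(nt)
    parts <- c(parts, nt); pos <- pos + nchar(nt)
  }
  parts <- c(parts, random_dna(spacers[length(spacers)]))
  body <- paste(parts, collapse = "")
  if (tir > 0) {
    tir_seq <- random_dna(tir)
    # break the repeat boundary so the planted TIR has exact ends
    nb <- nchar(body)
    comp_last <- revcomp_chr(substr(body, nb, nb))
    if (substr(body, 1, 1) == comp_last) {
      substr(body, 1, 1) <- sample(setdiff(c("A", "C", "G", "T"),
                                           comp_last), 1)
    }
    seq <- paste0(tir_seq, body, revcomp_chr(tir_seq))
    starts <- starts + tir; ends <- ends + tir
  } else {
    seq <- body
  }
  gene_ids <- sprintf("%s_g%02d", contig_id, seq_along(peps))
  list(seq = seq,
       genes = data.frame(gene_id = gene_ids, contig_id = contig_id,
                          start = starts, end = ends, strand = strands,
                          family = fams, stringsAsFactors = FALSE),
       peptides = setNames(peps, gene_ids),
       topology = topology,
       group = if (virophage) "virophage" else group)
}

# background contig: random sequence with decoy genes that hit nothing
generate_background <- function(spec, contig_id) {
  len <- sample(spec$background_length_range[1]:spec$background_length_range[2], 1)
  seq <- random_dna(len)
  n <- sample(5:15, 1)
  plens <- sample(80:250, n, replace = TRUE)
  # place decoy genes on a sparse grid; coordinates are bookkeeping only
  starts <- sort(sample.int(max(1, len - 3 * max(plens) - 1), n))
  genes <- data.frame(gene_id = sprintf("%s_g%02d", contig_id, seq_len(n)),
                      contig_id = contig_id,
                      start = starts, end = starts + 3 * plens,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      family = sprintf("decoy_%s_%02d", contig_id, seq_len(n)),
                      stringsAsFactors = FALSE)
  peps <- setNames(vapply(plens, random_peptide, character(1)), genes$gene_id)
  list(seq = seq, genes = genes, peptides = peps,
       topology = "linear", group = "background")
}

#' Plant an integrated element into a host contig
#'
#' Inserts a virus sequence at an interior position of a host sequence,
#' flanked on both sides by a duplicated `tsd_length`-bp host motif (the
#' target-site duplication). Terminal inverted repeats, if any, are part
#' of the virus sequence itself.
#'
#' @param host host contig sequence (character or `DNAString`).
#' @param virus virus sequence to insert.
#' @param tsd_length length of the target-site duplication (5-7 bp).
#' @param pos 0-based insertion point; default: host midpoint.
#' @return list with `seq` (the modified host), `ins_start`, `ins_end`
#'   (0-based half-open coordinates of the inserted virus), and `tsd`
#'   (the duplicated motif).
#' @export
plant_integration <- function(host, virus, tsd_length, pos = NULL) {
  host <- toupper(as.character(host)); virus <- toupper(as.character(virus))
  hl <- nchar(host); vl <- nchar(virus)
  if (hl < vl + 2 * tsd_length + 200)
    stop("plant_integration: host too short for insertion")
  if (is.null(pos)) pos <- hl %/% 2
  stopifnot(pos > tsd_length + 100, pos < hl - tsd_length - 100)
  tsd <- substr(host, pos - tsd_length + 1, pos)
  seq <- paste0(substr(host, 1, pos), virus, tsd,
                substr(host, pos + 1, hl))
  list(seq = seq, ins_start = pos, ins_end = pos + vl, tsd = tsd)
}

# -- read simulation ------------------------------------------------------

#' Simulate paired-end read placements for a set of contigs
#'
#' Fragment counts per contig are Poisson with mean
#' `copies * length / (2 * read_length)`, so `copies` is the expected
#' fold-coverage. Circular genomes produce origin-wrapping fragments,
#' emitted as the discordant mate placements a mapper would report (mate
#' near the 3' end on `+`, mate near the 5' end on `-`,
#' `proper_pair = FALSE`). Truth alignments are placements, not
#' error-containing sequences.
#'
#' @param contig_lengths named integer vector.
#' @param topologies named character vector (`circular` wraps).
#' @param abundance data.frame with `contig_id`, `viral_copies`,
#'   `microbial_copies`.
#' @param spec a [community_spec()].
#' @return list with `alignments` (truth-TSV dialect data.frame) and
#'   `fragments` (per-fragment log: `contig_id, sample, start, insert,
#'   wrap`).
#' @export
simulate_reads <- function(contig_lengths, topologies, abundance, spec) {
  rl <- spec$read_length
  aln_list <- list(); frag_list <- list()
  for (i in seq_len(nrow(abundance))) {
    cid <- abundance$contig_id[i]
    L <- contig_lengths[[cid]]
    circ <- identical(topologies[[cid]], "circular")
    if (spec$insert_mean > L)
      stop("simulate_reads: insert_mean exceeds length of ", cid)
    for (fraction in c("viral", "microbial")) {
      copies <- abundance[[paste0(fraction, "_copies")]][i]
      nf <- rpois(1, copies * L / (2 * rl))
      if (nf == 0) next
      ins <- pmin(pmax(round(rnorm(nf, spec$insert_mean, spec$insert_sd)),
                       2 * rl), min(spec$max_insert, L))
      if (circ) {
        start <- sample.int(L, nf, replace = TRUE) - 1L
      } else {
        start <- floor(runif(nf) * (L - ins + 1))
      }
      wrap <- start + ins > L
      s1 <- start
      s1 <- ifelse(s1 + rl > L, L - rl, s1)
      p2 <- start + ins - rl
      p2 <- ifelse(wrap, p2 %% L, p2)
      p2 <- ifelse(p2 + rl > L, if (circ) 0L else L - rl, p2)
      rid <- sprintf("%s.%s.%06d", cid, substr(fraction, 1, 1), seq_len(nf))
      aln_list[[length(aln_list) + 1]] <- data.frame(
        read_id = rep(rid, 2),
        mate_index = rep(1:2, each = nf),
        contig_id = cid,
        start = c(s1, p2), end = c(s1, p2) + rl,
        strand = rep(c("+", "-"), each = nf),
        mate_contig_id = cid,
        mate_start = c(p2, s1),
        proper_pair = rep(!wrap, 2),
        sample = fraction,
        stringsAsFactors = FALSE)
      frag_list[[length(frag_list) + 1]] <- data.frame(
        contig_id = cid, sample = fraction, start = start,
        insert = ins, wrap = wrap, stringsAsFactors = FALSE)
    }
  }
  list(alignments = if (length(aln_list)) do.call(rbind, aln_list)
                    else NULL,
       fragments = if (length(frag_list)) do.call(rbind, frag_list)
                   else NULL)
}

# -- whole community ------------------------------------------------------

#' Generate a synthetic community with planted ground truth
#'
#' Builds the full community described by the spec: free PLV and
#' virophage genomes, background contigs, host contigs with integrated
#' elements (terminal inverted repeats + target-site duplications), truth
#' read placements for both size fractions, and the reference material a
#' detection run needs (virophage MCP exemplars, per-group PLV MCP
#' exemplars and profiles, core-gene exemplars). Fully deterministic for
#' a fixed seed.
#'
#' @param spec a [community_spec()].
#' @return A `community` list: `contigs` (DNAStringSet), `genes`
#'   (data.frame), `proteins` (named character), `alignments`,
#'   `fragments`, `truth` (list of `contigs`, `abundance`,
#'   `integrations`, `gene_families`, `ancestors`), `reference` (list of
#'   `vmcp_db`, `plv_mcp_db`, `core_dbs`, `mcp_profiles`, `seed_db`),
#'   `fraction_gb`, `spec`.
#' @export
generate_community <- function(spec = community_spec()) {
  set.seed(spec$seed)
  pools <- community_pools(spec)
  entries <- list()
  for (g in pools$groups)
    for (i in seq_len(spec$genomes_per_group)) {
      cid <- sprintf("PLV_%s_%02d", g, i)
      entries[[cid]] <- generate_genome(g, spec, pools, cid)
    }
  for (i in seq_len(spec$n_virophages)) {
    cid <- sprintf("VIR_%02d", i)
    entries[[cid]] <- generate_genome("virophage", spec, pools, cid)
  }
  for (i in seq_len(spec$n_background)) {
    cid <- sprintf("BG_%02d", i)
    entries[[cid]] <- generate_background(spec, cid)
  }
  # integrated elements: fresh genomes (relatives of the free community)
  # inserted mid-host with TIRs and a TSD
  integrations <- list()
  for (j in seq_len(spec$n_integrations)) {
    g <- pools$groups[((j - 1) %% max(1, spec$n_groups)) + 1]
    hid <- sprintf("HOST_%02d", j)
    vid <- sprintf("%s_element", hid)
    virus <- generate_genome(g, spec, pools, vid, topology = "linear_TIR")
    vl <- nchar(virus$seq)
    host_len <- max(50000, 2 * vl)
    host <- random_dna(host_len)
    tsd_len <- spec$tsd_length[((j - 1) %% length(spec$tsd_length)) + 1]
    # pick an insertion point whose TSD is recovered uniquely (chance
    # flanking matches could extend or blur the planted duplication)
    pl <- NULL
    for (try in 1:50) {
      pos <- nchar(host) %/% 2 + sample(-2000:2000, 1)
      cand <- plant_integration(host, virus$seq, tsd_len, pos)
      det <- detect_tsd(cand$seq, cand$ins_start, cand$ins_end,
                        len_range = range(spec$tsd_length, 5, 7))
      if (identical(det, cand$tsd)) { pl <- cand; break }
    }
    if (is.null(pl)) pl <- plant_integration(host, virus$seq, tsd_len)
    genes <- virus$genes
    genes$start <- genes$start + pl$ins_start
    genes$end <- genes$end + pl$ins_start
    genes$contig_id <- hid
    genes$gene_id <- sub(vid, hid, genes$gene_id, fixed = TRUE)
    entries[[hid]] <- list(
      seq = pl$seq, genes = genes,
      peptides = setNames(virus$peptides,
                          sub(vid, hid, names(virus$peptides), fixed = TRUE)),
      topology = "linear", group = g, class = "integrated_host")
    integrations[[j]] <- data.frame(
      host_id = hid, virus_group = g,
      ins_start = pl$ins_start, ins_end = pl$ins_end,
      tir_length = spec$tir_length, tsd = pl$tsd,
      stringsAsFactors = FALSE)
  }

  ids <- names(entries)
  class_of <- vapply(entries, function(e) {
    if (!is.null(e$class)) e$class
    else if (identical(e$group, "virophage")) "virophage"
    else if (identical(e$group, "background")) "background"
    else "PLV"
  }, character(1))
  truth_contigs <- data.frame(
    contig_id = ids, class = unname(class_of),
    group = vapply(entries, function(e) e$group, character(1),
                   USE.NAMES = FALSE),
    topology = vapply(entries, function(e) e$topology, character(1),
                      USE.NAMES = FALSE),
    length = vapply(entries, function(e) nchar(e$seq), integer(1),
                    USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  # planted abundances: viruses enriched in the viral fraction with
  # per-genome fold enrichment; background/hosts live in the microbial one
  is_virus <- class_of %in% c("PLV", "virophage")
  n_virus <- sum(is_virus)
  folds <- numeric(length(ids))
  if (!is.null(spec$fold_values)) {
    folds[is_virus] <- rep_len(spec$fold_values, n_virus)
  } else {
    med <- ifelse(class_of[is_virus] == "PLV",
                  spec$fold_median[["PLV"]], spec$fold_median[["virophage"]])
    folds[is_virus] <- pmin(pmax(rlnorm(n_virus, log(med), spec$fold_sdlog),
                                 spec$fold_range[1]), spec$fold_range[2])
  }
  # the planted fold is on the normalized (per-Gb) scale the analysis
  # reports, so microbial copies must account for the relative sizes of
  # the two fraction metagenomes; the sizes depend on the copies, a
  # small fixed point solved by iteration
  L <- vapply(entries, function(e) nchar(e$seq), numeric(1))
  c_v <- ifelse(is_virus, spec$viral_copies,
                spec$background_copies[["viral"]])
  bases_v <- sum(c_v * L)
  bg_m_bases <- sum((!is_virus) * spec$background_copies[["microbial"]] * L)
  c_m <- ifelse(is_virus, 0, spec$background_copies[["microbial"]])
  for (iter in 1:4) {
    bases_m <- bg_m_bases + sum(c_m[is_virus] * L[is_virus])
    c_m[is_virus] <- (c_v[is_virus] / folds[is_virus]) * bases_m / bases_v
  }
  abundance <- data.frame(
    contig_id = ids,
    viral_copies = c_v,
    microbial_copies = c_m,
    planted_fold = ifelse(is_virus, folds, NA_real_),
    stringsAsFactors = FALSE)

  lens <- setNames(truth_contigs$length, ids)
  topo <- setNames(truth_contigs$topology, ids)
  reads <- simulate_reads(lens, topo, abundance, spec)

  genes <- do.call(rbind, lapply(entries, function(e) e$genes))
  rownames(genes) <- NULL
  proteins <- unlist(lapply(entries, function(e) e$peptides))
  names(proteins) <- unlist(lapply(entries, function(e) names(e$peptides)))
  gene_families <- genes[, c("gene_id", "contig_id", "family")]

  # reference material standing in for public databases/literature:
  # held-out family members never placed on a community contig
  ref_member <- function(anc, d, n, prefix)
    setNames(vapply(seq_len(n), function(i) family_member(anc, d),
                    character(1)), sprintf("%s_%d", prefix, seq_len(n)))
  vmcp_db <- ref_member(pools$vmcp, spec$mcp_divergence, 3, "ref_VMCP")
  plv_mcp <- lapply(pools$groups, function(g)
    ref_member(pools$mcp[[g]], spec$mcp_divergence, 3,
               paste0("ref_MCP_", g)))
  names(plv_mcp) <- pools$groups
  core_dbs <- list(
    ATPase = ref_member(pools$atpase, 0.3, 3, "ref_ATPase"),
    mCP = ref_member(pools$mcp_minor, 0.3, 3, "ref_mCP"))
  shared_ref <- setNames(
    vapply(names(pools$shared), function(f)
      family_member(pools$shared[[f]], spec$accessory_divergence),
      character(1)),
    paste0("ref_", names(pools$shared)))
  # profiles: one per known MCP family (generator families are
  # substitution-only, so exemplars are already aligned)
  mcp_profiles <- lapply(plv_mcp, build_profile)
  mcp_profiles$virophage <- build_profile(vmcp_db)
  seed_db <- c(vmcp_db, core_dbs$ATPase, core_dbs$mCP, shared_ref)

  fraction_gb <- vapply(c("viral", "microbial"), function(fr)
    sum(reads$alignments$sample == fr) * spec$read_length / 1e9, numeric(1))

  contigs <- Biostrings::DNAStringSet(
    vapply(entries, function(e) e$seq, character(1)))
  names(contigs) <- ids

  structure(list(
    contigs = contigs,
    genes = genes[, c(gene_table_cols)],
    proteins = proteins,
    alignments = reads$alignments,
    fragments = reads$fragments,
    truth = list(contigs = truth_contigs, abundance = abundance,
                 integrations = if (length(integrations))
                   do.call(rbind, integrations) else NULL,
                 gene_families = gene_families,
                 ancestors = pools),
    reference = list(vmcp_db = vmcp_db, plv_mcp_db = unlist(plv_mcp),
                     plv_mcp_by_group = plv_mcp, core_dbs = core_dbs,
                     mcp_profiles = mcp_profiles, seed_db = seed_db),
    fraction_gb = fraction_gb,
    spec = spec), class = "community")
}

#' @export
print.community <- function(x, ...) {
  tc <- x$truth$contigs
  cat(sprintf(paste0(
    "synthetic community: %d contigs (%d PLV, %d virophage, %d background,",
    " %d integrated hosts),\n  %d genes, %d read placements",
    " (viral %.1f Mb, microbial %.1f Mb)\n"),
    nrow(tc), sum(tc$class == "PLV"), sum(tc$class == "virophage"),
    sum(tc$class == "background"), sum(tc$class == "integrated_host"),
    nrow(x$genes), nrow(x$alignments),
    x$fraction_gb[["viral"]] * 1e3, x$fraction_gb[["microbial"]] * 1e3))
  invisible(x)
}

#' Write a generated community to a directory
#'
#' Emits `contigs.fasta`, `proteins.faa`, `genes.tsv`, `alignments.tsv`
#' (truth dialect, both fractions, `sample` column), truth tables
#' (`truth_contigs.tsv`, `truth_abundance.tsv`, `truth_integrations.tsv`)
#' and the reference databases under `reference/`. Identical spec (and
#' seed) produces identical files.
#'
#' @param spec a [community_spec()] or an already generated `community`.
#' @param dir output directory (created if needed).
#' @return the `community`, invisibly.
#' @export
emit_community <- function(spec, dir) {
  comm <- if (inherits(spec, "community")) spec else generate_community(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reference"), showWarnings = FALSE)
  write_fasta(comm$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(Biostrings::AAStringSet(comm$proteins),
              file.path(dir, "proteins.faa"))
  write_gene_table(comm$genes, file.path(dir, "genes.tsv"))
  write_alignments(comm$alignments, file.path(dir, "alignments.tsv"))
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(comm$truth$contigs, "truth_contigs.tsv")
  wt(comm$truth$abundance, "truth_abundance.tsv")
  if (!is.null(comm$truth$integrations))
    wt(comm$truth$integrations, "truth_integrations.tsv")
  wt(comm$truth$gene_families, "truth_gene_families.tsv")
  write_fasta(Biostrings::AAStringSet(comm$reference$seed_db),
              file.path(dir, "reference", "seed_db.faa"))
  write_fasta(Biostrings::AAStringSet(comm$reference$vmcp_db),
              file.path(dir, "reference", "virophage_mcp.faa"))
  write_fasta(Biostrings::AAStringSet(comm$reference$plv_mcp_db),
              file.path(dir, "reference", "plv_mcp.faa"))
  for (nm in names(comm$reference$mcp_profiles))
    write_profile(comm$reference$mcp_profiles[[nm]],
                  file.path(dir, "reference",
                            sprintf("mcp_profile_%s.txt", nm)))
  invisible(comm)
}

#' Emit read sequences as FASTQ (optional end-to-end support)
#'
#' Materializes read sequences for one fraction from the truth placements,
#' applying substitution errors at `spec$error_rate`, with constant
#' Phred+33 quality. Mainly for running a real mapper end-to-end; the
#' pipeline itself consumes truth placements.
#'
#' @param community a generated `community`.
#' @param fraction `"viral"` or `"microbial"`.
#' @param path_r1,path_r2 output FASTQ files for mates 1 and 2.
#' @export
write_fastq <- function(community, fraction, path_r1, path_r2) {
  aln <- community$alignments
  aln <- aln[aln$sample == fraction, ]
  seqs <- as.character(community$contigs)
  bases <- c("A", "C", "G", "T")
  emit <- function(mate, path) {
    a <- aln[aln$mate_index == mate, ]
    con <- file(path, "w")
    on.exit(close(con))
    qual <- strrep("I", community$spec$read_length)
    for (i in seq_len(nrow(a))) {
      s <- substr(seqs[[a$contig_id[i]]], a$start[i] + 1, a$end[i])
      if (a$strand[i] == "-") s <- revcomp_chr(s)
      if (community$spec$error_rate > 0) s <- mutate_dna(s, community$spec$error_rate)
      writeLines(c(paste0("@", a$read_id[i], "/", mate), s, "+", qual), con)
    }
  }
  emit(1L, path_r1)
  emit(2L, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Build a mock transcriptome embedding capsid-gene ORFs
#'
#' Embeds reverse-translated MCP peptides as intact ORFs (ATG ... stop)
#' inside random transcript sequences, on a chosen strand and frame, for
#' validating the transcriptome screening stage.
#'
#' @param mcp_peptides named character vector of MCP peptides to embed.
#' @param frames frame for each transcript (`+1 +2 +3 -1 -2 -3`, recycled).
#' @param flank_min,flank_max random flank length bounds (nt).
#' @return list with `transcripts` (DNAStringSet) and `truth` (data.frame
#'   of `transcript_id, mcp_id, frame`).
#' @export
mock_transcriptome <- function(mcp_peptides,
                               frames = c("+1", "+2", "+3", "-1", "-2", "-3"),
                               flank_min = 60, flank_max = 400) {
  frames <- rep_len(frames, length(mcp_peptides))
  seqs <- character(length(mcp_peptides))
  for (i in seq_along(mcp_peptides)) {
    pep <- paste0("M", mcp_peptides[[i]])
    orf <- paste0(rev_translate(pep), "TAA")
    off <- as.integer(substr(frames[i], 2, 2)) - 1L
    left <- sample(flank_min:flank_max, 1)
    left <- left - (left %% 3) + off
    right <- sample(flank_min:flank_max, 1)
    s <- paste0(random_dna(left), orf, random_dna(right))
    if (startsWith(frames[i], "-")) s <- revcomp_chr(s)
    seqs[i] <- s
  }
  ids <- sprintf("transcript_%02d", seq_along(mcp_peptides))
  tx <- Biostrings::DNAStringSet(seqs)
  names(tx) <- ids
  list(transcripts = tx,
       truth = data.frame(transcript_id = ids,
                          mcp_id = names(mcp_peptides),
                          frame = frames, stringsAsFactors = FALSE))
}
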