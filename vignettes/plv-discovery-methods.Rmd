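---
title: "Discovering Polinton-like viruses and virophages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering Polinton-like viruses and virophages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Polinton-like viruses (PLVs) and virophages are small (10–41 kb) dsDNA
viruses of unicellular eukaryotes. They are nearly invisible to
reference-based metagenome annotation: most of their genes have no
detectable homologs, and their major capsid proteins (MCPs) — double
jelly-roll folds distantly related to giant-virus capsids — diverge so
far between groups that pairwise sequence search fails. What *does*
identify them is a combination of weak but numerous signals: shared gene
content with virophages, the core gene triad (MCP, minor capsid protein
mCP, DNA-packaging ATPase), genome completeness signatures (circular
read mapping, terminal inverted repeats), enrichment in the < 0.2 µm
size fraction of paired metagenomes, and membership in gene-sharing
networks.

`plvscout` implements that decision procedure end to end, together with
a synthetic community generator that plants every signal with known
ground truth, so each stage is testable without any external data or
service.

## The decision procedure

A contig enters the pipeline with its predicted genes. The classifier
applies the three-criterion *putative* rule: (1) at least 20% of the
contig's genes hit a virophage-derived bait database at BLASTP-style
E ≤ 1e−5, (2) the contig is 10–45 kb (inclusive at both ends — the
bounds are configurable, and the inclusive reading is the safer
convention for a descriptive range), (3) no virophage MCP is present
(a virophage MCP hit instead labels the contig a virophage). The 20%
counts *distinct genes with at least one hit*, not hit multiplicity,
so paralogs are not double-counted.

*Confirmation* additionally requires 10–41 kb and an identified MCP
gene. In the original procedure, MCP identification on remote homologs
was done with an interactive structure-aware service; `plvscout`
replaces that with a hit to a library of MCP profile models (one per
known capsid family) at E ≤ 1e−5 and labels the evidence source in the
output (`mcp_method`: `blast` for a direct hit to a known MCP,
`profile` for a profile-only call). A putative contig carrying ATPase
and mCP evidence but no MCP is kept as putative with
`fallback_core = TRUE`, never confirmed.

Detection is iterative (*bait expansion*): genes of newly confirmed
contigs join the bait database and the search repeats until no new
genome is confirmed. The confirmed set can only grow, and the fixed
point does not depend on contig order.

## Homology engine

All searches run on the package's own Smith–Waterman kernel (C++, affine
gaps costing `open + L·ext`, BLOSUM62 with gap 11/1 by default).
E-values use the Karlin–Altschul form `E = K·m·n·e^{−λS}` with the
published gapped BLOSUM62 parameters (λ = 0.267, K = 0.041). The `X`
residue is score-neutral. Traceback tie-breaks (diagonal over
gap-in-subject over gap-in-query, anchor at the first maximal cell in
row-major order) are fixed so coordinates are reproducible. A shared
k-mer prefilter (k = 4) skips pairs that cannot plausibly align;
`seed_k = 0` forces full dynamic programming, which the deepest-homology
tests use.

Profile models are position-specific log-odds scores with affine gap
states, not full Plan-7 HMMs: columns with more than 50% gaps are
masked, frequencies are pseudocount-smoothed against the background, and
scores are natural-log odds. Because log-odds scores are asymptotically
their own λ = 1 statistic, profile E-values reuse the Karlin–Altschul
form with λ = 1 and the default K *uncalibrated*. These E-values are
ranked thresholds, not calibrated significance — sufficient here because
every profile decision is a cutoff at 1e−5, and the contract that
matters (recovering family members that single-sequence search misses,
with zero decoys) is asserted directly by the test suite.

## Completeness calls

For contigs over 10 kb, non-proper read pairs with one mate in each
terminal 1000 bp window are collected; if their depth within the two
windows strictly exceeds 10% of the mean contig coverage, the contig is
flagged. Pair orientation disambiguates: mates oriented as a fragment
crossing the origin (5′-window mate on `−`, 3′-window mate on `+`) mean
*circular*; same-layout orientation means a terminal repeat. The
"coverage depth" of the evidence is computed as aligned bases of the
end-linking mates divided by the total window length (2 × 1000 bp), a
per-base quantity directly comparable to mean coverage; whether the
original rule intended the discordant-pair depth or total terminal
coverage is ambiguous, and this reading is the one that is mechanically
checkable. The decision is invariant to duplicating the alignment
stream, since both sides of the ratio scale together.

Sequence-level terminal repeats compare the first T bp against the last
T bp (T = min(2000, length/2)), directly and against the reverse
complement. Among lengths meeting the 95% identity floor, the reported
repeat end is the *score-maximal* boundary (match +1, mismatch −9,
break-even at 90% identity): without that trimming, chance matches just
past a repeat let the 95% cumulative rule drift ~20 bp beyond the true
boundary. Inverted repeats win ties, as the expected signature of
complete Polinton-like elements.

Target-site duplications are matched exactly, longest first, over
5–7 bp: at that length, mismatch tolerance would be meaningless.

## Dereplication

Genome dereplication is greedy in length order, CD-HIT style. Sequence
identity is estimated by exact k-mer seeding (k = 12) with diagonal
chaining — a megablast-style sketch, not a full alignment: within the
best co-linear chain, a k-mer survives substitution with probability
id^k, so identity ≈ containment^(1/k). Global identity (the `-G 1`
semantics) rescales by chain coverage of the shorter sequence; the
local mode enforces a coverage fraction of the longer sequence
(`-aL`). Circular awareness doubles the representative so rotations
match end to end. The sketch is validated against planted mutants and
rotations in the tests; it is an approximation and will under-estimate
identity for highly indel-rich divergence, which the substitution-only
generator does not produce and real users should note.

## Size-fraction enrichment

Recruitment is quantified as aligned bases (depth) rather than read
counts — the package reports both "coverage per Gb" and "Mb per Gb"
quantities, and depth is the primary mode because the normalized-depth
phrasing is the one used for per-contig abundance. Fold enrichment is
the ratio of normalized coverages; genomes with zero microbial coverage
are `viral_only` and excluded from the median (they cannot be ranked)
but counted. Whether the "95% or more reads from the viral fraction"
share uses normalized or raw counts is unstated in the source
procedure; normalized is used for cross-metagenome comparability. All
per-Gb statistics are exactly invariant to jointly rescaling a
fraction's reads and its metagenome size.

## Gene-sharing network

Protein clusters (PCs) are connected components of the all-vs-all hit
graph at E ≤ 1e−4 (a stricter cutoff can only refine the clustering,
never merge it) — a deliberate simplification of the Markov-clustering
step of the vConTACT v.2 procedure, chosen because components are
deterministic and oracle-testable. Genome–genome edges are weighted by
−log10 of the hypergeometric upper-tail probability of the observed PC
overlap. Virus clusters (VCs) are connected components above an edge
weight threshold; components of ≥ 3 genomes are VCs, 2 are pairs;
genomes sharing PCs without a supra-threshold edge are outliers, and
genomes sharing nothing are singletons.

The default threshold is *multiplicity-corrected*:
`−log10(0.05 / n_pairs)` over the number of evaluated genome pairs.
A fixed lenient threshold (e.g. 1.0) looks reasonable per edge, but
single-linkage components chain distinct groups through occasional
chance overlaps once hundreds of pairs are tested; the Bonferroni-style
default keeps the family-wise rate of spurious edges at 5% and recovers
planted groups exactly. The threshold remains a parameter for users who
want the lenient behavior.

Large-scale virus groups are read off as the PC of each genome's MCP,
which on planted communities agrees exactly with the generating groups
at MCP divergence ≤ 0.35.

## Host linkage

Transcriptome contigs are translated in all six frames and aligned
against the MCP database; the best hit per transcript is accepted at
E ≤ 1e−10 with ≥ 200 aligned residues. "Over 200 amino acids" is
implemented as ≥ 200 with the boundary configurable — a one-residue
boundary is biologically immaterial but must be pinned for tests — and
the length rule refers to alignment length (not subject coverage),
the natural reading for a translated search. The length rule dominates:
a 150-residue hit at E = 1e−30 is rejected.

## The synthetic community generator

The generator's defaults are the study conditions the pipeline targets:

* 8 PLV groups × 5 genomes plus 5 virophages, 20 background contigs and
  3 integrated elements; genomes 10–41 kb carrying MCP + mCP + ATPase
  plus 5–20 accessory genes;
* group-specific MCP families at 30% expected *pairwise* divergence
  (members are drawn from a family ancestor at the per-sequence rate
  that yields the requested pairwise divergence; divergence ≥ 0.95 is
  rejected as unrecoverable);
* accessory genes drawn from group-private pools and from a pool shared
  with virophages (probability 0.4) — the sharing that makes the 20%
  bait criterion and the gene-sharing network meaningful;
* topologies sampled as circular (0.5), linear with 300 bp terminal
  inverted repeats (0.3), linear (0.2); integrations flanked by 5–7 bp
  target-site duplications;
* paired 2 × 150 bp fragments with insert 450 ± 80 bp (bounded at
  800 bp), Poisson fragment counts proportional to copy number ×
  length, i.e. `copies` is expected fold-coverage (default 30× viral).
  The insert default matters for circularity detection: the expected
  end-linking evidence depth is `coverage × insert / (2 × window)`, so
  at 450 bp the rule's 10%-of-mean-coverage threshold is cleared with a
  ~3.7 σ Poisson margin at 30×, whereas a fully-overlapping 300 bp
  insert (unrealistic for a 2 × 150 library) would leave the published
  rule statistically marginal;
* per-genome viral:microbial fold enrichments drawn log-normally with
  median 190 for PLVs and 108 for virophages, clipped to 1–2816. The
  planted fold is defined on the normalized per-Gb scale the analysis
  reports, so microbial copy numbers are solved from a small fixed
  point involving the two fraction sizes;
* random peptides use Robinson–Robinson residue frequencies: uniform
  composition would inflate chance BLOSUM62 scores above what the
  Karlin–Altschul defaults model and produce spurious sub-1e−5 hits.

Two generator choices exist purely so planted truth is exact: the base
flanking a terminal repeat is forced to break the repeat (otherwise a
chance match extends the repeat past its planted end), and integration
points are re-drawn until the planted TSD is the unique detection
(otherwise flanking coincidences lengthen it).

What the generator does **not** emulate: indels and assembly errors,
low-complexity and compositionally biased proteins, gene prediction
errors, uneven coverage (GC bias), chimeric contigs, or real taxonomic
background. Passing tests therefore demonstrate that the decision
procedure is implemented correctly and recovers planted structure under
realistic divergence and sampling noise — not that the thresholds would
achieve the same precision on real lake viromes.

## Problem sizes and numerical choices

The shipped validation runs use the default community (68 contigs,
~1000 genes, ~320k read placements; detection ≈ 45 s, network ≈ 20 s on
one core), a 45-genome network community, and 300–1000-pair alignment
oracle panels; these sizes were chosen as the smallest at which every
planted signal is statistically unambiguous. Degenerate inputs are
defined, not errors: contigs with zero genes are rejected with reason
`no_genes`; empty search results and empty assemblies propagate as
empty tables; profile construction requires ≥ 2 sequences and a
non-ragged alignment; E-value floors use the smallest positive double
to keep −log10 weights finite.

## Known limitations

* Profile E-values are uncalibrated (see above); treat them as ranked
  thresholds.
* The dereplication identity sketch assumes substitution-dominated
  divergence.
* Hit lists are not expected to replicate BLAST's on real data: word
  size, composition-based statistics and low-complexity masking are not
  modeled (masking is off by default and there is no compositional
  adjustment).
* Integrated-element discovery relies on planted coordinates (or
  upstream annotation) for TSD checks; ab initio provirus boundary
  detection is out of scope.
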