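# fabricated hit tables and one-shot rule application, shared by the
# classifier unit tests and the acceptance boundary matrix

fake_hits <- function(gene_ids) {
  data.frame(query_id = gene_ids,
             subject_id = rep_len("bait", length(gene_ids)),
             evalue = rep_len(1e-10, length(gene_ids)),
             stringsAsFactors = FALSE)
}

apply_rules <- function(n_hit, n_genes, length, vmcp = FALSE,
                        mcp = TRUE, cfg = classifier_config()) {
  gid <- sprintf("g%02d", seq_len(n_genes))
  row <- flag_putative_plv("c", length, gid, fake_hits(head(gid, n_hit)),
                           vmcp, cfg)
  if (row$label == "putative_PLV") {
    prof <- if (mcp) data.frame(subject_id = gid[1], evalue = 1e-8)
            else data.frame(subject_id = character(0), evalue = numeric(0))
    row <- confirm_plv(row, length,
                       plvscout:::empty_hits(), prof,
                       list(ATPase = fake_hits(character(0)),
                            mCP = fake_hits(character(0))), gid, cfg)
  }
  row$label
}

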