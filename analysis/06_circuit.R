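#!/usr/bin/env Rscript
# Stage 6: circuit assembly. Validated forks sharing members are
# merged into connected components, edges are annotated with
# per-condition pairwise correlations, nodes with differential
# abundance, and a curated regulator gene is attached to the planted
# fork's focal compound to illustrate the regulator layer.

library(metafork)

met <- read_omics_table("results/data/metabolites.csv", "metabolite",
                        pathway_class_col = "pathway_class")
tr <- read_omics_table("results/data/expression.tsv", "transcript")
design <- read_design("results/data/design.tsv")
m <- combine_omics(
  log_transform(impute_min(subset_features(met, c("sulfur", "lipid", "sugar")))),
  log_transform(tr))

forks <- utils::read.table("results/forks.tsv", header = TRUE, sep = "\t")
screened <- utils::read.table("results/screened.tsv", header = TRUE,
                              sep = "\t")
de <- utils::read.table("results/de.tsv", header = TRUE, sep = "\t",
                        na.strings = "")

validated <- forks[forks$is_fork, ]
si <- match(paste(validated$A, validated$B, validated$C),
            paste(screened$A, screened$B, screened$C))
validated$cor_control <- screened$cor_control[si]
validated$cor_treatment <- screened$cor_treatment[si]
validated$delta <- screened$delta[si]

circ <- merge_forks(validated,
                    omic_type = setNames(m$omic_type, m$feature_id))
circ <- annotate_pairwise(circ, m, design)
circ <- annotate_de(circ, de)

# curated illustration: an expression regulator acting on the focal
# compound of the strongest fork
if (nrow(circ$forks) > 0) {
  reg <- data.frame(gene_id = "tr_null_001", target = circ$forks$A[1],
                    relation = "regulates")
  if (!reg$gene_id %in% circ$nodes$feature_id)
    circ <- attach_regulators(circ, reg, de)
}

write_circuit(circ, "results/circuit.json", "json")
write_circuit(circ, "results/circuit.graphml", "graphml")
write_result_tsv(circuit_components(circ), "results/components.tsv")

print(circ)
print(circuit_components(circ)[, c("component", "n_nodes", "n_forks")],
      row.names = FALSE)
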