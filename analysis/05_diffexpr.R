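#!/usr/bin/env Rscript
# Stage 5: per-feature differential abundance and expression. Welch's
# two-sample t-test on log values, treatment vs control, used to
# annotate circuit nodes with the direction of change.

library(metafork)

met <- read_omics_table("results/data/metabolites.csv", "metabolite",
                        pathway_class_col = "pathway_class")
tr <- read_omics_table("results/data/expression.tsv", "transcript")
design <- read_design("results/data/design.tsv")

de <- rbind(
  de_table(log_transform(impute_min(met)), design),
  de_table(log_transform(tr), design))
write_result_tsv(de, "results/de.tsv")

cat(nrow(de), "features tested;",
    sum(de$direction == "up"), "up,",
    sum(de$direction == "down"), "down at alpha = 0.05\n")
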