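#!/usr/bin/env Rscript
# Stage 4: model validation. Each screened candidate is fit in both
# directions (A ~ ratio and ratio ~ A) with a condition-by-predictor
# interaction; a triplet is a validated metabolic fork only when the
# interaction term is significant (p < .05) in both models.

library(metafork)

met <- read_omics_table("results/data/metabolites.csv", "metabolite",
                        pathway_class_col = "pathway_class")
tr <- read_omics_table("results/data/expression.tsv", "transcript")
design <- read_design("results/data/design.tsv")
m <- combine_omics(
  log_transform(impute_min(subset_features(met, c("sulfur", "lipid", "sugar")))),
  log_transform(tr))

screened <- utils::read.table("results/screened.tsv", header = TRUE,
                              sep = "\t")
forks <- batch_evaluate(screened, m, design, model_config())
write_result_tsv(forks, "results/forks.tsv")

cat(sum(forks$is_fork), "of", nrow(forks),
    "screened candidates validated as forks\n")
if (any(forks$is_fork))
  print(forks[forks$is_fork, c("A", "B", "C", "p_forward", "p_reverse")],
        row.names = FALSE)
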