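#!/usr/bin/env Rscript
# Stage 3: differential-correlation screen. Every triplet (A, {B, C})
# over the preprocessed features is scored by
# |cor(A, logB - logC)_treatment - cor(A, logB - logC)_control| and
# kept when the difference is 1.2 or greater. Cross-omic triplets use
# the nested 8+8 transcriptome samples.

library(metafork)

source_data <- function() {
  met <- read_omics_table("results/data/metabolites.csv", "metabolite",
                          pathway_class_col = "pathway_class")
  tr <- read_omics_table("results/data/expression.tsv", "transcript")
  design <- read_design("results/data/design.tsv")
  met_log <- log_transform(impute_min(subset_features(
    met, c("sulfur", "lipid", "sugar"))))
  list(m = combine_omics(met_log, log_transform(tr)), design = design)
}

ds <- source_data()
screened <- screen_triplets(ds$m, ds$design, screen_config())
write_result_tsv(screened, "results/screened.tsv")

cat(nrow(screened), "triplets screened over", length(ds$m$feature_id),
    "features;", sum(screened$passed), "pass the 1.2 threshold\n")
cat("largest deltas:\n")
print(utils::head(screened[order(-screened$delta),
                           c("A", "B", "C", "cor_control",
                             "cor_treatment", "delta")], 5),
      row.names = FALSE)
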