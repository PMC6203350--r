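#!/usr/bin/env Rscript
# Stage 2: data conditioning. Subset metabolites to the pathway
# classes under study, impute non-detects with each compound's
# minimum observed value, log-transform both omics (natural log,
# pseudocount 1 for FPKM zeros). Downstream correlations and
# interaction p-values are invariant to the base. Later stages
# re-derive the log matrices from the text tables, so no binary
# checkpoint is written — only the funnel record.

library(metafork)

met <- read_omics_table("results/data/metabolites.csv", "metabolite",
                        pathway_class_col = "pathway_class")
design <- read_design("results/data/design.tsv")

met_sel <- subset_features(met, c("sulfur", "lipid", "sugar"))
met_log <- log_transform(impute_min(met_sel))

dir.create("results/preprocessed", recursive = TRUE, showWarnings = FALSE)
writeLines(c("funnel\tbefore\tafter",
             sprintf("pathway_subset\t%d\t%d",
                     attr(met_sel, "funnel")[["before"]],
                     attr(met_sel, "funnel")[["after"]])),
           "results/preprocessed/funnel.tsv")
cat("retained", length(met_log$feature_id), "of", length(met$feature_id),
    "metabolites;", sum(is.na(met$values)), "non-detect cells imputed\n")
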