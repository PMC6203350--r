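#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-condition multi-omics dataset.
#
# Emulates the sampling structure the pipeline is designed for: 12
# control + 11 treatment metabolome samples, an 8+8 transcriptome
# subset nested within them, one planted metabolic fork (slope +1
# under control, -1 under treatment, noise sd 0.1) among 40 null
# metabolites and 20 null transcripts, with low-abundance non-detects
# masked at 2%.

library(metafork)

out <- "results/data"
d <- generate_synthetic(sim_config(seed = 1))
write_synthetic(d, out)

cat("metabolites:", nrow(d$metabolites$values), "features x",
    ncol(d$metabolites$values), "samples;",
    sum(is.na(d$metabolites$values)), "non-detect cells\n")
cat("transcripts:", nrow(d$transcripts$values), "features x",
    ncol(d$transcripts$values), "samples\n")
cat("planted fork:", paste(unlist(d$truth$planted[, c("A", "B", "C")]),
                           collapse = " / "),
    "with slopes", d$truth$planted$slope_control, "->",
    d$truth$planted$slope_treatment, "\n")
cat("tables written under", out, "\n")
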