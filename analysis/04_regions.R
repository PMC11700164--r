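#!/usr/bin/env Rscript
# Stage 4: regional aggregation. Weights each cluster's enrichment Z-score
# by the cluster's share of neuronal cells in each anatomical dissection
# and flags dissections whose weighted Z survives FDR.

suppressMessages(library(cellherit))

out <- "results"
comp_df <- read.delim(file.path(out, "composition.tsv"), check.names = FALSE)
comp <- as.matrix(comp_df[, -1])
rownames(comp) <- comp_df$cluster
hier <- read.delim(file.path(out, "hierarchy.tsv"))
enr <- read.delim(file.path(out, "cluster_enrichment.tsv"))

cluster_z <- setNames(enr$z, enr$annotation)
prop <- cluster_proportions(comp, hier, neuronal_only = TRUE)
reg <- dissection_enrichment(prop, cluster_z)
write.table(reg, file.path(out, "regional_enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

top <- reg[order(-reg$z), ][1, ]
cat(sprintf("top dissection: %s (Z = %.2f, fdr = %.2g); %d of %d at FDR<=0.05\n",
            top$dissection, top$z, top$fdr, sum(reg$fdr <= 0.05), nrow(reg)))
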