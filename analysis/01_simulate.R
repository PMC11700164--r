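#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs — gene annotation, cell-type
# atlas with planted cluster markers, GWAS summary statistics with an
# enriched SNP annotation, and two case/control connectivity datasets.
# Everything downstream (02-06) reads from results/.

suppressMessages(library(cellherit))

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = 20260924L, marker_fold = 8, enrich_tau = 10,
                  n_individuals = 5000L, h2 = 0.4,
                  delta_pairs = list(c(3L, 7L, 0.5)))

ann <- generate_gene_annotation(cfg)
atlas <- generate_atlas(cfg)
write.table(ann, file.path(out, "gene_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(atlas$expr), atlas$expr,
                       check.names = FALSE),
            file.path(out, "expression_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(atlas$hierarchy, file.path(out, "hierarchy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster = rownames(atlas$composition),
                       atlas$composition, check.names = FALSE),
            file.path(out, "composition.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
truth <- lapply(atlas$truth$marker_genes, as.list)
jsonlite::write_json(truth, file.path(out, "marker_truth.json"),
                     auto_unbox = FALSE)

cat(sprintf("simulated %d genes x %d clusters; %d markers planted\n",
            cfg$n_genes, cfg$n_clusters,
            sum(lengths(atlas$truth$marker_genes))))
cat("config seed:", cfg$seed, "\n")
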