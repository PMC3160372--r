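#!/usr/bin/env Rscript
# Step 2: run the State-Change filter chain (quantile normalization, log2,
# moderated two-group contrast, BH <= 0.05, |fold change| > 1.3) on the
# simulated experiment.

source("analysis/00_config.R")

m <- as.matrix(read.csv(file.path(OUT_DIR, "matrix.csv"), row.names = 1))
groups <- read.delim(file.path(OUT_DIR, "groups.tsv"))
mat <- expression_matrix(m, groups$group,
                         setNames(rownames(m), rownames(m)))

chain <- state_change_chain(mat, de_thresholds())
sc <- chain$state_changes
cat("State Changes:", length(sc$changes), "of", length(sc$universe),
    "measured genes (", sum(sc$changes > 0), "up /", sum(sc$changes < 0),
    "down )\n")

write.table(chain$results, file.path(OUT_DIR, "probe_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = names(sc$changes), direction = sc$changes),
            file.path(OUT_DIR, "state_changes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote probe_results.tsv, state_changes.tsv under", OUT_DIR, "\n")
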