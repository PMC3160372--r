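#!/usr/bin/env Rscript
# Step 1: build the synthetic causal knowledge graph and the matched
# two-group expression experiment with planted active controllers.

source("analysis/00_config.R")

cfg <- benchmark_config()
graph <- simulate_kam(cfg)
sim <- simulate_expression(graph, cfg)

cen <- census(graph)
cat("Simulated knowledge graph:", cen$total_nodes, "nodes,",
    cen$causal_edge_count, "causal edges\n")
cat("Planted", nrow(sim$truth$active), "active controllers over",
    length(sim$truth$downstream_expected), "downstream genes;",
    length(sim$truth$conflicts), "sign conflicts\n")

save_graph(graph, file.path(OUT_DIR, "graph.tsv"), "native-tsv")
write.csv(sim$matrix$intensities, file.path(OUT_DIR, "matrix.csv"))
write.table(data.frame(sample = colnames(sim$matrix$intensities),
                       group = sim$matrix$groups),
            file.path(OUT_DIR, "groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(controller = sim$truth$active$controller_id,
                       direction = sim$truth$active$direction),
            file.path(OUT_DIR, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote graph.tsv, matrix.csv, groups.tsv, truth.tsv under", OUT_DIR, "\n")
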