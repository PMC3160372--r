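#!/usr/bin/env Rscript
# Step 3: score every (controller, direction) hypothesis against the observed
# State Changes with hypergeometric richness and binomial concordance.

source("analysis/00_config.R")

graph <- load_graph(file.path(OUT_DIR, "graph.tsv"), "native-tsv")
sc_tab <- read.delim(file.path(OUT_DIR, "state_changes.tsv"))
pr <- read.delim(file.path(OUT_DIR, "probe_results.tsv"))

state_changes <- structure(
  list(changes = setNames(as.integer(sc_tab$direction), sc_tab$gene),
       universe = pr$probe_id),
  class = "state_change_set")

hyp <- generate_hypotheses(graph, state_changes, rcr_config())
sig <- hyp[hyp$significant, ]
cat("Scored", nrow(hyp), "hypotheses;", nrow(sig), "significant\n")
cat("Top significant hypotheses:\n")
print(utils::head(sig[, c("node_id", "direction", "n_overlap", "n_correct",
                          "richness_p", "concordance_p")], 10),
      row.names = FALSE)

write.table(hyp, file.path(OUT_DIR, "hypotheses.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Wrote hypotheses.tsv under", OUT_DIR, "\n")
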