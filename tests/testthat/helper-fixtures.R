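# Fixture builders shared across test files.

# Small curated-style graph: a kinase activity driving three mRNAs (two up,
# one down), its root protein, and a second controller sharing one target
# with the opposite sign.
toy_graph <- function() {
  nodes <- data.frame(
    node_id = c("CDK2", "kaof(CDK2)", "taof(TF1)",
                "exp(m1)", "exp(m2)", "exp(m3)"),
    label = c("CDK2", "kaof(CDK2)", "taof(TF1)",
              "exp(m1)", "exp(m2)", "exp(m3)"),
    entity_class = c("protein", "activity", "activity",
                     "mRNA", "mRNA", "mRNA"),
    base_entity = c("", "CDK2", "TF1", "m1", "m2", "m3"),
    modification = "",
    activity_kind = c("", "kinase", "transcriptional", "", "", ""),
    species_scope = "human",
    block_tag = c("CellCycle", "CellCycle", "", "CellCycle", "", ""),
    stringsAsFactors = FALSE)
  causal <- data.frame(
    source = c("kaof(CDK2)", "kaof(CDK2)", "kaof(CDK2)", "taof(TF1)"),
    target = c("exp(m1)", "exp(m2)", "exp(m3)", "exp(m1)"),
    sign = c(1L, 1L, -1L, -1L),
    stringsAsFactors = FALSE)
  evidence <- data.frame(
    source = causal$source, target = causal$target, sign = causal$sign,
    citation_id = c("PMID:1", "PMID:1", "PMID:2", "PMID:3"),
    quote = c("q1", "q2", "q3", "q4"),
    species = c("human", "human", "mouse", "human"),
    tissue = c("lung", "lung", "fibroblast", "lung"),
    stringsAsFactors = FALSE)
  noncausal <- data.frame(source = "CDK2", target = "kaof(CDK2)",
                          relation = "has-activity", stringsAsFactors = FALSE)
  causal_graph(nodes, causal, noncausal, evidence,
               metadata = list(name = "toy", species = "human"))
}

# Random valid graph for property tests: n_ctrl activity nodes wired to a
# pool of mRNA nodes with random signs and evidence.
random_graph <- function(seed, n_ctrl = 4, n_genes = 12) {
  set.seed(seed)
  ctrl <- sprintf("c%02d", seq_len(n_ctrl))
  genes <- sprintf("g%02d", seq_len(n_genes))
  nodes <- rbind(
    data.frame(node_id = ctrl, label = ctrl, entity_class = "activity",
               base_entity = toupper(ctrl), modification = "",
               activity_kind = "transcriptional", species_scope = "human",
               block_tag = "", stringsAsFactors = FALSE),
    data.frame(node_id = paste0("exp(", genes, ")"),
               label = paste0("exp(", genes, ")"),
               entity_class = "mRNA", base_entity = genes, modification = "",
               activity_kind = "", species_scope = "human", block_tag = "",
               stringsAsFactors = FALSE))
  edges <- do.call(rbind, lapply(ctrl, function(cc) {
    tg <- sample(genes, sample(2:6, 1))
    data.frame(source = cc, target = paste0("exp(", tg, ")"),
               sign = sample(c(-1L, 1L), length(tg), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  evidence <- data.frame(
    source = edges$source, target = edges$target, sign = edges$sign,
    citation_id = paste0("PMID:", sample(100:999, nrow(edges))),
    quote = paste0("evidence ", seq_len(nrow(edges))),
    species = sample(c("human", "mouse", "rat"), nrow(edges), replace = TRUE),
    tissue = "lung", stringsAsFactors = FALSE)
  causal_graph(nodes, edges, evidence = evidence,
               metadata = list(name = paste0("rand", seed)))
}

# Expression matrix with prescribed per-gene group means (log2) and noise.
toy_expression <- function(means_control, means_treated, noise_sd = 0.2,
                           n_rep = 3, seed = 1) {
  set.seed(seed)
  genes <- names(means_control)
  lg <- cbind(
    matrix(rnorm(length(genes) * n_rep, means_control, noise_sd),
           ncol = n_rep),
    matrix(rnorm(length(genes) * n_rep, means_treated, noise_sd),
           ncol = n_rep))
  rownames(lg) <- genes
  colnames(lg) <- c(paste0("c", 1:n_rep), paste0("t", 1:n_rep))
  expression_matrix(2^lg, rep(c("control", "treated"), each = n_rep),
                    setNames(genes, genes), scale = "linear")
}

# Brute-force BH step-up definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive richness oracle: enumerate all changed-gene subsets of the
# universe and count those with at least n_overlap hits among the targets.
richness_brute <- function(n_universe, n_targets, n_changed, n_overlap) {
  if (n_changed == 0) return(as.numeric(n_overlap == 0))
  subsets <- utils::combn(n_universe, n_changed)
  hits <- colSums(subsets <= n_targets)  # targets are genes 1..n_targets
  mean(hits >= n_overlap)
}

# Exhaustive concordance oracle at q = 0.5: all 2^n direction assignments.
concordance_brute <- function(n, c) {
  if (n == 0) return(as.numeric(c <= 0))
  matches <- vapply(0:(2^n - 1), function(m)
    sum(bitwAnd(m, 2^(0:(n - 1))) > 0), numeric(1))
  mean(matches >= c)
}
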