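test_that("constructor merges duplicate causal edges and accumulates evidence", {
  g <- toy_graph()
  dup_edges <- rbind(g$causal_edges, g$causal_edges[1, ])
  extra_ev <- g$evidence[1, ]
  extra_ev$citation_id <- "PMID:99"
  g2 <- causal_graph(g$nodes, dup_edges, g$noncausal_edges,
                     rbind(g$evidence, extra_ev), g$metadata)
  expect_equal(nrow(g2$causal_edges), nrow(g$causal_edges))
  expect_equal(nrow(g2$evidence), nrow(g$evidence) + 1)
})

test_that("validation rejects invariant violations", {
  g <- toy_graph()
  bad_nodes <- g$nodes
  bad_nodes$entity_class[1] <- "gene"
  expect_error(causal_graph(bad_nodes, g$causal_edges, g$noncausal_edges,
                            g$evidence), "entity_class")
  bad_edges <- g$causal_edges
  bad_edges$target[1] <- "exp(nowhere)"
  expect_error(causal_graph(g$nodes, bad_edges, g$noncausal_edges), "dangling")
  self <- g$causal_edges
  self$target[1] <- self$source[1]
  expect_error(causal_graph(g$nodes, self, g$noncausal_edges), "self-edge")
  bad_nc <- g$noncausal_edges
  bad_nc$relation <- "binds"
  expect_error(causal_graph(g$nodes, g$causal_edges, bad_nc), "relation")
  # modification field must pair exactly with the modified-protein class
  mod_nodes <- g$nodes
  mod_nodes$modification[1] <- "P@S373"
  expect_error(causal_graph(mod_nodes, g$causal_edges, g$noncausal_edges),
               "modification")
})

test_that("census counts classes, edges and unique citations", {
  g <- toy_graph()
  cen <- census(g)
  expect_equal(cen$total_nodes, 6)
  expect_equal(unname(cen$class_counts[["mRNA"]]), 3)
  expect_equal(unname(cen$class_counts[["activity"]]), 2)
  expect_equal(cen$causal_edge_count, 4)
  expect_equal(cen$noncausal_edge_count, 1)
  expect_equal(cen$total_edges, 5)
  expect_equal(cen$unique_citation_count, 3)  # PMID:1 shared by two edges
  expect_equal(sum(cen$class_counts), cen$total_nodes)

  empty <- census(causal_graph())
  expect_equal(empty$total_nodes, 0)
  expect_equal(empty$total_edges, 0)
  expect_equal(empty$unique_citation_count, 0)
})

test_that("census conservation holds on random graphs", {
  for (seed in 1:10) {
    cen <- census(random_graph(seed))
    expect_equal(sum(cen$class_counts), cen$total_nodes)
    expect_equal(cen$causal_edge_count + cen$noncausal_edge_count,
                 cen$total_edges)
  }
})

test_that("downstream targets at depth 1 carry edge signs, conflicts ambiguous", {
  g <- toy_graph()
  tg <- downstream_mrna_targets(g, "kaof(CDK2)")
  expect_setequal(tg$gene, c("m1", "m2", "m3"))
  expect_equal(tg$sign[tg$gene == "m1"], 1L)
  expect_equal(tg$sign[tg$gene == "m3"], -1L)

  # m1 reached by + and - edges from a single node -> ambiguous
  conf <- causal_graph(
    g$nodes,
    data.frame(source = "kaof(CDK2)", target = c("exp(m1)", "exp(m1)"),
               sign = c(1L, -1L), stringsAsFactors = FALSE))
  tg2 <- downstream_mrna_targets(conf, "kaof(CDK2)")
  expect_equal(tg2$sign[tg2$gene == "m1"], 0L)

  expect_error(downstream_mrna_targets(g, "nope"), "unknown node")
})

test_that("depth-1 targets equal a brute-force scan of the edge list", {
  for (seed in 1:8) {
    g <- random_graph(seed)
    for (nd in unique(g$causal_edges$source)) {
      tg <- downstream_mrna_targets(g, nd)
      e <- g$causal_edges[g$causal_edges$source == nd, ]
      expected <- tapply(e$sign, e$target, function(s)
        if (length(unique(s)) > 1) 0L else unique(s))
      expect_setequal(tg$node_id, names(expected))
      expect_equal(tg$sign, as.integer(expected[tg$node_id]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("path sign at depth 2 is the product of edge signs", {
  nodes <- data.frame(
    node_id = c("a", "b", "exp(m)"), label = c("a", "b", "exp(m)"),
    entity_class = c("activity", "activity", "mRNA"),
    base_entity = c("A", "B", "m"), modification = "",
    activity_kind = c("kinase", "kinase", ""), species_scope = "",
    block_tag = "", stringsAsFactors = FALSE)
  edges <- data.frame(source = c("a", "b"), target = c("b", "exp(m)"),
                      sign = c(-1L, 1L), stringsAsFactors = FALSE)
  g <- causal_graph(nodes, edges)
  expect_equal(nrow(downstream_mrna_targets(g, "a", depth = 1)), 0)
  tg <- downstream_mrna_targets(g, "a", depth = 2)
  expect_equal(tg$sign, -1L)  # (-1) x (+1)

  # brute-force path enumeration oracle on random graphs, depth 2
  enumerate_paths <- function(g, node, depth) {
    ce <- g$causal_edges
    walk <- function(cur, sgn, d) {
      out <- list()
      nxt <- ce[ce$source == cur, , drop = FALSE]
      for (i in seq_len(nrow(nxt))) {
        s <- sgn * nxt$sign[i]
        out[[length(out) + 1L]] <- data.frame(node = nxt$target[i], sign = s)
        if (d > 1) out <- c(out, list(walk(nxt$target[i], s, d - 1)))
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(node = character(), sign = integer())
    }
    walk(node, 1L, depth)
  }
  for (seed in 1:5) {
    g2 <- random_graph(seed, n_ctrl = 5, n_genes = 8)
    nd <- g2$causal_edges$source[1]
    paths <- enumerate_paths(g2, nd, 2)
    mrna <- g2$nodes$node_id[g2$nodes$entity_class == "mRNA"]
    paths <- paths[paths$node %in% setdiff(mrna, nd), , drop = FALSE]
    expected <- tapply(paths$sign, paths$node, function(s) {
      u <- unique(s)
      if (length(u) > 1) 0L else u
    })
    tg <- downstream_mrna_targets(g2, nd, depth = 2)
    expect_setequal(tg$node_id, names(expected))
    expect_equal(tg$sign, as.integer(expected[tg$node_id]),
                 ignore_attr = TRUE)
  }
})

test_that("ortholog augmentation translates edges with donor evidence", {
  base <- toy_graph()
  donor <- random_graph(3)
  map <- data.frame(donor_id = c("c01", "exp(g01)", "exp(g02)"),
                    base_id = c("taof(TF1)", "exp(m2)", "exp(m3)"),
                    stringsAsFactors = FALSE)
  aug <- augment_with_orthologs(base, donor, map)
  de <- donor$causal_edges[donor$causal_edges$source == "c01", ]
  translatable <- de[de$target %in% c("exp(g01)", "exp(g02)"), ]
  expect_equal(nrow(aug$causal_edges),
               nrow(base$causal_edges) + nrow(translatable))
  expect_equal(attr(aug, "skipped_edges"),
               nrow(donor$causal_edges) - nrow(translatable))
  # donor evidence rides along
  if (nrow(translatable) > 0) {
    ev <- aug$evidence[aug$evidence$source == "taof(TF1)" &
                         aug$evidence$target %in% c("exp(m2)", "exp(m3)"), ]
    expect_true(all(grepl("^PMID:", ev$citation_id)))
  }
})

test_that("ortholog augmentation is idempotent and merges existing edges", {
  base <- toy_graph()
  donor <- random_graph(4)
  map <- data.frame(donor_id = c("c01", "exp(g01)", "exp(g02)", "exp(g03)"),
                    base_id = c("kaof(CDK2)", "exp(m1)", "exp(m2)", "exp(m3)"),
                    stringsAsFactors = FALSE)
  once <- augment_with_orthologs(base, donor, map)
  twice <- augment_with_orthologs(once, donor, map)
  attr(once, "skipped_edges") <- NULL
  attr(twice, "skipped_edges") <- NULL
  expect_identical(twice, once)
})

test_that("many-to-many ortholog policies expand or skip", {
  base <- toy_graph()
  nodes <- data.frame(node_id = c("d1", "exp(x)"), label = c("d1", "exp(x)"),
                      entity_class = c("activity", "mRNA"),
                      base_entity = c("D1", "x"), modification = "",
                      activity_kind = c("kinase", ""), species_scope = "",
                      block_tag = "", stringsAsFactors = FALSE)
  donor <- causal_graph(nodes, data.frame(source = "d1", target = "exp(x)",
                                          sign = 1L))
  # taof(TF1) has no existing edges to m2/m3, so both expansions are new
  map <- data.frame(donor_id = c("d1", "exp(x)", "exp(x)"),
                    base_id = c("taof(TF1)", "exp(m2)", "exp(m3)"),
                    stringsAsFactors = FALSE)
  expanded <- augment_with_orthologs(base, donor, map, policy = "expand-all")
  expect_equal(nrow(expanded$causal_edges), nrow(base$causal_edges) + 2)
  skipped <- augment_with_orthologs(base, donor, map, policy = "skip-ambiguous")
  expect_equal(nrow(skipped$causal_edges), nrow(base$causal_edges))
  expect_equal(attr(skipped, "skipped_edges"), 1L)
})

test_that("subgraph by building-block tag induces on tagged nodes", {
  g <- toy_graph()
  sub <- subgraph_by_tag(g, "CellCycle")
  expect_setequal(sub$nodes$node_id,
                  c("CDK2", "kaof(CDK2)", "exp(m1)"))
  expect_equal(nrow(sub$causal_edges), 1)  # kaof(CDK2) -> exp(m1)
  expect_equal(nrow(sub$noncausal_edges), 1)

  none <- subgraph_by_tag(g, "Epigenetics")
  expect_equal(nrow(none$nodes), 0)

  all_tagged <- g
  all_tagged$nodes$block_tag <- "X"
  all_g <- causal_graph(all_tagged$nodes, g$causal_edges, g$noncausal_edges,
                        g$evidence, g$metadata)
  sub_all <- subgraph_by_tag(all_g, "X")
  expect_equal(census(sub_all)$total_edges, census(g)$total_edges)
})
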