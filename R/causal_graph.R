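#' @importFrom stats phyper pbinom pt rnorm setNames medpolish p.adjust var
#' @importFrom utils read.delim write.table head
NULL

## Closed vocabularies for the knowledge-graph data model.
entity_classes <- function() {
  c("mRNA", "protein", "modified-protein", "activity", "complex",
    "protein-family", "biological-process", "proxy", "other")
}

noncausal_relations <- function() {
  c("has-activity", "has-modified-form", "has-member", "has-component")
}

evidence_species <- function() c("human", "mouse", "rat", "unspecified")

empty_nodes <- function() {
  data.frame(node_id = character(), label = character(),
             entity_class = character(), base_entity = character(),
             modification = character(), activity_kind = character(),
             species_scope = character(), block_tag = character(),
             stringsAsFactors = FALSE)
}

empty_causal_edges <- function() {
  data.frame(source = character(), target = character(), sign = integer(),
             stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(source = character(), target = character(), sign = integer(),
             citation_id = character(), quote = character(),
             species = character(), tissue = character(),
             stringsAsFactors = FALSE)
}

empty_noncausal_edges <- function() {
  data.frame(source = character(), target = character(), relation = character(),
             stringsAsFactors = FALSE)
}

fill_node_columns <- function(nodes) {
  template <- empty_nodes()
  for (col in names(template)) {
    if (is.null(nodes[[col]])) nodes[[col]] <- ""
    nodes[[col]] <- as.character(nodes[[col]])
    nodes[[col]][is.na(nodes[[col]])] <- ""
  }
  nodes[, names(template), drop = FALSE]
}

#' Construct a signed causal knowledge graph
#'
#' A `causal_graph` holds typed biological entity nodes (mRNAs, proteins,
#' modified proteins, activities, complexes, families, processes, proxies),
#' signed causal edges (`+1` increases, `-1` decreases) each backed by one or
#' more literature-evidence records, and unsigned non-causal edges that link
#' different forms of the same entity (a protein to its kinase activity, to a
#' phosphorylated form, a family to its members, a complex to its components).
#'
#' Duplicate causal edges — identical `(source, target, sign)` — are merged,
#' with their evidence records accumulated. Self-edges are rejected. Every
#' edge endpoint must be a declared node.
#'
#' @param nodes data frame with columns `node_id`, `label`, `entity_class`
#'   and optionally `base_entity`, `modification`, `activity_kind`,
#'   `species_scope` (comma-separated subset of human/mouse/rat) and
#'   `block_tag` (comma-separated building-block labels).
#' @param causal_edges data frame with columns `source`, `target`,
#'   `sign` (+1/-1).
#' @param noncausal_edges data frame with columns `source`, `target`,
#'   `relation` (one of `has-activity`, `has-modified-form`, `has-member`,
#'   `has-component`).
#' @param evidence data frame with columns `source`, `target`, `sign`,
#'   `citation_id`, `quote`, `species`, `tissue`; one row per evidence record
#'   supporting a causal edge.
#' @param metadata named list; conventionally `name`, `species`, `provenance`.
#' @return an object of class `causal_graph`.
#' @export
causal_graph <- function(nodes = empty_nodes(),
                         causal_edges = empty_causal_edges(),
                         noncausal_edges = empty_noncausal_edges(),
                         evidence = empty_evidence(),
                         metadata = list()) {
  nodes <- fill_node_columns(as.data.frame(nodes, stringsAsFactors = FALSE))

  causal_edges <- as.data.frame(causal_edges, stringsAsFactors = FALSE)
  if (nrow(causal_edges) == 0) causal_edges <- empty_causal_edges()
  causal_edges$sign <- as.integer(causal_edges$sign)

  noncausal_edges <- as.data.frame(noncausal_edges, stringsAsFactors = FALSE)
  if (nrow(noncausal_edges) == 0) noncausal_edges <- empty_noncausal_edges()

  evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
  if (nrow(evidence) == 0) {
    evidence <- empty_evidence()
  } else {
    for (col in c("citation_id", "quote", "species", "tissue")) {
      if (is.null(evidence[[col]])) evidence[[col]] <- ""
      evidence[[col]][is.na(evidence[[col]])] <- ""
    }
    evidence$sign <- as.integer(evidence$sign)
    evidence <- evidence[, names(empty_evidence()), drop = FALSE]
  }

  ## merge duplicate (source, target, sign) causal edges; evidence accumulates
  if (nrow(causal_edges) > 0) {
    key <- paste(causal_edges$source, causal_edges$target, causal_edges$sign,
                 sep = "\r")
    causal_edges <- causal_edges[!duplicated(key), , drop = FALSE]
    rownames(causal_edges) <- NULL
  }
  if (nrow(evidence) > 0) {
    evidence <- unique(evidence)
    rownames(evidence) <- NULL
  }

  g <- structure(list(nodes = nodes,
                      causal_edges = causal_edges,
                      noncausal_edges = noncausal_edges,
                      evidence = evidence,
                      metadata = metadata),
                 class = "causal_graph")
  validate_graph(g)
  ## canonical sort order so structurally equal graphs are identical()
  canonicalize_graph(g)
}

#' Validate a causal graph against its structural invariants
#'
#' Checks node-id uniqueness, the closed entity-class and relation
#' vocabularies, the modified-protein/activity field constraints, sign
#' validity, absence of self-edges, and referential integrity of every edge
#' endpoint. Cycles are legal (biological feedback).
#'
#' @param g a `causal_graph`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "causal_graph"))
  n <- g$nodes
  if (anyDuplicated(n$node_id)) {
    stop("duplicate node_id: ", n$node_id[duplicated(n$node_id)][1])
  }
  bad <- setdiff(unique(n$entity_class), entity_classes())
  if (length(bad)) stop("unknown entity_class: ", paste(bad, collapse = ", "))
  mod_bad <- (n$entity_class == "modified-protein") != (n$modification != "")
  if (any(mod_bad)) {
    stop("modification must be set exactly for modified-protein nodes: ",
         n$node_id[mod_bad][1])
  }
  act_bad <- (n$entity_class == "activity") != (n$activity_kind != "")
  if (any(act_bad)) {
    stop("activity_kind must be set exactly for activity nodes: ",
         n$node_id[act_bad][1])
  }

  ce <- g$causal_edges
  if (nrow(ce) > 0) {
    if (!all(ce$sign %in% c(-1L, 1L))) stop("causal edge sign must be +1 or -1")
    if (any(ce$source == ce$target)) {
      stop("self-edge not allowed: ", ce$source[ce$source == ce$target][1])
    }
  }
  nce <- g$noncausal_edges
  if (nrow(nce) > 0) {
    bad <- setdiff(unique(nce$relation), noncausal_relations())
    if (length(bad)) stop("unknown non-causal relation: ", paste(bad, collapse = ", "))
  }
  ids <- n$node_id
  endpoints <- c(ce$source, ce$target, nce$source, nce$target)
  dangling <- setdiff(unique(endpoints), ids)
  if (length(dangling)) {
    stop("dangling edge endpoint(s): ", paste(head(dangling, 5), collapse = ", "))
  }
  ev <- g$evidence
  if (nrow(ev) > 0) {
    ekey <- paste(ce$source, ce$target, ce$sign, sep = "\r")
    vkey <- paste(ev$source, ev$target, ev$sign, sep = "\r")
    orphan <- setdiff(unique(vkey), ekey)
    if (length(orphan)) stop("evidence row without matching causal edge")
    bad <- setdiff(unique(ev$species), c(evidence_species(), ""))
    if (length(bad)) stop("unknown evidence species: ", paste(bad, collapse = ", "))
  }
  invisible(g)
}

#' @export
print.causal_graph <- function(x, ...) {
  cen <- census(x)
  cat("<causal_graph>",
      if (!is.null(x$metadata$name)) paste0(" ", x$metadata$name), "\n",
      "  nodes: ", cen$total_nodes,
      "  causal edges: ", cen$causal_edge_count,
      "  non-causal edges: ", cen$noncausal_edge_count,
      "  citations: ", cen$unique_citation_count, "\n", sep = "")
  invisible(x)
}

#' Census of a causal graph
#'
#' Tabulates node counts per entity class, causal and non-causal edge counts,
#' and the number of distinct citation identifiers over all causal-edge
#' evidence records — the statistics conventionally reported for a curated
#' network (nodes, mRNAs, proteins, phosphoproteins, activities, complexes,
#' protein families, biological processes, proxies, total edges, causal
#' edges, unique source citations).
#'
#' @param g a `causal_graph`.
#' @return a list of class `network_census` with `class_counts` (named
#'   integer vector over the entity-class vocabulary), `total_nodes`,
#'   `total_edges`, `causal_edge_count`, `noncausal_edge_count` and
#'   `unique_citation_count`.
#' @export
census <- function(g) {
  stopifnot(inherits(g, "causal_graph"))
  cls <- factor(g$nodes$entity_class, levels = entity_classes())
  class_counts <- as.integer(table(cls))
  names(class_counts) <- entity_classes()
  cit <- g$evidence$citation_id
  cit <- unique(cit[!is.na(cit) & cit != ""])
  structure(list(
    class_counts = class_counts,
    total_nodes = nrow(g$nodes),
    causal_edge_count = nrow(g$causal_edges),
    noncausal_edge_count = nrow(g$noncausal_edges),
    total_edges = nrow(g$causal_edges) + nrow(g$noncausal_edges),
    unique_citation_count = length(cit)
  ), class = "network_census")
}

#' @export
print.network_census <- function(x, ...) {
  cat("Nodes:", x$total_nodes, "\n")
  for (cl in names(x$class_counts)) {
    if (x$class_counts[[cl]] > 0) cat("  ", cl, ": ", x$class_counts[[cl]], "\n", sep = "")
  }
  cat("Total edges:", x$total_edges,
      "(causal", x$causal_edge_count,
      "/ non-causal", x$noncausal_edge_count, ")\n")
  cat("Unique citations:", x$unique_citation_count, "\n")
  invisible(x)
}

#' Signed downstream mRNA targets of a node
#'
#' Walks causal edges outward from `node` up to `depth` steps and returns
#' every mRNA-class node reached, with the sign of the path (product of edge
#' signs). A gene reachable with both `+1` and `-1` path signs is flagged
#' ambiguous (`sign = 0`): it is evidence of connectivity but carries no
#' usable direction.
#'
#' @param g a `causal_graph`.
#' @param node node identifier to start from.
#' @param depth maximum causal path length (default 1: direct transcriptional
#'   consequences only, the standard substrate for upstream-controller
#'   scoring).
#' @return data frame with columns `gene` (the mRNA node's gene symbol,
#'   taken from `base_entity` when set, else `label`), `node_id`, and `sign`
#'   in `{-1, 0, +1}` where 0 marks an ambiguous (conflicting-sign) target.
#' @export
downstream_mrna_targets <- function(g, node, depth = 1L) {
  stopifnot(inherits(g, "causal_graph"), depth >= 1)
  if (!node %in% g$nodes$node_id) stop("unknown node: ", node)
  ce <- g$causal_edges
  mrna_ids <- g$nodes$node_id[g$nodes$entity_class == "mRNA"]

  ## reachable (node, path-sign) states, by path length 1..depth
  reached_pos <- character(0)  # nodes reached with + path sign
  reached_neg <- character(0)
  frontier <- data.frame(node = node, psign = 1L, stringsAsFactors = FALSE)
  for (step in seq_len(depth)) {
    hit <- merge(frontier, ce, by.x = "node", by.y = "source")
    if (nrow(hit) == 0) break
    nxt <- unique(data.frame(node = hit$target,
                             psign = hit$psign * hit$sign,
                             stringsAsFactors = FALSE))
    reached_pos <- union(reached_pos, nxt$node[nxt$psign == 1L])
    reached_neg <- union(reached_neg, nxt$node[nxt$psign == -1L])
    frontier <- nxt
  }

  pos <- intersect(reached_pos, mrna_ids)
  neg <- intersect(reached_neg, mrna_ids)
  both <- intersect(pos, neg)
  ids <- union(pos, neg)
  ids <- setdiff(ids, node)
  if (length(ids) == 0) {
    return(data.frame(gene = character(), node_id = character(),
                      sign = integer(), stringsAsFactors = FALSE))
  }
  sign <- ifelse(ids %in% both, 0L, ifelse(ids %in% pos, 1L, -1L))
  nd <- g$nodes[match(ids, g$nodes$node_id), , drop = FALSE]
  gene <- ifelse(nd$base_entity != "", nd$base_entity, nd$label)
  out <- data.frame(gene = gene, node_id = ids, sign = as.integer(sign),
                    stringsAsFactors = FALSE)
  out[order(out$node_id), , drop = FALSE]
}

#' Augment a graph with orthologous causal edges from a donor graph
#'
#' Translates the donor graph's causal edges into the base graph's namespace
#' through an ortholog map and adds them, keeping the donor-species evidence.
#' Edges whose endpoints have no ortholog in the map are skipped and counted.
#' Re-augmenting with the same donor adds nothing (evidence rows are
#' deduplicated), so the operation is idempotent.
#'
#' @param base the graph to augment (e.g. the human knowledge assembly model).
#' @param donor the graph contributing causal assertions (e.g. mouse or rat).
#' @param ortholog_map data frame with columns `donor_id`, `base_id`; may be
#'   many-to-many.
#' @param policy `"expand-all"` translates a donor edge to every mapped
#'   ortholog pair; `"skip-ambiguous"` skips edges whose endpoints map to
#'   more than one base node.
#' @return the augmented `causal_graph`, with attribute `skipped_edges`
#'   giving the number of donor causal edges left untranslated.
#' @export
augment_with_orthologs <- function(base, donor, ortholog_map,
                                   policy = c("expand-all", "skip-ambiguous")) {
  policy <- match.arg(policy)
  stopifnot(inherits(base, "causal_graph"), inherits(donor, "causal_graph"))
  m <- as.data.frame(ortholog_map, stringsAsFactors = FALSE)
  stopifnot(all(c("donor_id", "base_id") %in% names(m)))
  if (!all(m$donor_id %in% donor$nodes$node_id)) {
    stop("ortholog_map donor_id not present in donor graph")
  }
  if (!all(m$base_id %in% base$nodes$node_id)) {
    stop("ortholog_map base_id not present in base graph")
  }
  map_list <- split(m$base_id, m$donor_id)
  if (policy == "skip-ambiguous") {
    map_list <- map_list[vapply(map_list, length, 1L) == 1L]
  }

  new_edges <- empty_causal_edges()
  new_ev <- empty_evidence()
  skipped <- 0L
  de <- donor$causal_edges
  for (i in seq_len(nrow(de))) {
    src <- map_list[[de$source[i]]]
    tgt <- map_list[[de$target[i]]]
    if (is.null(src) || is.null(tgt)) { skipped <- skipped + 1L; next }
    pairs <- expand.grid(source = src, target = tgt,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
    if (nrow(pairs) == 0) { skipped <- skipped + 1L; next }
    pairs$sign <- de$sign[i]
    new_edges <- rbind(new_edges, pairs)
    ev <- donor$evidence[donor$evidence$source == de$source[i] &
                           donor$evidence$target == de$target[i] &
                           donor$evidence$sign == de$sign[i], , drop = FALSE]
    if (nrow(ev) > 0) {
      for (j in seq_len(nrow(pairs))) {
        tev <- ev
        tev$source <- pairs$source[j]
        tev$target <- pairs$target[j]
        new_ev <- rbind(new_ev, tev)
      }
    }
  }

  out <- causal_graph(
    nodes = base$nodes,
    causal_edges = rbind(base$causal_edges, new_edges),
    noncausal_edges = base$noncausal_edges,
    evidence = rbind(base$evidence, new_ev),
    metadata = base$metadata
  )
  attr(out, "skipped_edges") <- skipped
  out
}

#' Induced subgraph on a building-block tag
#'
#' Nodes may carry comma-separated building-block labels (e.g. "CellCycle",
#' "GrowthFactors") in their `block_tag` field. Returns the subgraph induced
#' on the nodes carrying `tag`: edges are retained only when both endpoints
#' are tagged. A tag carried by no node yields an empty graph.
#'
#' @param g a `causal_graph`.
#' @param tag building-block label.
#' @return a `causal_graph`.
#' @export
subgraph_by_tag <- function(g, tag) {
  stopifnot(inherits(g, "causal_graph"), is.character(tag), length(tag) == 1)
  tags <- strsplit(g$nodes$block_tag, ",", fixed = TRUE)
  keep <- vapply(tags, function(tt) tag %in% trimws(tt), logical(1))
  ids <- g$nodes$node_id[keep]
  ce <- g$causal_edges
  ce <- ce[ce$source %in% ids & ce$target %in% ids, , drop = FALSE]
  nce <- g$noncausal_edges
  nce <- nce[nce$source %in% ids & nce$target %in% ids, , drop = FALSE]
  ev <- g$evidence
  ev <- ev[ev$source %in% ids & ev$target %in% ids, , drop = FALSE]
  causal_graph(nodes = g$nodes[keep, , drop = FALSE],
               causal_edges = ce, noncausal_edges = nce, evidence = ev,
               metadata = c(g$metadata, list(block_tag = tag)))
}
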