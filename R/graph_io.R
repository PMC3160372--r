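## Native serialization dialects for causal graphs.
##
## native-tsv: one flat TSV, a `record` column discriminating row kinds —
##   metadata (key/value), node (node table fields), causal (one row per
##   evidence record: source, relation, target, sign, citation_id, species,
##   tissue, quote), noncausal (source, relation, target).
## native-json: the same tables mirrored as JSON arrays.
## supplementary-table: importer for a tabular (TSV/CSV) export of a
##   published nodes-edges-evidence table; relation strings are mapped onto
##   the signed/non-causal vocabulary and unmapped rows are reported, never
##   guessed.

tsv_columns <- function() {
  c("record", "id", "label", "entity_class", "base_entity", "modification",
    "activity_kind", "species_scope", "block_tag",
    "source", "relation", "target", "sign",
    "citation_id", "species", "tissue", "quote", "key", "value")
}

canonicalize_graph <- function(g) {
  o <- order(g$nodes$node_id)
  g$nodes <- g$nodes[o, , drop = FALSE]
  rownames(g$nodes) <- NULL
  o <- order(g$causal_edges$source, g$causal_edges$target, g$causal_edges$sign)
  g$causal_edges <- g$causal_edges[o, , drop = FALSE]
  rownames(g$causal_edges) <- NULL
  o <- order(g$noncausal_edges$source, g$noncausal_edges$target,
             g$noncausal_edges$relation)
  g$noncausal_edges <- g$noncausal_edges[o, , drop = FALSE]
  rownames(g$noncausal_edges) <- NULL
  ev <- g$evidence
  o <- order(ev$source, ev$target, ev$sign, ev$citation_id, ev$quote,
             ev$species, ev$tissue)
  g$evidence <- ev[o, , drop = FALSE]
  rownames(g$evidence) <- NULL
  g
}

#' Write a causal graph to disk
#'
#' The native TSV dialect is a single flat file (one evidence record per
#' causal-edge row); the native JSON dialect mirrors the same tables and
#' preserves text byte-exactly. Saving then loading reproduces the graph on
#' all fields (graphs are kept in canonical sort order, so the round trip is
#' an identity).
#'
#' @param g a `causal_graph`.
#' @param path destination file.
#' @param dialect `"native-tsv"` or `"native-json"`.
#' @return `path`, invisibly.
#' @export
save_graph <- function(g, path, dialect = c("native-tsv", "native-json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(g, "causal_graph"))
  g <- canonicalize_graph(g)

  if (dialect == "native-json") {
    payload <- list(metadata = g$metadata,
                    nodes = g$nodes,
                    causal_edges = g$causal_edges,
                    noncausal_edges = g$noncausal_edges,
                    evidence = g$evidence)
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      TRUE
    }, error = function(e) {
      stop("failed to write ", path, ": ", conditionMessage(e))
    })
    return(invisible(path))
  }

  blank_row <- function() {
    r <- as.list(setNames(rep("", length(tsv_columns())), tsv_columns()))
    as.data.frame(r, stringsAsFactors = FALSE)
  }
  rows <- list()
  md <- g$metadata
  for (k in names(md)) {
    r <- blank_row(); r$record <- "metadata"; r$key <- k
    r$value <- as.character(md[[k]])
    rows[[length(rows) + 1L]] <- r
  }
  for (i in seq_len(nrow(g$nodes))) {
    r <- blank_row(); r$record <- "node"
    nd <- g$nodes[i, ]
    r$id <- nd$node_id; r$label <- nd$label; r$entity_class <- nd$entity_class
    r$base_entity <- nd$base_entity; r$modification <- nd$modification
    r$activity_kind <- nd$activity_kind; r$species_scope <- nd$species_scope
    r$block_tag <- nd$block_tag
    rows[[length(rows) + 1L]] <- r
  }
  ## causal edges: one row per evidence record; edges without evidence get a
  ## bare row
  ekey <- paste(g$causal_edges$source, g$causal_edges$target,
                g$causal_edges$sign, sep = "\r")
  vkey <- paste(g$evidence$source, g$evidence$target, g$evidence$sign,
                sep = "\r")
  for (i in seq_len(nrow(g$causal_edges))) {
    e <- g$causal_edges[i, ]
    ev <- g$evidence[vkey == ekey[i], , drop = FALSE]
    n_ev <- max(1L, nrow(ev))
    for (j in seq_len(n_ev)) {
      r <- blank_row(); r$record <- "causal"
      r$source <- e$source; r$target <- e$target
      r$sign <- as.character(e$sign)
      r$relation <- if (e$sign > 0) "increases" else "decreases"
      if (nrow(ev) >= j) {
        r$citation_id <- ev$citation_id[j]; r$species <- ev$species[j]
        r$tissue <- ev$tissue[j]; r$quote <- ev$quote[j]
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  for (i in seq_len(nrow(g$noncausal_edges))) {
    e <- g$noncausal_edges[i, ]
    r <- blank_row(); r$record <- "noncausal"
    r$source <- e$source; r$relation <- e$relation; r$target <- e$target
    rows[[length(rows) + 1L]] <- r
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character()), length(tsv_columns())),
                           tsv_columns()), stringsAsFactors = FALSE)
  tryCatch(
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8"),
    error = function(e) stop("failed to write ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a causal graph from disk
#'
#' @param path file to read.
#' @param dialect `"native-tsv"`, `"native-json"`, or
#'   `"supplementary-table"` (a tabular export of a published
#'   nodes-edges-evidence table; see Details).
#' @details The supplementary-table importer expects columns (matched
#'   case-insensitively, with common synonyms) `source`, `relation`
#'   (`relationship`), `target`, `citation` (`pmid`, `reference`), `species`,
#'   `tissue`, `quote` (`evidence`). Relation strings `increases` /
#'   `directlyincreases` map to sign +1, `decreases` / `directlydecreases`
#'   to -1, and `hasactivity`, `hasmodification` / `hasmodifiedform`,
#'   `hasmember`, `hascomponent` to the non-causal vocabulary. Rows with any
#'   other relation are rejected and their row numbers reported in the
#'   `rejected_rows` attribute (with a warning). Node records are inferred
#'   from edge endpoints: labels of the form `kaof(X)` / `taof(X)` become
#'   activity nodes of X, labels containing `P@...` become modified-protein
#'   nodes, `exp(X)` becomes the mRNA of X, `complex(...)`, `fam(...)` and
#'   `bp(...)` become complex / protein-family / biological-process nodes,
#'   and bare symbols become protein nodes.
#' @return a validated `causal_graph`; duplicate `(source, target, sign)`
#'   causal rows are merged with their evidence accumulated.
#' @export
load_graph <- function(path, dialect = c("native-tsv", "native-json",
                                         "supplementary-table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)

  if (dialect == "native-json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    md <- as.list(payload$metadata)
    as_df <- function(x, template) {
      if (is.null(x) || length(x) == 0 ||
          (is.data.frame(x) && nrow(x) == 0)) return(template)
      df <- as.data.frame(x, stringsAsFactors = FALSE)
      for (col in names(template)) if (is.null(df[[col]])) df[[col]] <-
          if (is.integer(template[[col]])) NA_integer_ else ""
      df[, names(template), drop = FALSE]
    }
    return(canonicalize_graph(causal_graph(
      nodes = as_df(payload$nodes, empty_nodes()),
      causal_edges = as_df(payload$causal_edges, empty_causal_edges()),
      noncausal_edges = as_df(payload$noncausal_edges, empty_noncausal_edges()),
      evidence = as_df(payload$evidence, empty_evidence()),
      metadata = md
    )))
  }

  if (dialect == "supplementary-table") {
    return(load_supplementary_table(path))
  }

  ## native-tsv
  if (file.size(path) == 0) return(causal_graph())
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", fileEncoding = "UTF-8",
                    check.names = FALSE)
  if (nrow(tab) == 0) return(causal_graph())
  missing_cols <- setdiff(tsv_columns(), names(tab))
  if (length(missing_cols)) {
    stop("malformed native-tsv file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }

  md_rows <- tab[tab$record == "metadata", , drop = FALSE]
  metadata <- as.list(setNames(md_rows$value, md_rows$key))

  nd <- tab[tab$record == "node", , drop = FALSE]
  nodes <- data.frame(node_id = nd$id, label = nd$label,
                      entity_class = nd$entity_class,
                      base_entity = nd$base_entity,
                      modification = nd$modification,
                      activity_kind = nd$activity_kind,
                      species_scope = nd$species_scope,
                      block_tag = nd$block_tag, stringsAsFactors = FALSE)

  ca <- tab[tab$record == "causal", , drop = FALSE]
  sgn <- suppressWarnings(as.integer(ca$sign))
  bad <- which(is.na(sgn) | !(sgn %in% c(-1L, 1L)))
  if (length(bad)) {
    stop("malformed row ", rownames(ca)[bad[1]], " in ", path,
         ": field 'sign' must be +1 or -1, got '", ca$sign[bad[1]], "'")
  }
  causal_edges <- data.frame(source = ca$source, target = ca$target,
                             sign = sgn, stringsAsFactors = FALSE)
  has_ev <- ca$citation_id != "" | ca$quote != "" | ca$species != "" |
    ca$tissue != ""
  evidence <- data.frame(source = ca$source, target = ca$target, sign = sgn,
                         citation_id = ca$citation_id, quote = ca$quote,
                         species = ca$species, tissue = ca$tissue,
                         stringsAsFactors = FALSE)[has_ev, , drop = FALSE]

  nc <- tab[tab$record == "noncausal", , drop = FALSE]
  noncausal_edges <- data.frame(source = nc$source, target = nc$target,
                                relation = nc$relation,
                                stringsAsFactors = FALSE)

  unknown <- setdiff(unique(tab$record),
                     c("metadata", "node", "causal", "noncausal"))
  if (length(unknown)) {
    stop("malformed native-tsv file ", path, ": unknown record kind '",
         unknown[1], "'")
  }

  canonicalize_graph(causal_graph(nodes = nodes, causal_edges = causal_edges,
                                  noncausal_edges = noncausal_edges,
                                  evidence = evidence, metadata = metadata))
}

## Infer a typed node record from a label in the kaof/taof/P@ convention.
infer_node <- function(label) {
  node <- list(node_id = label, label = label, entity_class = "protein",
               base_entity = "", modification = "", activity_kind = "",
               species_scope = "", block_tag = "")
  m <- regmatches(label, regexec("^([kt]aof)\\((.+)\\)$", label))[[1]]
  if (length(m) == 3) {
    node$entity_class <- "activity"
    node$activity_kind <- if (m[2] == "kaof") "kinase" else "transcriptional"
    node$base_entity <- m[3]
    return(node)
  }
  m <- regmatches(label, regexec("^aof\\((.+)\\)$", label))[[1]]
  if (length(m) == 2) {
    node$entity_class <- "activity"
    node$activity_kind <- "generic"
    node$base_entity <- m[2]
    return(node)
  }
  m <- regmatches(label, regexec("^exp\\((.+)\\)$", label))[[1]]
  if (length(m) == 2) {
    node$entity_class <- "mRNA"
    node$base_entity <- m[2]
    return(node)
  }
  m <- regmatches(label, regexec("^complex\\((.+)\\)$", label))[[1]]
  if (length(m) == 2) {
    node$entity_class <- "complex"
    return(node)
  }
  m <- regmatches(label, regexec("^fam\\((.+)\\)$", label))[[1]]
  if (length(m) == 2) {
    node$entity_class <- "protein-family"
    return(node)
  }
  m <- regmatches(label, regexec("^bp\\((.+)\\)$", label))[[1]]
  if (length(m) == 2) {
    node$entity_class <- "biological-process"
    return(node)
  }
  m <- regmatches(label, regexec("^(.+) (P@.+)$", label))[[1]]
  if (length(m) == 3) {
    node$entity_class <- "modified-protein"
    node$base_entity <- m[2]
    node$modification <- m[3]
    return(node)
  }
  node
}

load_supplementary_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", fileEncoding = "UTF-8",
                    check.names = FALSE)
  lc <- tolower(trimws(names(tab)))
  pick <- function(...) {
    i <- which(lc %in% c(...))
    if (length(i)) tab[[i[1]]] else rep("", nrow(tab))
  }
  src <- pick("source", "source node", "subject")
  rel <- pick("relation", "relationship")
  tgt <- pick("target", "target node", "object")
  cit <- pick("citation", "citation_id", "pmid", "reference")
  spc <- pick("species")
  tis <- pick("tissue", "tissue/cell type", "cell type")
  qte <- pick("quote", "evidence", "evidence text", "text")
  if (all(src == "") || all(rel == "") || all(tgt == "")) {
    stop("supplementary table ", path,
         " lacks recognizable source/relation/target columns")
  }

  relkey <- gsub("[^a-z]", "", tolower(rel))
  sign <- rep(NA_integer_, length(relkey))
  sign[relkey %in% c("increases", "directlyincreases")] <- 1L
  sign[relkey %in% c("decreases", "directlydecreases")] <- -1L
  nc_map <- c(hasactivity = "has-activity",
              actsin = "has-activity",
              hasmodification = "has-modified-form",
              hasmodifiedform = "has-modified-form",
              hasmember = "has-member",
              hasmembers = "has-member",
              hascomponent = "has-component",
              hascomponents = "has-component")
  ncrel <- unname(nc_map[relkey])

  is_causal <- !is.na(sign)
  is_noncausal <- !is.na(ncrel) & !is_causal
  rejected <- which(!is_causal & !is_noncausal)
  if (length(rejected)) {
    warning(length(rejected), " row(s) with unmapped relation string(s) ",
            "rejected: ", paste(unique(rel[rejected]), collapse = ", "))
  }

  labels <- unique(c(src[is_causal | is_noncausal],
                     tgt[is_causal | is_noncausal]))
  nodes <- if (length(labels)) {
    do.call(rbind, lapply(labels, function(l)
      as.data.frame(infer_node(l), stringsAsFactors = FALSE)))
  } else empty_nodes()

  causal_edges <- data.frame(source = src[is_causal], target = tgt[is_causal],
                             sign = sign[is_causal], stringsAsFactors = FALSE)
  evidence <- data.frame(source = src[is_causal], target = tgt[is_causal],
                         sign = sign[is_causal],
                         citation_id = cit[is_causal], quote = qte[is_causal],
                         species = ifelse(spc[is_causal] %in%
                                            evidence_species(),
                                          spc[is_causal], "unspecified"),
                         tissue = tis[is_causal], stringsAsFactors = FALSE)
  noncausal_edges <- data.frame(source = src[is_noncausal],
                                target = tgt[is_noncausal],
                                relation = ncrel[is_noncausal],
                                stringsAsFactors = FALSE)
  g <- canonicalize_graph(causal_graph(
    nodes = nodes, causal_edges = causal_edges,
    noncausal_edges = noncausal_edges, evidence = evidence,
    metadata = list(name = basename(path), provenance = "supplementary-table")
  ))
  attr(g, "rejected_rows") <- rejected
  g
}
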