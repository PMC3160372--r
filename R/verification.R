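#' Bundle one dataset's RCR outcome
#'
#' @param dataset_id short label for the experiment.
#' @param observed_direction observed change in the phenotype (e.g. cell
#'   proliferation): +1 increased, -1 decreased.
#' @param hypotheses scored hypothesis table from [generate_hypotheses()].
#' @return a list of class `dataset_outcome`.
#' @export
dataset_outcome <- function(dataset_id, observed_direction, hypotheses) {
  stopifnot(observed_direction %in% c(-1L, 1L),
            is.data.frame(hypotheses))
  structure(list(dataset_id = dataset_id,
                 observed_direction = as.integer(observed_direction),
                 hypotheses = hypotheses),
            class = "dataset_outcome")
}

#' Classify one consistency-matrix cell
#'
#' A predicted node direction is consistent with an experiment when the
#' prediction, pushed through the node's annotated effect on the phenotype,
#' reproduces the observed phenotype direction:
#' `predicted * expected_effect == observed`.
#'
#' @param predicted predicted node direction (+1/-1).
#' @param expected_effect annotated effect of the node on the phenotype
#'   (+1 pro, -1 anti).
#' @param observed observed phenotype direction (+1/-1).
#' @return `"consistent"` or `"inconsistent"` (vectorized).
#' @export
classify_consistency <- function(predicted, expected_effect, observed) {
  stopifnot(all(predicted %in% c(-1L, 1L)),
            all(expected_effect %in% c(-1L, 1L)),
            all(observed %in% c(-1L, 1L)))
  ifelse(predicted * expected_effect == observed, "consistent", "inconsistent")
}

#' Consistency matrix of predicted hypotheses vs expected directions
#'
#' For every annotated node and dataset, takes the best-scoring significant
#' hypothesis for that node (lowest concordance p, then lowest richness p)
#' and classifies its direction against the node's annotated effect on the
#' phenotype and the dataset's observed phenotype direction. Nodes with no
#' significant hypothesis in a dataset are marked `not-predicted`.
#'
#' @param outcomes list of [dataset_outcome()] objects.
#' @param annotations data frame with columns `node_id`,
#'   `expected_effect` (+1 pro-proliferative / -1 anti-proliferative) and
#'   `origin` (`"L"` literature model, `"D"` data-set-derived).
#' @return a list of class `consistency_matrix`: `cells` (long data frame:
#'   node_id, dataset_id, predicted, status), `status` (node x dataset
#'   character matrix), `annotations`, and attribute `unannotated` listing
#'   significant nodes that had no annotation.
#' @export
build_consistency_matrix <- function(outcomes, annotations) {
  stopifnot(length(outcomes) > 0,
            all(vapply(outcomes, inherits, TRUE, "dataset_outcome")),
            all(c("node_id", "expected_effect", "origin") %in% names(annotations)))
  if (anyDuplicated(annotations$node_id)) {
    stop("duplicate annotation for node: ",
         annotations$node_id[duplicated(annotations$node_id)][1])
  }
  if (!all(annotations$origin %in% c("L", "D"))) {
    stop("annotation origin must be 'L' or 'D'")
  }
  if (!all(annotations$expected_effect %in% c(-1L, 1L))) {
    stop("expected_effect must be +1 or -1")
  }

  unannotated <- character(0)
  cells <- list()
  for (oc in outcomes) {
    hyp <- oc$hypotheses
    sig <- hyp[hyp$significant, , drop = FALSE]
    unannotated <- union(unannotated,
                         setdiff(unique(sig$node_id), annotations$node_id))
    for (i in seq_len(nrow(annotations))) {
      nd <- annotations$node_id[i]
      cand <- sig[sig$node_id == nd, , drop = FALSE]
      if (nrow(cand) == 0) {
        cells[[length(cells) + 1L]] <- data.frame(
          node_id = nd, dataset_id = oc$dataset_id,
          predicted = NA_integer_, status = "not-predicted",
          stringsAsFactors = FALSE)
      } else {
        best <- cand[order(cand$concordance_p, cand$richness_p,
                           -cand$direction), , drop = FALSE][1, ]
        cells[[length(cells) + 1L]] <- data.frame(
          node_id = nd, dataset_id = oc$dataset_id,
          predicted = best$direction,
          status = classify_consistency(best$direction,
                                        annotations$expected_effect[i],
                                        oc$observed_direction),
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  datasets <- vapply(outcomes, function(o) o$dataset_id, "")
  status <- matrix("not-predicted", nrow(annotations), length(datasets),
                   dimnames = list(annotations$node_id, datasets))
  status[cbind(cells$node_id, cells$dataset_id)] <- cells$status
  out <- structure(list(cells = cells, status = status,
                        annotations = annotations),
                   class = "consistency_matrix")
  attr(out, "unannotated") <- sort(unannotated)
  out
}

#' Coverage of a network by RCR predictions
#'
#' Counts how much of a curated network the method could, and did, predict.
#' "Possible" nodes meet the minimum criteria to be predicted: in the
#' default `"kb-targets"` mode, at least `min_targets` measured downstream
#' mRNA targets in the knowledgebase substrate in at least one dataset's
#' measured-gene universe; in `"consistent-changes"` mode, at least
#' `min_consistent` direction-consistent observed changes (in either
#' direction) in at least one dataset. "Predicted" nodes are possible nodes
#' with a significant hypothesis (either direction) in at least one dataset.
#'
#' @param network the curated `causal_graph` whose coverage is assessed.
#' @param kb the knowledgebase `causal_graph` used as the RCR substrate
#'   (may be the same object).
#' @param outcomes list of [dataset_outcome()] objects (hypothesis tables
#'   must include non-significant candidates, as [generate_hypotheses()]
#'   returns).
#' @param config an [rcr_config()].
#' @param universes named list, dataset_id -> character vector of measured
#'   genes (required for `"kb-targets"` mode).
#' @param mode `"kb-targets"` (default) or `"consistent-changes"`.
#' @return a list of class `coverage_report` with `n_network_nodes`,
#'   `n_possible`, `n_predicted_union`, `per_dataset` (data frame:
#'   dataset_id, n_predicted, pct_of_possible), `pct_predicted_union`,
#'   `possible_nodes`, `predicted_nodes`.
#' @export
coverage_report <- function(network, kb, outcomes, config = rcr_config(),
                            universes = NULL,
                            mode = c("kb-targets", "consistent-changes")) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "causal_graph"), inherits(kb, "causal_graph"))
  net_nodes <- network$nodes$node_id

  if (mode == "kb-targets") {
    if (is.null(universes)) stop("kb-targets mode needs per-dataset universes")
    possible <- character(0)
    for (u in universes) {
      tmap <- measured_target_map(kb, u, config)
      ok <- names(tmap)[vapply(tmap, nrow, 1L) >= config$min_targets]
      possible <- union(possible, intersect(ok, net_nodes))
    }
  } else {
    possible <- character(0)
    for (oc in outcomes) {
      hyp <- oc$hypotheses
      ok <- unique(hyp$node_id[hyp$n_correct >= config$min_consistent])
      possible <- union(possible, intersect(ok, net_nodes))
    }
  }
  possible <- sort(possible)

  per <- lapply(outcomes, function(oc) {
    sig <- unique(oc$hypotheses$node_id[oc$hypotheses$significant])
    pred <- intersect(sig, possible)
    data.frame(dataset_id = oc$dataset_id, n_predicted = length(pred),
               pct_of_possible = if (length(possible))
                 100 * length(pred) / length(possible) else 0,
               stringsAsFactors = FALSE)
  })
  predicted <- sort(Reduce(union, lapply(outcomes, function(oc)
    intersect(unique(oc$hypotheses$node_id[oc$hypotheses$significant]),
              possible)), character(0)))

  structure(list(
    n_network_nodes = length(net_nodes),
    n_possible = length(possible),
    n_predicted_union = length(predicted),
    pct_predicted_union = if (length(possible))
      100 * length(predicted) / length(possible) else 0,
    per_dataset = do.call(rbind, per),
    possible_nodes = possible,
    predicted_nodes = predicted,
    mode = mode
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", x$n_possible, " possible of ",
      x$n_network_nodes, " network nodes; ", x$n_predicted_union,
      " predicted (", sprintf("%.0f%%", x$pct_predicted_union),
      ") in >=1 dataset\n", sep = "")
  print(x$per_dataset, row.names = FALSE)
  invisible(x)
}

#' Expansion candidates: significant hypotheses outside the network
#'
#' Lists every significant hypothesis whose node is not in the curated
#' network, with the datasets supporting it — input to human curation, never
#' auto-merged into the network.
#'
#' @param outcomes list of [dataset_outcome()] objects.
#' @param network the curated `causal_graph`.
#' @return data frame with columns `node_id`, `direction`, `datasets`
#'   (comma-separated dataset ids), `n_datasets`.
#' @export
expansion_candidates <- function(outcomes, network) {
  stopifnot(inherits(network, "causal_graph"))
  rows <- list()
  for (oc in outcomes) {
    sig <- oc$hypotheses[oc$hypotheses$significant, , drop = FALSE]
    sig <- sig[!sig$node_id %in% network$nodes$node_id, , drop = FALSE]
    if (nrow(sig)) {
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = sig$node_id, direction = sig$direction,
        dataset_id = oc$dataset_id, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(node_id = character(), direction = integer(),
                      datasets = character(), n_datasets = integer(),
                      stringsAsFactors = FALSE))
  }
  long <- do.call(rbind, rows)
  key <- paste(long$node_id, long$direction, sep = "\r")
  agg <- lapply(split(long, key), function(d) data.frame(
    node_id = d$node_id[1], direction = d$direction[1],
    datasets = paste(sort(unique(d$dataset_id)), collapse = ","),
    n_datasets = length(unique(d$dataset_id)), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$node_id, -out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
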