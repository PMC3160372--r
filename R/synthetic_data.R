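#' Configuration for the planted-controller benchmark
#'
#' Describes a synthetic signed controller-to-mRNA causal graph and a
#' matched two-group expression experiment. A subset of controllers is
#' "planted" active with a direction; genes downstream of a planted
#' controller are shifted in log2 intensity by `effect_size_delta` times the
#' expected sign (planted direction times edge sign) on top of Gaussian
#' noise, emulating the kind of transcriptional footprint an upstream
#' regulator leaves on a microarray.
#'
#' Planted controllers receive dedicated, pairwise-disjoint target genes by
#' default (`overlap_allowed = FALSE`); non-planted controllers draw their
#' targets from a shared background pool, so their targets stay unshifted
#' and provide the null.
#'
#' @param n_controllers number of controller (activity) nodes (default 200).
#' @param targets_per_controller downstream mRNA targets per controller; a
#'   single integer or a `c(min, max)` sampling range (default 10).
#' @param sign_positive_prob probability an edge sign is +1 (default 0.5).
#' @param n_background_genes size of the shared background gene pool
#'   (default 2000).
#' @param n_planted number of active controllers (default 20).
#' @param planted_directions vector of +1/-1 of length `n_planted`; default
#'   alternates.
#' @param effect_size_delta log2-units expression shift per planted edge
#'   (default 2.0).
#' @param noise_sd log2-units Gaussian noise standard deviation (default 0.5).
#' @param replicates_per_group samples per group (default 3).
#' @param baseline_log2_mean baseline log2 intensity (default 8).
#' @param overlap_allowed let planted controllers share target genes with
#'   the background pool (and hence each other), exercising the
#'   conflicting-sign pathway (default FALSE).
#' @param seed mandatory integer seed; every stochastic operation derives
#'   its own stream from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_controllers = 200L,
                              targets_per_controller = 10L,
                              sign_positive_prob = 0.5,
                              n_background_genes = 2000L,
                              n_planted = 20L,
                              planted_directions = NULL,
                              effect_size_delta = 2.0,
                              noise_sd = 0.5,
                              replicates_per_group = 3L,
                              baseline_log2_mean = 8,
                              overlap_allowed = FALSE,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_controllers >= 1, all(targets_per_controller >= 1),
            length(targets_per_controller) %in% c(1L, 2L),
            sign_positive_prob >= 0, sign_positive_prob <= 1,
            n_background_genes >= 1, n_planted >= 0,
            n_planted <= n_controllers, effect_size_delta >= 0,
            noise_sd > 0, replicates_per_group >= 2)
  if (is.null(planted_directions)) {
    planted_directions <- rep_len(c(1L, -1L), n_planted)
  }
  stopifnot(length(planted_directions) == n_planted,
            all(planted_directions %in% c(-1L, 1L)))
  if (max(targets_per_controller) > n_background_genes) {
    stop("targets_per_controller exceeds the background gene pool")
  }
  structure(list(n_controllers = as.integer(n_controllers),
                 targets_per_controller = as.integer(targets_per_controller),
                 sign_positive_prob = sign_positive_prob,
                 n_background_genes = as.integer(n_background_genes),
                 n_planted = as.integer(n_planted),
                 planted_directions = as.integer(planted_directions),
                 effect_size_delta = effect_size_delta,
                 noise_sd = noise_sd,
                 replicates_per_group = as.integer(replicates_per_group),
                 baseline_log2_mean = baseline_log2_mean,
                 overlap_allowed = isTRUE(overlap_allowed),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sample_targets_per_controller <- function(config) {
  t <- config$targets_per_controller
  if (length(t) == 1L) rep(t, config$n_controllers)
  else sample(seq(t[1], t[2]), config$n_controllers, replace = TRUE)
}

## Deterministic gene-symbol pool for a configuration: the first
## n_planted x max(targets) symbols are reserved for planted controllers'
## dedicated targets (unless overlap is allowed), the rest are background.
simulated_gene_pool <- function(config) {
  n_dedicated <- if (config$overlap_allowed) 0L else
    config$n_planted * max(config$targets_per_controller)
  n <- n_dedicated + config$n_background_genes
  list(all = sprintf("g%05d", seq_len(n)),
       n_dedicated = n_dedicated)
}

#' Simulate a signed controller-to-mRNA causal graph
#'
#' Controllers are transcriptional-activity nodes; each gets its sampled
#' number of signed causal edges to distinct mRNA nodes (e.g. an increase in
#' a transcription factor's activity increasing the expression of its target
#' genes). Reproducible under the configuration seed. The planted
#' controllers are by convention the first `n_planted` (node ids
#' `ctrl001`...).
#'
#' @param config a [simulation_config()].
#' @return a `causal_graph`.
#' @export
simulate_kam <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pool <- simulated_gene_pool(config)
  n_per <- sample_targets_per_controller(config)

  ctrl_ids <- sprintf("ctrl%03d", seq_len(config$n_controllers))
  edges <- vector("list", config$n_controllers)
  used_dedicated <- 0L
  background <- pool$all[(pool$n_dedicated + 1):length(pool$all)]
  for (i in seq_len(config$n_controllers)) {
    if (!config$overlap_allowed && i <= config$n_planted) {
      genes <- pool$all[used_dedicated + seq_len(n_per[i])]
      used_dedicated <- used_dedicated + n_per[i]
    } else {
      genes <- sample(background, n_per[i])
    }
    signs <- ifelse(stats::runif(n_per[i]) < config$sign_positive_prob, 1L, -1L)
    edges[[i]] <- data.frame(source = ctrl_ids[i],
                             target = paste0("exp(", genes, ")"),
                             sign = signs, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)

  gene_nodes <- sort(unique(sub("^exp\\((.+)\\)$", "\\1", edges$target)))
  nodes <- rbind(
    data.frame(node_id = ctrl_ids, label = ctrl_ids,
               entity_class = "activity", base_entity = toupper(ctrl_ids),
               modification = "", activity_kind = "transcriptional",
               species_scope = "human", block_tag = "",
               stringsAsFactors = FALSE),
    data.frame(node_id = paste0("exp(", gene_nodes, ")"),
               label = paste0("exp(", gene_nodes, ")"),
               entity_class = "mRNA", base_entity = gene_nodes,
               modification = "", activity_kind = "",
               species_scope = "human", block_tag = "",
               stringsAsFactors = FALSE)
  )
  evidence <- data.frame(source = edges$source, target = edges$target,
                         sign = edges$sign, citation_id = "SYNTH",
                         quote = "", species = "unspecified", tissue = "",
                         stringsAsFactors = FALSE)
  causal_graph(nodes = nodes, causal_edges = edges, evidence = evidence,
               metadata = list(name = "synthetic-kam",
                               provenance = "simulate_kam",
                               seed = config$seed))
}

#' Simulate two-group expression data with planted active controllers
#'
#' Control samples are Gaussian per gene in log2 space around the baseline;
#' treated samples add `effect_size_delta` times the expected sign for every
#' gene downstream of a planted controller (the planted direction times the
#' edge sign), zero elsewhere. When overlapping planted controllers imply
#' opposite signs for one gene the shifts sum (and may cancel); such genes
#' are flagged as conflicts in the truth record. The matrix is emitted on
#' the linear scale, one probe per gene.
#'
#' @param graph the `causal_graph` from [simulate_kam()].
#' @param config the same [simulation_config()].
#' @param planted optional data frame (`controller_id`, `direction`)
#'   overriding the default planting (first `n_planted` controllers with
#'   `planted_directions`).
#' @return list with `matrix` (an `expression_matrix`, linear scale) and
#'   `truth` (class `simulation_truth`: `active` data frame,
#'   `downstream_expected` named gene -> expected sign with 0 for cancelled,
#'   `conflicts` character vector of conflicted genes).
#' @export
simulate_expression <- function(graph, config, planted = NULL) {
  stopifnot(inherits(graph, "causal_graph"),
            inherits(config, "simulation_config"))
  if (is.null(planted)) {
    planted <- data.frame(
      controller_id = sprintf("ctrl%03d", seq_len(config$n_planted)),
      direction = config$planted_directions, stringsAsFactors = FALSE)
  }
  missing_ctrl <- setdiff(planted$controller_id, graph$nodes$node_id)
  if (length(missing_ctrl)) {
    stop("planted controller not in graph: ", missing_ctrl[1])
  }

  pool <- simulated_gene_pool(config)
  genes <- pool$all

  ## expected per-gene shift units: sum of direction x edge sign over planted
  shift <- setNames(numeric(length(genes)), genes)
  pos_seen <- neg_seen <- setNames(logical(length(genes)), genes)
  ce <- graph$causal_edges
  for (i in seq_len(nrow(planted))) {
    e <- ce[ce$source == planted$controller_id[i], , drop = FALSE]
    g <- sub("^exp\\((.+)\\)$", "\\1", e$target)
    contrib <- planted$direction[i] * e$sign
    shift[g] <- shift[g] + contrib
    pos_seen[g[contrib > 0]] <- TRUE
    neg_seen[g[contrib < 0]] <- TRUE
  }
  conflicts <- genes[pos_seen & neg_seen]
  downstream_expected <- sign(shift[pos_seen | neg_seen])
  mode(downstream_expected) <- "integer"

  set.seed(config$seed + 1L)
  n_rep <- config$replicates_per_group
  n_genes <- length(genes)
  log2_mat <- matrix(rnorm(n_genes * 2 * n_rep, mean = config$baseline_log2_mean,
                           sd = config$noise_sd),
                     nrow = n_genes,
                     dimnames = list(genes,
                                     c(sprintf("control_%d", seq_len(n_rep)),
                                       sprintf("treated_%d", seq_len(n_rep)))))
  treated_cols <- n_rep + seq_len(n_rep)
  log2_mat[, treated_cols] <- log2_mat[, treated_cols] +
    config$effect_size_delta * shift

  mat <- expression_matrix(
    intensities = 2^log2_mat,
    groups = rep(c("control", "treated"), each = n_rep),
    probe_to_gene = setNames(genes, genes),
    scale = "linear")
  truth <- structure(list(active = planted,
                          downstream_expected = downstream_expected,
                          conflicts = conflicts),
                     class = "simulation_truth")
  list(matrix = mat, truth = truth)
}

#' End-to-end recovery benchmark
#'
#' Runs the whole pipeline — simulate the graph, simulate expression, call
#' State Changes, generate and score hypotheses — and measures how well the
#' planted controllers are recovered, plus the false-positive behaviour of a
#' matched run with zero effect size.
#'
#' @param config a [simulation_config()].
#' @param thresholds State-Change thresholds (default: adjusted p 0.05,
#'   fold change 1.3, no abundance floor — the synthetic intensities carry
#'   no platform-specific abundance artefact).
#' @param rcr RCR configuration (default [rcr_config()]).
#' @param null_run also run the matched zero-delta null (default TRUE).
#' @return list of class `recovery_metrics`: `sensitivity` (fraction of
#'   planted (node, direction) pairs flagged significant), `precision`
#'   (fraction of significant hypotheses that are planted pairs),
#'   `direction_accuracy` (among planted controllers with any significant
#'   call, fraction whose best-scoring direction matches the planted one),
#'   `null_fp_fraction` (significant fraction among candidate hypotheses in
#'   the zero-delta run), plus the intermediate `hypotheses`,
#'   `state_changes` and `truth`.
#' @export
recovery_harness <- function(config, thresholds = de_thresholds(),
                             rcr = rcr_config(), null_run = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  graph <- simulate_kam(config)
  sim <- simulate_expression(graph, config)
  chain <- state_change_chain(sim$matrix, thresholds)
  hyp <- generate_hypotheses(graph, chain$state_changes, rcr)

  planted <- sim$truth$active
  planted_key <- paste(planted$controller_id, planted$direction)
  sig <- hyp[hyp$significant, , drop = FALSE]
  sig_key <- paste(sig$node_id, sig$direction)
  sensitivity <- if (nrow(planted)) mean(planted_key %in% sig_key) else NA_real_
  precision <- if (nrow(sig)) mean(sig_key %in% planted_key) else NA_real_

  recovered <- intersect(planted$controller_id, sig$node_id)
  if (length(recovered)) {
    best_dir <- vapply(recovered, function(nd) {
      cand <- sig[sig$node_id == nd, , drop = FALSE]
      cand$direction[order(cand$concordance_p, cand$richness_p)][1]
    }, integer(1))
    truth_dir <- planted$direction[match(recovered, planted$controller_id)]
    direction_accuracy <- mean(best_dir == truth_dir)
  } else {
    direction_accuracy <- NA_real_
  }

  null_fp <- NA_real_
  if (null_run) {
    null_cfg <- config
    null_cfg$effect_size_delta <- 0
    null_sim <- simulate_expression(graph, null_cfg)
    null_chain <- state_change_chain(null_sim$matrix, thresholds)
    null_hyp <- generate_hypotheses(graph, null_chain$state_changes, rcr)
    null_fp <- if (nrow(null_hyp)) mean(null_hyp$significant) else 0
  }

  structure(list(sensitivity = sensitivity,
                 precision = precision,
                 direction_accuracy = direction_accuracy,
                 null_fp_fraction = null_fp,
                 n_state_changes = length(chain$state_changes$changes),
                 hypotheses = hyp,
                 state_changes = chain$state_changes,
                 truth = sim$truth,
                 graph = graph),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("<recovery_metrics>\n",
      "  sensitivity:        ", sprintf("%.3f", x$sensitivity), "\n",
      "  precision:          ", sprintf("%.3f", x$precision), "\n",
      "  direction accuracy: ", sprintf("%.3f", x$direction_accuracy), "\n",
      "  null FP fraction:   ", sprintf("%.4f", x$null_fp_fraction), "\n",
      "  State Changes:      ", x$n_state_changes, "\n", sep = "")
  invisible(x)
}
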