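#' Configuration for Reverse Causal Reasoning
#'
#' @param alpha_richness richness p-value cutoff for significance
#'   (default 0.1).
#' @param alpha_concordance concordance p-value cutoff (default 0.1).
#' @param min_targets minimum measured downstream mRNA targets a node needs
#'   to be a candidate hypothesis (default 4).
#' @param min_consistent minimum direction-consistent observed State Changes
#'   a hypothesis needs to be significant (default 4).
#' @param concordance_q success probability of a direction match under the
#'   null: `0.5` (each changed gene equally likely up or down) or
#'   `"empirical"` (match probability derived from the observed up-fraction
#'   among all State Changes; when the hypothesis predicts mixed target
#'   signs this uses the mean per-target match probability, a binomial
#'   approximation to the exact Poisson-binomial null).
#' @param universe_mode `"measured"` (default: the richness null draws from
#'   all platform-measured genes) or `"kb-covered"` (only genes downstream
#'   of at least one graph node).
#' @param depth causal path depth for downstream targets (default 1,
#'   direct transcriptional consequences).
#' @return a list of class `rcr_config`.
#' @export
rcr_config <- function(alpha_richness = 0.1, alpha_concordance = 0.1,
                       min_targets = 4L, min_consistent = 4L,
                       concordance_q = 0.5,
                       universe_mode = c("measured", "kb-covered"),
                       depth = 1L) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(alpha_richness > 0, alpha_richness < 1,
            alpha_concordance > 0, alpha_concordance < 1,
            min_targets >= 1, min_consistent >= 1, depth >= 1)
  if (!identical(concordance_q, "empirical")) {
    stopifnot(is.numeric(concordance_q), concordance_q > 0, concordance_q < 1)
  }
  structure(list(alpha_richness = alpha_richness,
                 alpha_concordance = alpha_concordance,
                 min_targets = as.integer(min_targets),
                 min_consistent = as.integer(min_consistent),
                 concordance_q = concordance_q,
                 universe_mode = universe_mode,
                 depth = as.integer(depth)),
            class = "rcr_config")
}

#' Richness p-value of a hypothesis
#'
#' The probability that at least the observed number of State Changes among
#' a node's downstream targets arises by chance: the hypergeometric upper
#' tail P(X >= n_overlap) when n_targets genes are drawn without replacement
#' from a universe of n_universe measured genes of which n_changed_total
#' changed.
#'
#' @param n_universe measured genes in the evaluation universe.
#' @param n_targets measured downstream mRNA targets of the node.
#' @param n_changed_total State Changes in the universe.
#' @param n_overlap targets that are State Changes.
#' @return p-value (vectorized over its arguments).
#' @export
score_richness <- function(n_universe, n_targets, n_changed_total, n_overlap) {
  if (any(n_overlap < 0) ||
      any(n_overlap > pmin(n_targets, n_changed_total)) ||
      any(pmax(n_targets, n_changed_total) > n_universe)) {
    stop("inconsistent counts: need 0 <= n_overlap <= min(n_targets, ",
         "n_changed_total) <= n_universe")
  }
  phyper(n_overlap - 1, n_changed_total, n_universe - n_changed_total,
         n_targets, lower.tail = FALSE)
}

#' Concordance p-value of a hypothesis
#'
#' The probability that at least the observed number of direction-consistent
#' State Changes arises by chance: the binomial upper tail P(X >= n_correct)
#' with n_directional trials (overlap genes reached with an unambiguous path
#' sign) and success probability `q`.
#'
#' @param n_directional directional overlap genes (overlap minus
#'   ambiguous-sign targets).
#' @param n_correct overlap genes whose observed direction matches the
#'   hypothesis direction times the path sign.
#' @param q null match probability, in (0, 1); default 0.5.
#' @return p-value (vectorized).
#' @export
score_concordance <- function(n_directional, n_correct, q = 0.5) {
  if (any(q <= 0) || any(q >= 1)) stop("q must lie strictly in (0, 1)")
  if (any(n_correct < 0) || any(n_correct > n_directional)) {
    stop("need 0 <= n_correct <= n_directional")
  }
  pbinom(n_correct - 1, n_directional, q, lower.tail = FALSE)
}

## Measured downstream-target table for every non-mRNA node, keyed by node.
## Returns list(node_id -> data.frame(gene, sign)) restricted to `universe`.
measured_target_map <- function(graph, universe, config) {
  sources <- unique(graph$causal_edges$source)
  cls <- graph$nodes$entity_class[match(sources, graph$nodes$node_id)]
  sources <- sources[cls != "mRNA"]  # expression nodes are evidence, not controllers
  out <- list()
  for (nd in sources) {
    tg <- downstream_mrna_targets(graph, nd, depth = config$depth)
    tg <- tg[tg$gene %in% universe, , drop = FALSE]
    ## several mRNA nodes may map to one gene; combine their path signs
    if (nrow(tg) > 0 && anyDuplicated(tg$gene)) {
      sgn <- tapply(tg$sign, tg$gene, function(s) {
        u <- unique(s[s != 0L])
        if (length(u) == 1 && !any(s == 0L)) u else 0L
      })
      tg <- data.frame(gene = names(sgn), sign = as.integer(sgn),
                       stringsAsFactors = FALSE)
    }
    out[[nd]] <- tg[order(tg$gene), c("gene", "sign"), drop = FALSE]
  }
  out
}

#' Enumerate candidate upstream-controller hypotheses
#'
#' Every non-mRNA node with at least `min_targets` measured downstream mRNA
#' targets yields two candidates, one per direction (+1 increased activity/
#' abundance, -1 decreased). mRNA nodes are never candidates: their
#' expression is the evidence being explained.
#'
#' @param graph a `causal_graph` (the knowledge-assembly substrate).
#' @param universe character vector of measured gene symbols.
#' @param config an [rcr_config()].
#' @return data frame with columns `node_id`, `direction`.
#' @export
candidate_hypotheses <- function(graph, universe, config = rcr_config()) {
  stopifnot(inherits(graph, "causal_graph"), length(universe) > 0)
  tmap <- measured_target_map(graph, universe, config)
  n_targets <- vapply(tmap, nrow, 1L)
  ids <- sort(names(tmap)[n_targets >= config$min_targets])
  if (length(ids) == 0) {
    return(data.frame(node_id = character(), direction = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(node_id = rep(ids, each = 2L),
             direction = rep(c(1L, -1L), length(ids)),
             stringsAsFactors = FALSE)
}

#' Generate and score upstream-controller hypotheses
#'
#' For every candidate (node, direction) pair, counts the node's measured
#' downstream mRNA targets, their overlap with the State Changes, and the
#' direction-consistent / contradictory / ambiguous split, then computes the
#' hypergeometric richness and binomial concordance p-values. Ambiguous-sign
#' targets count toward the overlap (they witness connectivity) but are
#' excluded from the concordance trials (they carry no direction). A
#' hypothesis is significant when richness_p <= alpha_richness,
#' concordance_p <= alpha_concordance and n_correct >= min_consistent.
#'
#' @param graph a `causal_graph`.
#' @param state_changes a `state_change_set` (from
#'   [call_state_changes()]); its `universe` defines the measured genes.
#' @param config an [rcr_config()].
#' @return data frame sorted by (concordance_p, richness_p, node_id,
#'   direction): one row per hypothesis with all counts, both p-values and
#'   the `significant` flag.
#' @export
generate_hypotheses <- function(graph, state_changes, config = rcr_config()) {
  stopifnot(inherits(graph, "causal_graph"),
            inherits(state_changes, "state_change_set"))
  universe <- state_changes$universe
  changes <- state_changes$changes
  tmap <- measured_target_map(graph, universe, config)

  if (config$universe_mode == "kb-covered") {
    covered <- sort(unique(unlist(lapply(tmap, function(t) t$gene))))
    universe <- covered
    changes <- changes[names(changes) %in% covered]
    tmap <- lapply(tmap, function(t) t[t$gene %in% covered, , drop = FALSE])
  }

  n_targets_all <- vapply(tmap, nrow, 1L)
  cand <- sort(names(tmap)[n_targets_all >= config$min_targets])
  n_universe <- length(universe)
  n_changed_total <- length(changes)

  if (identical(config$concordance_q, "empirical")) {
    frac_up <- if (n_changed_total > 0) mean(changes > 0) else 0.5
    frac_up <- min(max(frac_up, 1e-9), 1 - 1e-9)
  }

  rows <- vector("list", 2L * length(cand))
  k <- 0L
  for (nd in cand) {
    tg <- tmap[[nd]]
    obs <- changes[match(tg$gene, names(changes))]
    hit <- !is.na(obs)
    n_overlap <- sum(hit)
    rich <- score_richness(n_universe, nrow(tg), n_changed_total, n_overlap)
    amb <- hit & tg$sign == 0L
    n_ambiguous <- sum(amb)
    dir_hit <- hit & !amb
    for (dir in c(1L, -1L)) {
      predicted <- dir * tg$sign[dir_hit]
      n_correct <- sum(obs[dir_hit] == predicted)
      n_contra <- sum(dir_hit) - n_correct
      if (identical(config$concordance_q, "empirical")) {
        ## per-target match probability under the empirical up-fraction
        pred_all <- dir * tg$sign[tg$sign != 0L]
        qvec <- ifelse(pred_all > 0, frac_up, 1 - frac_up)
        q <- if (length(qvec)) mean(qvec) else 0.5
      } else {
        q <- config$concordance_q
      }
      conc <- score_concordance(n_correct + n_contra, n_correct, q)
      k <- k + 1L
      rows[[k]] <- data.frame(
        node_id = nd, direction = dir,
        n_universe = n_universe, n_targets = nrow(tg),
        n_changed_total = n_changed_total, n_overlap = n_overlap,
        n_correct = n_correct, n_contra = n_contra,
        n_ambiguous = n_ambiguous,
        richness_p = rich, concordance_p = conc,
        significant = rich <= config$alpha_richness &
          conc <= config$alpha_concordance &
          n_correct >= config$min_consistent,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(data.frame(node_id = character(), direction = integer(),
                      n_universe = integer(), n_targets = integer(),
                      n_changed_total = integer(), n_overlap = integer(),
                      n_correct = integer(), n_contra = integer(),
                      n_ambiguous = integer(), richness_p = numeric(),
                      concordance_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$concordance_p, out$richness_p, out$node_id,
                   -out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
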