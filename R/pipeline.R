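## 32-bit FNV-1a hash of a string; used to fingerprint a run configuration
## in output provenance headers without external dependencies.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte; keep the arithmetic in doubles
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    ## 32-bit multiply by the FNV prime 16777619 in 16-bit halves so no
    ## intermediate exceeds 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  ## render as hex from the two 16-bit halves (h may exceed .Machine$integer.max)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

provenance_header <- function(config_json, seed) {
  c(paste0("# rcrnet ", as.character(utils::packageVersion("rcrnet"))),
    paste0("# config_hash: ", fnv1a32(config_json)),
    paste0("# seed: ", seed),
    paste0("# config: ", config_json))
}

write_tsv_with_provenance <- function(df, path, header_lines) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_lines, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV artifact written with a provenance header
#'
#' @param path file written by [run_pipeline()].
#' @return data frame; the `# `-prefixed provenance lines are attached as
#'   attribute `provenance`.
#' @export
read_artifact <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "# ")]
  df <- read.delim(text = lines[!startsWith(lines, "# ")], sep = "\t",
                   stringsAsFactors = FALSE)
  attr(df, "provenance") <- hdr
  df
}

#' Run the State-Change / RCR / verification pipeline on one dataset
#'
#' Executes the three analysis stages in order — differential expression to
#' State Changes, Reverse Causal Reasoning to scored hypotheses, and (when
#' annotations are supplied) the consistency/coverage verification — writing
#' every artifact as a TSV/JSON file with a provenance header carrying the
#' configuration hash, seed and package version. Re-running with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config named list with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{integer seed recorded in provenance (and used when
#'       `simulation` is given).}
#'     \item{graph}{a `causal_graph`, or a path plus `graph_dialect`.}
#'     \item{matrix}{an `expression_matrix` (omit when `simulation` is
#'       given).}
#'     \item{simulation}{optional [simulation_config()]; when present the
#'       graph and matrix are simulated and the truth written too.}
#'     \item{thresholds}{[de_thresholds()]; default defaults.}
#'     \item{rcr}{[rcr_config()]; default defaults.}
#'     \item{dataset_id}{label for the dataset (default "dataset").}
#'     \item{observed_direction}{observed phenotype direction (+1/-1),
#'       needed for verification.}
#'     \item{annotations}{data frame (`node_id`, `expected_effect`,
#'       `origin`) or path to such a TSV; when absent the verify stage is
#'       skipped with a log notice.}
#'   }
#' @return invisible list of artifact paths plus the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  thresholds <- config$thresholds %||% de_thresholds()
  rcr <- config$rcr %||% rcr_config()
  dataset_id <- config$dataset_id %||% "dataset"
  seed <- config$seed %||% config$simulation$seed %||% 0L

  cfg_for_hash <- list(
    dataset_id = dataset_id, seed = seed,
    thresholds = unclass(thresholds), rcr = unclass(rcr),
    simulation = if (!is.null(config$simulation)) unclass(config$simulation),
    observed_direction = config$observed_direction)
  config_json <- as.character(jsonlite::toJSON(cfg_for_hash,
                                               auto_unbox = TRUE,
                                               digits = NA, null = "null"))
  hdr <- provenance_header(config_json, seed)
  paths <- list()

  ## stage: inputs ----------------------------------------------------------
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      note("simulating graph and expression data")
      graph <- simulate_kam(config$simulation)
      sim <- simulate_expression(graph, config$simulation)
      mat <- sim$matrix
      truth_df <- data.frame(gene = names(sim$truth$downstream_expected),
                             expected_sign = sim$truth$downstream_expected,
                             stringsAsFactors = FALSE)
      paths$truth <- file.path(out_dir, "truth.tsv")
      write_tsv_with_provenance(truth_df, paths$truth, hdr)
      paths$graph <- file.path(out_dir, "graph.tsv")
      save_graph(graph, paths$graph, dialect = "native-tsv")
    } else {
      graph <- config$graph
      if (is.character(graph)) {
        graph <- load_graph(graph,
                            dialect = config$graph_dialect %||% "native-tsv")
      }
      mat <- config$matrix
      stopifnot(inherits(graph, "causal_graph"),
                inherits(mat, "expression_matrix"))
      sim <- NULL
    }
    list(graph = graph, mat = mat, sim = sim)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  graph <- res$graph; mat <- res$mat

  ## stage: diffexp ---------------------------------------------------------
  stage <- "diffexp"
  chain <- tryCatch(state_change_chain(mat, thresholds), error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  sc <- chain$state_changes
  note("state changes: ", length(sc$changes), " of ", length(sc$universe),
       " measured genes")
  paths$probe_results <- file.path(out_dir, "probe_results.tsv")
  write_tsv_with_provenance(
    within(chain$results, {
      log2_fc <- sprintf("%.6g", log2_fc)
      t_statistic <- sprintf("%.6g", t_statistic)
      raw_p <- sprintf("%.6g", raw_p)
      adj_p <- sprintf("%.6g", adj_p)
      mean_intensity_control <- sprintf("%.6g", mean_intensity_control)
      mean_intensity_treated <- sprintf("%.6g", mean_intensity_treated)
    }),
    paths$probe_results, hdr)
  paths$state_changes <- file.path(out_dir, "state_changes.tsv")
  write_tsv_with_provenance(
    data.frame(gene = names(sc$changes), direction = sc$changes,
               stringsAsFactors = FALSE),
    paths$state_changes, hdr)

  ## stage: rcr -------------------------------------------------------------
  stage <- "rcr"
  hyp <- tryCatch(generate_hypotheses(graph, sc, rcr), error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  note("hypotheses: ", nrow(hyp), " scored, ", sum(hyp$significant),
       " significant")
  paths$hypotheses <- file.path(out_dir, "hypotheses.tsv")
  write_tsv_with_provenance(
    within(hyp, {
      richness_p <- sprintf("%.6g", richness_p)
      concordance_p <- sprintf("%.6g", concordance_p)
    }),
    paths$hypotheses, hdr)

  ## stage: verify ----------------------------------------------------------
  stage <- "verify"
  consistency <- NULL; coverage <- NULL
  ann <- config$annotations
  if (is.null(ann)) {
    note("verify stage skipped: no annotations supplied")
  } else {
    if (is.character(ann)) {
      if (!file.exists(ann)) {
        note("verify stage skipped: annotation file not found: ", ann)
        ann <- NULL
      } else {
        ann <- read.delim(ann, sep = "\t", stringsAsFactors = FALSE)
      }
    }
    if (!is.null(ann)) {
      obs <- config$observed_direction %||% 1L
      outcome <- dataset_outcome(dataset_id, obs, hyp)
      consistency <- tryCatch(
        build_consistency_matrix(list(outcome), ann),
        error = function(e) stop("pipeline failed at stage '", stage, "': ",
                                 conditionMessage(e)))
      paths$consistency <- file.path(out_dir, "consistency_matrix.tsv")
      write_tsv_with_provenance(consistency$cells, paths$consistency, hdr)
      coverage <- coverage_report(graph, graph, list(outcome), rcr,
                                  universes = setNames(list(sc$universe),
                                                       dataset_id))
      paths$coverage <- file.path(out_dir, "coverage.json")
      jsonlite::write_json(
        c(list(provenance = list(config_hash = fnv1a32(config_json),
                                 seed = seed)),
          coverage[c("n_network_nodes", "n_possible", "n_predicted_union",
                     "pct_predicted_union")]),
        paths$coverage, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note("coverage: ", coverage$n_predicted_union, " of ",
           coverage$n_possible, " possible nodes predicted")
    }
  }

  paths$log <- file.path(out_dir, "run.log")
  writeLines(c(hdr, log_lines), paths$log)

  invisible(list(paths = paths, state_changes = sc, hypotheses = hyp,
                 consistency = consistency, coverage = coverage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
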