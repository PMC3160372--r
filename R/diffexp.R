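#' Construct a two-group expression matrix
#'
#' Probe-level microarray intensities with sample group labels and a
#' probe-to-gene annotation. Intensities are either linear-scale
#' (non-negative, as extracted from the array) or already log2, indicated by
#' `scale`.
#'
#' @param intensities numeric matrix, probes x samples; rownames are probe
#'   ids, colnames sample ids.
#' @param groups character/factor of length `ncol(intensities)` with levels
#'   `control` and `treated`.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol (possibly many probes to one gene; probes absent from the map
#'   are treated as unannotated).
#' @param scale `"linear"` or `"log2"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(intensities, groups, probe_to_gene,
                              scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (is.null(rownames(intensities))) stop("intensities need probe rownames")
  if (anyDuplicated(rownames(intensities))) stop("probe ids must be unique")
  groups <- as.character(groups)
  if (length(groups) != ncol(intensities)) {
    stop("need one group label per sample")
  }
  bad <- setdiff(unique(groups), c("control", "treated"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (sum(groups == "control") < 2 || sum(groups == "treated") < 2) {
    stop("each contrasted group needs at least 2 samples")
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- paste0("s", seq_len(ncol(intensities)))
  }
  structure(list(intensities = intensities,
                 groups = groups,
                 probe_to_gene = probe_to_gene,
                 scale = scale),
            class = "expression_matrix")
}

#' State-Change calling thresholds
#'
#' The filter chain that turns probe-level test results into signed gene
#' State Changes: Benjamini-Hochberg adjusted p-value at most `adj_p_max`,
#' absolute linear fold change strictly greater than `fold_change_min`
#' (equivalently |log2 fold change| > log2(fold_change_min)), and optionally
#' a linear-scale abundance floor — the group mean intensity must exceed
#' `abundance_min` in the control or the treated group.
#'
#' @param adj_p_max adjusted p-value ceiling (default 0.05).
#' @param fold_change_min absolute linear fold change, exclusive (default 1.3).
#' @param abundance_min linear-intensity floor, or `NULL` (default) for none;
#'   typical per-platform values are 250 (Affymetrix) or 10 (CodeLink).
#' @return a list of class `de_thresholds`.
#' @export
de_thresholds <- function(adj_p_max = 0.05, fold_change_min = 1.3,
                          abundance_min = NULL) {
  stopifnot(adj_p_max > 0, adj_p_max < 1, fold_change_min > 1,
            is.null(abundance_min) || abundance_min >= 0)
  structure(list(adj_p_max = adj_p_max, fold_change_min = fold_change_min,
                 abundance_min = abundance_min),
            class = "de_thresholds")
}

#' Quantile-normalize the columns of an intensity matrix
#'
#' After normalization every column carries the same sorted values: the
#' row-wise mean of the sorted input columns, written back in each column's
#' original rank order. Row (probe) order is preserved. Idempotent.
#'
#' @param x numeric matrix (probes x samples) or an `expression_matrix`.
#' @return object of the same type with normalized intensities.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "expression_matrix")) {
    x$intensities <- quantile_normalize(x$intensities)
    return(x)
  }
  stopifnot(is.matrix(x))
  if (!is.numeric(x) || anyNA(x)) stop("non-numeric or missing cells")
  if (ncol(x) < 2) stop("need at least 2 samples")
  sorted <- apply(x, 2, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = nrow(x))
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) out[order(x[, j]), j] <- ref
  out
}

#' RMA-style summarization of probe-level intensities to probe sets
#'
#' Applies the standard expression-array preprocessing chain: normal +
#' exponential convolution ("normexp") background correction, quantile
#' normalization, log2 transform, and per-probe-set median polish — the
#' probe-set summary for a sample is the fitted overall effect plus that
#' sample's column effect. Single-probe sets pass through unchanged after
#' normalization.
#'
#' @param intensities numeric matrix of linear-scale probe intensities.
#' @param probe_sets named character/factor of length `nrow(intensities)`
#'   assigning each probe to a probe set.
#' @param background apply normexp background correction (default TRUE;
#'   disable for data already background-adjusted).
#' @param normalize apply quantile normalization (default TRUE).
#' @return numeric matrix, probe sets x samples, log2 scale.
#' @export
rma_summarize <- function(intensities, probe_sets, background = TRUE,
                          normalize = TRUE) {
  stopifnot(is.matrix(intensities), length(probe_sets) == nrow(intensities))
  probe_sets <- as.character(probe_sets)
  if (any(is.na(probe_sets) | probe_sets == "")) {
    stop("every probe needs a probe-set assignment")
  }
  bg <- if (background) {
    limma::backgroundCorrect.matrix(intensities, method = "normexp",
                                    verbose = FALSE)
  } else intensities
  qn <- if (normalize) quantile_normalize(bg) else bg
  lg <- log2(qn)
  sets <- sort(unique(probe_sets))
  out <- matrix(NA_real_, length(sets), ncol(intensities),
                dimnames = list(sets, colnames(intensities)))
  for (s in sets) {
    block <- lg[probe_sets == s, , drop = FALSE]
    if (nrow(block) == 1) {
      out[s, ] <- block[1, ]
    } else {
      mp <- medpolish(block, trace.iter = FALSE)
      out[s, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Two-group linear contrast per probe
#'
#' Fits the two-group contrast on log2 intensities: log2 fold change is
#' mean(treated) - mean(control); the t-statistic uses the pooled
#' within-group variance, optionally shrunk toward a common prior by
#' closed-form empirical-Bayes moderation — the posterior variance is
#' (d0 s0^2 + d s^2) / (d0 + d) with the prior (d0, s0^2) estimated by
#' moment matching on the log variances, and the t distribution gains d0
#' degrees of freedom. Two-sided p-values.
#'
#' @param x an `expression_matrix` on the log2 scale, or a log2 numeric
#'   matrix plus `groups`.
#' @param groups group labels if `x` is a bare matrix.
#' @param moderation `"empirical-bayes"` (default) or `"none"` (ordinary
#'   pooled t; probes with zero within-group variance are flagged degenerate
#'   with `NA` p-values).
#' @param linear_intensities optional linear-scale matrix used only to
#'   compute the group mean intensities reported for the abundance gate;
#'   defaults to `2^x`.
#' @return data frame with one row per probe: `probe_id`, `log2_fc`,
#'   `t_statistic`, `raw_p`, `adj_p` (BH), `mean_intensity_control`,
#'   `mean_intensity_treated`, `degenerate`.
#' @export
fit_two_group <- function(x, groups = NULL,
                          moderation = c("empirical-bayes", "none"),
                          linear_intensities = NULL) {
  moderation <- match.arg(moderation)
  if (inherits(x, "expression_matrix")) {
    if (x$scale != "log2") stop("fit_two_group expects log2 intensities")
    groups <- x$groups
    x <- x$intensities
  }
  stopifnot(is.matrix(x), !is.null(groups))
  ic <- which(groups == "control")
  it <- which(groups == "treated")
  if (length(ic) < 2 || length(it) < 2) {
    stop("each contrasted group needs at least 2 samples")
  }
  n1 <- length(ic); n2 <- length(it)
  mc <- rowMeans(x[, ic, drop = FALSE])
  mt <- rowMeans(x[, it, drop = FALSE])
  lfc <- mt - mc
  ss1 <- rowSums((x[, ic, drop = FALSE] - mc)^2)
  ss2 <- rowSums((x[, it, drop = FALSE] - mt)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  se_factor <- sqrt(1 / n1 + 1 / n2)

  degenerate <- rep(FALSE, nrow(x))
  if (moderation == "none") {
    degenerate <- s2 <= 0
    tt <- ifelse(degenerate, ifelse(lfc == 0, 0, Inf * sign(lfc)),
                 lfc / (sqrt(s2) * se_factor))
    df <- rep(d, nrow(x))
    p <- ifelse(degenerate & lfc != 0, NA_real_,
                2 * pt(abs(tt), df, lower.tail = FALSE))
  } else {
    sq <- limma::squeezeVar(s2, df = d)
    s2_post <- sq$var.post
    df <- rep(d + sq$df.prior, nrow(x))
    tt <- lfc / (sqrt(s2_post) * se_factor)
    p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  }

  lin <- if (!is.null(linear_intensities)) linear_intensities else 2^x
  data.frame(
    probe_id = rownames(x),
    log2_fc = unname(lfc),
    t_statistic = unname(tt),
    raw_p = unname(p),
    adj_p = unname(bh_adjust(p)),
    mean_intensity_control = unname(rowMeans(lin[, ic, drop = FALSE])),
    mean_intensity_treated = unname(rowMeans(lin[, it, drop = FALSE])),
    degenerate = unname(degenerate),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of raw p-values in `[0, 1]`; `NA`/`NaN` entries
#'   propagate with a warning giving their count.
#' @return adjusted p-values, monotone in rank and capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  n_bad <- sum(is.na(p))
  if (n_bad > 0) warning(n_bad, " missing p-value(s) propagated")
  ok <- p[!is.na(p)]
  if (length(ok) && (any(ok < 0) || any(ok > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call signed gene State Changes from probe-level results
#'
#' A probe passes when its adjusted p-value is at most `adj_p_max`, its
#' absolute linear fold change exceeds `fold_change_min`, and (when an
#' abundance floor is set) its mean linear intensity exceeds the floor in
#' the control or treated group. A gene changes if at least one of its
#' probes passes; its direction is the sign of the passing probe's log2
#' fold change. Genes whose passing probes disagree in direction are dropped
#' and counted as conflicts. The measured universe is every gene with at
#' least one annotated probe; unannotated probes are excluded and counted.
#'
#' @param results data frame from [fit_two_group()].
#' @param thresholds a [de_thresholds()] object.
#' @param probe_to_gene named character vector, probe id to gene symbol.
#' @return a list of class `state_change_set`: `changes` (named integer
#'   vector, gene -> +1/-1), `universe` (character vector of measured
#'   genes), `thresholds`, `n_conflicts`, `n_unannotated`.
#' @export
call_state_changes <- function(results, thresholds, probe_to_gene) {
  stopifnot(inherits(thresholds, "de_thresholds"),
            all(c("probe_id", "log2_fc", "adj_p") %in% names(results)))
  gene <- unname(probe_to_gene[results$probe_id])
  annotated <- !is.na(gene) & gene != ""
  n_unannotated <- sum(!annotated)
  universe <- sort(unique(gene[annotated]))

  lfc_gate <- abs(results$log2_fc) > log2(thresholds$fold_change_min)
  p_gate <- !is.na(results$adj_p) & results$adj_p <= thresholds$adj_p_max
  if (is.null(thresholds$abundance_min)) {
    ab_gate <- rep(TRUE, nrow(results))
  } else {
    ab_gate <- results$mean_intensity_control > thresholds$abundance_min |
      results$mean_intensity_treated > thresholds$abundance_min
  }
  pass <- annotated & p_gate & lfc_gate & ab_gate & results$log2_fc != 0

  dirs <- tapply(sign(results$log2_fc[pass]), gene[pass],
                 function(s) unique(as.integer(s)))
  n_conflicts <- 0L
  changes <- integer(0)
  if (length(dirs)) {
    conflicted <- vapply(dirs, length, 1L) > 1L
    n_conflicts <- sum(conflicted)
    changes <- vapply(dirs[!conflicted], identity, integer(1))
    changes <- changes[order(names(changes))]
  }
  structure(list(changes = changes, universe = universe,
                 thresholds = thresholds, n_conflicts = n_conflicts,
                 n_unannotated = n_unannotated),
            class = "state_change_set")
}

#' @export
print.state_change_set <- function(x, ...) {
  cat("<state_change_set> ", length(x$changes), " State Changes (",
      sum(x$changes > 0), " up / ", sum(x$changes < 0), " down) in a universe of ",
      length(x$universe), " genes\n", sep = "")
  if (x$n_conflicts > 0) cat("  direction conflicts dropped:", x$n_conflicts, "\n")
  invisible(x)
}

#' Run the full State-Change chain on an expression matrix
#'
#' Convenience wrapper: quantile normalization (on the linear scale), log2
#' transform, two-group moderated contrast, BH adjustment, and State-Change
#' calling. Matrices already on the log2 scale skip the transform.
#'
#' @param mat an `expression_matrix`.
#' @param thresholds a [de_thresholds()] object.
#' @param moderation passed to [fit_two_group()].
#' @param normalize quantile-normalize first (default TRUE).
#' @return list with `results` (probe table) and `state_changes`.
#' @export
state_change_chain <- function(mat, thresholds = de_thresholds(),
                               moderation = "empirical-bayes",
                               normalize = TRUE) {
  stopifnot(inherits(mat, "expression_matrix"))
  if (normalize) mat <- quantile_normalize(mat)
  if (mat$scale == "linear") {
    lin <- mat$intensities
    lg <- log2(pmax(lin, 2^-10))
  } else {
    lg <- mat$intensities
    lin <- 2^lg
  }
  res <- fit_two_group(lg, mat$groups, moderation = moderation,
                       linear_intensities = lin)
  sc <- call_state_changes(res, thresholds, mat$probe_to_gene)
  list(results = res, state_changes = sc)
}
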