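---
title: "Reverse Causal Reasoning on signed causal networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse Causal Reasoning on signed causal networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcrnet)
```

# The model

## Knowledge representation

A `causal_graph` is a typed, signed multigraph in the style of curated
causal knowledge assemblies. Nodes carry an entity class from a closed
vocabulary — `mRNA`, `protein`, `modified-protein`, `activity`, `complex`,
`protein-family`, `biological-process`, `proxy`, `other` — plus optional
attributes (the base entity behind an mRNA or activity node, the activity
kind for `kaof`/`taof`-style nodes, the modification for modified proteins,
and comma-separated block tags for subgraph extraction). Causal edges carry
a sign (+1 increases, −1 decreases) and one or more evidence records
(citation, quoted sentence, species). Non-causal edges (`has-activity`,
`has-modified-form`, `has-member`, `has-component`) connect an entity to its
functional forms but never propagate signs.

Duplicate causal statements — the same (source, target, sign) asserted by
several papers — are merged into one edge with pooled, de-duplicated
evidence. The constructor canonicalizes ordering, so two structurally equal
graphs are `identical()` and a save/load round trip is exact.

## Downstream target sets

`downstream_mrna_targets()` walks causal edges away from a node, multiplying
edge signs along each path, and reports every reachable mRNA with its net
predicted direction. When two paths to the same gene disagree, the gene is
kept but flagged ambiguous (sign 0): it still counts as *measured evidence
about the hypothesis* for richness, but it cannot contribute a directional
trial to concordance. The default search depth is 1 — direct transcriptional
consequences — because signed inference over longer paths multiplies
curation errors; depth is a `rcr_config()` parameter for users who want
transitive closure.

## The State-Change filter chain

`state_change_chain()` reproduces the standard microarray decision rule for
calling differential expression in a two-group design:

1. **Quantile normalization** of linear intensities (each column is mapped
   onto the mean of the sorted columns). This removes array-wide intensity
   shifts under the assumption that the *overall* intensity distribution is
   the same in both groups.
2. **log2** transform (with a small floor so non-positive background-corrected
   values do not produce −Inf).
3. **Pooled two-sample t** per gene, with closed-form empirical-Bayes
   variance moderation: the per-gene variance is shrunk toward a common
   prior, `(d0·s0² + d·s²) / (d0 + d)`, which is essential at 3 vs 3
   replicates where raw variances are unstable. The hyperparameters are
   estimated by `limma::squeezeVar()`; the resulting statistics match
   `limma::eBayes()` exactly (the test suite asserts this).
4. **Benjamini–Hochberg** adjustment across all measured genes.
5. **Gates**: adjusted p ≤ 0.05, |fold change| > 1.3 on the linear scale
   (i.e. |log2 FC| > log2 1.3), and an optional abundance floor that the
   *mean* intensity must clear in at least one group. The floor models the
   platform-specific detection limit: a fold change computed between two
   near-background intensities is noise, not biology.
6. **Probe → gene collapse**: a gene is a State Change if at least one
   annotated probe passes; genes whose passing probes disagree in direction
   are dropped and reported in `n_conflicts` rather than silently resolved,
   because a sign conflict usually indicates cross-hybridization or
   transcript-isoform effects that the downstream causal logic cannot use.

Where raw probe-level data exist, `rma_summarize()` provides the preceding
RMA-style summarization: normexp background correction
(`limma::backgroundCorrect.matrix`), quantile normalization, log2, and
Tukey median polish per probe set, with the gene summary taken as overall
plus column effects.

## RCR scoring

Every non-mRNA node with at least `min_targets` (default 4) *measured*
downstream transcripts generates two hypotheses, one per direction. For each
hypothesis:

- **Richness** is the hypergeometric upper tail
  `phyper(k − 1, n, N − n, t, lower.tail = FALSE)` with `N` measured genes,
  `n` State Changes, `t` targets, `k` overlap. It asks whether the node's
  targets are enriched among the changes at all, irrespective of direction;
  ambiguous-sign targets count here.
- **Concordance** is the binomial upper tail
  `pbinom(c − 1, m, q, lower.tail = FALSE)` over the `m` overlapping targets
  with an unambiguous predicted sign, `c` of which moved as predicted. The
  default success probability is q = 0.5 — under the null, an observed
  change is equally likely to agree or disagree with the prediction.
- A hypothesis is **significant** when richness ≤ 0.1, concordance ≤ 0.1,
  *and* `n_correct ≥ min_consistent` (default 4). The minimum-4 rule is
  applied twice deliberately: once at candidacy (a node with 3 measured
  targets can never produce convincing evidence) and once at the consistency
  count (a perfect 3-of-3 concordance reaches p = 0.125 but rests on too few
  observations to act on).

Hypotheses are returned sorted by concordance p, then richness p, then node
id, then direction — a total order, so output is deterministic.

### The empirical-q option

With `concordance_q = "empirical"`, q is set to the mean per-target
probability that a random measured gene both changed and matched the
predicted direction. The exact null here is Poisson-binomial (each target
has its own match probability); we approximate it with a single binomial at
the mean probability. The approximation errs slightly conservative for the
tail events we care about and keeps the statistic in closed form; the
default q = 0.5 conditions on the overlap and does not need it.

## Verification

`build_consistency_matrix()` crosses significant hypotheses with annotated
expected effects. The annotation gives each node an expected effect on the
process (+1 promotes, −1 inhibits) and an origin (`"L"` literature, `"D"`
derived from the datasets). A prediction is consistent when
`predicted × expected == observed` — e.g. predicting *decreased* activity of
a process *promoter* in a proliferation-*inhibiting* experiment is
consistent. When several significant hypotheses exist for one node in one
dataset, the one with the best (lowest) concordance, then richness, p-value
fills the cell; remaining cells are `not-predicted`.

`coverage_report()` answers "how much of the network could this method ever
see": *possible* nodes are those with enough measured targets to be
candidates, and predicted percentages are recomputed from the counts rather
than stored. Two modes differ in the denominator: `kb-targets` counts nodes
whose knowledge-base targets are measured at all, the more honest statement
of reach; `consistent-changes` restricts to nodes with ≥ `min_consistent`
observed changed targets, the tighter bound on what could have been called
in these particular datasets. We default to `kb-targets` because coverage is
meant to characterize the *network against the platform*, not against one
experiment's outcome.

# The synthetic benchmark

`simulate_kam()` + `simulate_expression()` exist so the pipeline can be
validated against a known truth. Design choices:

- **Defaults are the study conditions.** 200 controllers × 10 targets,
  20 planted active controllers in alternating directions, δ = 2.0
  log2-units, σ = 0.5, 3 vs 3 replicates, baseline log2 intensity 8. These
  are typical of a moderately powered perturbation microarray experiment:
  δ/σ = 4 per gene, but only 3 replicates per group, so single-gene calls
  are imperfect and the aggregation performed by RCR is actually exercised.
- **Disjoint planted targets, shared background pool.** Planted controllers
  regulate dedicated genes; non-planted controllers draw targets from a
  common background pool (default 2000 genes). This cleanly separates signal
  from null structure: the planted signal cannot leak into non-planted
  hypotheses through shared targets, so the null false-positive rate
  measures the statistics, not the topology. Setting
  `overlap_allowed = TRUE` relaxes this and produces sign conflicts, which
  the truth object tracks.
- **Emission on the linear scale.** Expression is generated as Gaussian on
  the log2 scale and emitted as `2^x` linear intensities, so the benchmark
  passes through the same normalization and log transform as real data.
- **Determinism.** The graph is drawn under `seed` and the expression under
  `seed + 1`; the same configuration always reproduces the same benchmark,
  and `run_pipeline()` reruns are byte-identical (artifacts carry a content
  hash and a config hash, never timestamps).

What the generator deliberately does **not** emulate: probe-level structure
(the probe→gene map is the identity), non-causal edge scaffolding,
intensity-dependent variance, batch effects, or correlated noise between
genes. It is a benchmark for the *inference chain*, not a microarray
simulator.

One numerical caveat worth recording: quantile normalization assumes most
genes are unchanged. If a large fraction of the measured genes is shifted by
a huge effect (an easy mistake when shrinking the benchmark for quick
tests), normalization redistributes the baseline genes into inflated tails
and produces spurious calls. Keep the planted fraction realistic (the
defaults shift 200 of 2200 genes) or disable normalization when testing the
arithmetic in isolation.

# Recovery metrics

`recovery_harness()` runs the full chain and reports:

- **sensitivity** — fraction of planted (controller, direction) pairs
  recovered as significant hypotheses;
- **direction accuracy** — among recovered planted controllers, the fraction
  whose best significant hypothesis has the planted direction;
- **precision** — fraction of significant hypotheses that are planted;
- **null false-positive fraction** — the significant fraction in a matched
  rerun with δ = 0, where every gene is exchangeable noise.

At the default conditions the harness recovers all 20 planted controllers
with 100% direction accuracy and a null fraction of 0.

# Limitations

- Depth-1 target sets ignore indirect regulation; deeper walks are supported
  but compound curation noise and make sign ambiguity common.
- Concordance treats targets as independent Bernoulli trials; co-regulated
  target sets violate this and make the p-value anti-conservative.
- The binomial approximation to the empirical-q null is inexact for very
  heterogeneous per-target probabilities.
- The moderated t assumes equal group variances; strongly heteroscedastic
  perturbations would need Welch-style handling the chain does not provide.
- The benchmark's clean topology gives an optimistic picture of real curated
  networks, where hub controllers share many targets.
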