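---
title: "Scoring protein-protein interaction essentiality by dual-graph propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-protein interaction essentiality by dual-graph propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiess)
```

## The problem

Pooled knockdown screens (shRNA, siRNA, CRISPR) measure how essential each
*gene* is for the survival of a cancer cell line. But silencing a gene
removes *all* of its protein-protein interactions (PPIs) at once, so the
contribution of any single interaction is hidden inside the gene-level
signal. There is no experimental technology that disrupts one endogenous
PPI at a time at genome scale. `ppiess` infers a per-interaction
essentiality score by combining the gene-level measurements with the
topology of a curated pathway network, so that individual interactions —
the actual target class of a growing family of PPI-inhibitor compounds —
can be ranked and screened.

## The model

### From proteins to interactions: the dual graph

The input network has proteins as nodes and PPIs as edges. We transform it
into its *dual* (line) graph: every PPI becomes a node, and two dual nodes
are adjacent exactly when their PPIs share a protein. Each dual edge
therefore corresponds to a protein, and it is weighted by an exponential
kernel of that protein's essentiality,

$$\mathrm{weight}(i \sim j) = e^{\,w\, p_s},$$

where $p_s \in [0,1]$ is the normalized essentiality of the shared protein
$s$ and $w \ge 0$ controls how strongly protein essentiality is allowed to
shape interaction essentiality. At $w = 0$ the score is purely structural
(network centrality of the interaction); larger $w$ makes interactions
between essential proteins dominate.

The working assumption is *locality of essentiality*: if an interaction is
vital, the interactions adjacent to it (through an essential protein) tend
to be vital too, so essentiality should diffuse along the dual graph.

### Propagation to a stationary score

Scores are computed by a smoothed iterative update. With $P$ the
row-stochastic matrix of dual-edge weights and smoothing parameter
$\alpha \in (0, 1]$, the default (`mass`) update is

$$e(t+1) = (1-\alpha)\, e(t) + \alpha\, P^{\top} e(t),$$

i.e. score mass flows along the weighted random walk, in the manner of
PageRank. On a connected dual graph the fixed point is the stationary
distribution of $P$ — for the reversible walk on an undirected weighted
graph this is proportional to node *strength* (the sum of incident dual
weights) — so the limit is independent of both the initialization and of
$\alpha$, which only controls the approach speed and damping. The fixed
point can equally be obtained per connected component as the leading left
eigenvector of $M = (1-\alpha) I + \alpha P$; `closed_form_scores()`
implements that eigendecomposition route and is required to agree with
`propagate()` elementwise within $10^{-8}$.

A second update mode, `averaging`,

$$e(t+1) = (1-\alpha)\, e(t) + \alpha\, P e(t),$$

replaces every node's score with the weighted average of its neighbors.
This transcription is kept for comparison, but it provably converges to a
*consensus* (all scores equal) on any connected graph, with a limit that
depends on the initialization — it cannot produce a non-trivial ranking,
which is why `mass` is the default and the scientific mode. The property
tests document the consensus behavior explicitly.

After convergence the scores are divided by their maximum, so every cell
line's scores lie in $(0, 1]$ with its most essential PPI at exactly 1.
Divide-by-max was chosen over min-max because min-max would force an
artifactual exact zero onto the least essential PPI.

### From screen files to protein essentialities

* **Hairpin collapse.** Gene-level lethality is the *second most lethal*
  hairpin score (`collapse_shrna_to_gene()`), which suppresses
  single-hairpin off-target artifacts; genes with fewer than two hairpins
  are excluded.
* **Normalization.** Screen scores (more negative = more lethal) are
  mapped per cell line to $p \in [0,1]$ by a negated min-max transform,
  so the most lethal gene gets $p = 1$. The source data carry no canonical
  scale for $p$; this bounded choice makes the kernel span $[1, e^w]$. A
  degenerate all-equal profile maps to $p = 0.5$ everywhere (with a
  warning) so the kernel stays defined.
* **Context rewiring.** For each cell line, nodes that are deleted,
  deleteriously mutated, not expressed, or unmeasured are excised with
  their incident edges (`apply_context()`) before the dual transform;
  their PPIs are reported as missing (`NaN` on disk) for that line. The
  expression-absence cutoff is an input decision: `not_expressed_genes()`
  applies a user-set threshold (default: non-positive log expression).
  Homodimer edges (A–A) are dropped at ingest — the dual transform is not
  defined for self-loops.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.5 | smoothing: fraction of each update taken from neighbors; $(0,1]$ |
| `w` | 0.5 | kernel coefficient on protein essentiality (dimensionless) |
| `tol` | 1e-10 | convergence bound on the remaining change of the scores |
| `max_iter` | 10000 | iteration cap; non-convergence is flagged, not hidden |
| `max_missing_fraction` | 0.2 | cell lines with more missing PPIs are dropped |
| `min_mean` | 0.5 | mean essentiality defining the "most essential" PPI set |
| `n_perm` | 1000 | target-set permutations for the drug-screen FDR |
| `ks_threshold` | 0.5 | KS rank statistic required to call a PPI group-essential |

The defaults for `alpha` and `w` are the published operating point; the
converged *ranking* is mathematically independent of `alpha` (the fixed
point does not involve it), which the test suite verifies across
$\alpha \in \{0.1, 0.5, 0.9\}$. `alpha = 0` is rejected: it freezes the
initialization and defines no stationary score.

## Downstream statistics

* **MPER** (`compute_mper()`): a PPI's rank percentile among all PPIs of
  the cell line divided by the best rank percentile of its two partner
  proteins among all proteins. MPER is computed on the *percentile* scale
  by default — ranks avoid systematic magnitude biases between the PPI
  and protein scales — with the raw-ratio variant available via
  `scale = "raw"`. Values above 1 flag interactions more critical than
  either partner's knockdown suggests; percentiles are `rank/n` with
  average ties, so the denominator is never zero.
* **KS rank enrichment** (`ks_rank_statistic()`): a one-sample signed
  sup-deviation of a PPI's rank percentiles (across a cell-line group,
  e.g. lung adenocarcinoma lines) from the uniform distribution; near +1
  means consistently top-ranked. A one-sample form was chosen because the
  comparison target (uniform ranks) is exact and parameter-free; a
  two-sample variant against the complement group would be a natural
  extension.
* **Drug-target enrichment** (`target_enrichment()`): essentiality values
  of PPIs touching a compound's target genes versus all other PPIs, by
  one-sided Wilcoxon rank-sum. The permutation FDR redraws target sets of
  the same size from the network's gene universe; because redrawn sets
  induce different group sizes, the exceedance statistic is the
  *standardized* rank-sum $z$, which is comparable across relabelings
  (the raw $W$ is not). Zero exceedances are floored at `1/n_perm`.
* **Differential essentiality** (`differential_essentiality()`): Welch
  (unequal-variance) two-sample $t$ per PPI between mutant and wild-type
  cell lines, Benjamini–Hochberg adjusted across PPIs.
* **Survival screen** (`patient_ppi_logrank()`, `survival_screen()`): a
  patient lacks a PPI iff a partner gene carries a nonsense mutation,
  frameshift mutation, or homozygous deletion; missense and silent
  variants leave it intact. The two-group log-rank test is implemented
  from the risk-table definition (hypergeometric variance, simultaneous
  risk sets for ties), p-values are Benjamini–Yekutieli adjusted — the
  harmonic-factor step-up valid under the arbitrary dependence created by
  overlapping PPIs — and the final screen keeps PPIs passing both the
  nominal log-rank threshold and the KS threshold in the matched
  cell-line group. Cox modeling is deliberately out of scope; the screen's
  statistic is the log-rank test. Expression-based absence is available as
  an optional third criterion in context tables but is off by default for
  patients.

## Numerical choices

* **Initialization** is the uniform vector (total mass 1). On connected
  dual graphs the limit is initialization-independent; the suite checks
  two random starts agree within $10^{-6}$.
* **Stopping rule.** A small iterate change does not by itself certify a
  small distance to the fixed point when the spectral gap is small, so
  iteration stops only when the max-norm step is below `tol` *and* the
  geometric-decay tail bound $\delta_t^2 / (\delta_{t-1} - \delta_t)$ is
  below `tol` (or the step has reached its numerical floor). This keeps
  the closed-form agreement inside $10^{-8}$.
* **Disconnected dual graphs.** The limit from a uniform start gives each
  component its share of the initial mass; `closed_form_scores()`
  reproduces exactly that (per-component stationary distribution scaled
  by component size over total), so the two routes agree on every input.
  Isolated dual nodes (a lone edge in its component) keep their initial
  mass. No teleportation term is added; positive weights on an undirected
  connected component already guarantee a unique stationary distribution.
* **Ties in rankings.** Score ties are real (graph automorphisms produce
  mathematically equal scores), so rank comparisons are made after
  rounding converged scores to 8 decimals; PPI lists break mean-score
  ties lexicographically on the identifier.

## The synthetic study

`simulate_dataset()` generates every input the pipeline consumes, from a
single mandatory seed that fans out into per-stage streams (network,
screen, contexts, drugs, survival), so each stage is independently
reproducible and identical configurations give byte-identical files.

What it emulates, and the defaults chosen for the study conditions:

* a superpathway built from 8 overlapping preferential-attachment
  pathways of 15–40 proteins over a 150-protein pool, with 10% designated
  hubs seeding every pathway (hub-heavy overlap, as in merged curated
  pathway collections) plus a few screen-derived "novel" edges;
* a hairpin-level screen (4 hairpins/gene, replicate noise sd 0.3 on the
  depletion scale, small per-line wobble) over 30 cell lines in which hub
  genes are shifted 2 units more lethal — a few strongly essential
  proteins against a null background;
* per-line gene losses at rate 0.03 with mutation/deletion/expression
  event types;
* one compound whose AUC tracks the planted target's mean PPI
  essentiality at an intended Pearson $r = 0.7$, among otherwise null
  compounds;
* 200 patients with exponential survival, hazard tripled for patients
  retaining the planted PPI (absence rate 0.4 via nonsense/frameshift/
  homozygous-deletion events), administratively censored at 3000 days
  (roughly 30% censoring at the default hazard).

What it does **not** emulate: the marginal distributions, sample sizes and
batch structure of real screen/drug/patient compendia, off-target hairpin
structure beyond i.i.d. noise, co-occurrence patterns of mutations, or
linkage between the drug and survival layers. Passing the planted-effect
and calibration tests therefore shows that the method recovers effects of
the assumed form at desk scale — not that it reproduces any particular
published cohort.

## Problem sizes used by the checks

The oracle-equivalence checks run on 50 random connected networks of up
to 100 PPIs; initialization-independence and smoothing-invariance on 20
networks each; the planted-effect study on the default configuration
above (about 350 PPIs x 30 cell lines, 1000 permutations, 200 patients);
and the null calibrations on 500 replicates per screen (log-rank at
n = 40, Welch t at 20 vs 20, rank-sum at 20 vs 25 values). These sizes
were chosen so the entire analysis reruns from scratch in well under a
minute on a laptop while leaving the binomial envelopes tight enough to
detect miscalibration.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
data <- simulate_dataset(cfg, "study")
m <- data$matrix                      # PPIs x cell lines, NA = absent

flt <- filter_uniform_ppis(filter_cell_lines(m, 0.2))
head(top_ppis(flt, min_mean = 0.5))

enr <- target_enrichment(m, data$planted$drug_target,
                         n_perm = 1000, seed = 2)
enr$perm_fdr

lr <- patient_ppi_logrank(data$patients$mutations,
                          data$patients$clinical,
                          data$planted$survival_ppi)
lr$p
```

## Known limitations

* The method ranks *known* interactions; it neither predicts new PPIs nor
  corrects the input network.
* Scores are relative within a cell line (max-normalized), so absolute
  values are not comparable across datasets with different networks.
* The context model is binary (a PPI is present or absent); partner
  abundance, pathway activation state and dosage effects are not modeled.
* Directed, signed, or multi-edge interaction semantics are out of scope,
  as are hierarchical clustering and heatmap rendering — the package
  exports matrices for external visualization tools.
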