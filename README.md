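# ppiess

Infer the essentiality of individual **protein–protein interactions
(PPIs)** from gene-level knockdown screens and pathway network topology.

Pooled shRNA/CRISPR screens tell you how essential each *gene* is to a
cancer cell line, but silencing a gene removes all of its interactions at
once — the contribution of any single PPI is invisible. `ppiess` is for
computational biologists who want to rank interactions (the target class
of PPI-inhibitor drugs) rather than proteins: it deconvolves gene-level
essentiality into per-interaction scores and provides the downstream
screens that connect those scores to drug sensitivity, mutation status and
patient survival.

## Method

1. **Superpathway.** Curated pathway edge lists (SIF) are merged into one
   undirected network over HUGO symbols, with per-edge provenance
   (`merge_pathways()`).
2. **Gene essentiality.** Hairpin-level screen scores (GCT 1.2, more
   negative = more lethal) are collapsed to gene level by the
   second-most-lethal rule and normalized per cell line to
   `p ∈ [0, 1]` (`collapse_shrna_to_gene()`,
   `normalize_protein_essentiality()`).
3. **Context rewiring.** Per cell line, genes that are deleted, mutated,
   not expressed, or unmeasured are excised with their edges
   (`apply_context()`).
4. **Dual graph + propagation.** The network is inverted: PPIs become
   nodes, shared proteins become edges weighted `exp(w · p_s)`. A
   smoothed mass-propagation

   `e(t+1) = (1 − α) e(t) + α Pᵀ e(t)`

   (P row-stochastic; defaults α = 0.5, w = 0.5) is iterated to its
   stationary distribution and divided by its maximum, giving PPI
   essentiality scores in (0, 1] with the top interaction at exactly 1
   (`build_dual_graph()`, `propagate()`; eigendecomposition closed form
   in `closed_form_scores()`; whole-matrix pipeline in `score_matrix()`).
5. **Screens.** PPI/max-partner percentile ratios (`compute_mper()`), KS
   rank enrichment (`ks_rank_statistic()`), drug-target enrichment with
   permutation FDR (`target_enrichment()`), mutant-vs-wild-type Welch t
   with BH correction (`differential_essentiality()`), and patient
   survival splitting by PPI presence with a risk-table log-rank test and
   Benjamini–Yekutieli correction (`patient_ppi_logrank()`,
   `survival_screen()`).

A seed-reproducible generator (`simulate_dataset()`) emits synthetic
inputs in exactly the formats the readers consume — a hub-structured
multi-pathway network, a hairpin screen with planted essential hubs,
alteration contexts, drug AUCs with a planted target correlation, and
patient survival with a planted hazard effect.

## Worked example

```r
library(ppiess)

cfg  <- simulation_config(seed = 1)          # planted synthetic study
data <- simulate_dataset(cfg, "study")       # writes SIF/GCT/TSV inputs
m    <- data$matrix                          # 371 PPIs x 30 cell lines

flt <- filter_uniform_ppis(filter_cell_lines(m, 0.2))
head(top_ppis(flt, min_mean = 0.5), 5)
#>         ppi mean_essentiality n_cell_lines
#> 1 G003_G015         0.9916751           28
#> 2 G011_G015         0.9834816           28
#> 3 G005_G015         0.9787941           29
#> 4 G003_G011         0.9344955           28
#> 5 G003_G005         0.9299907           29

enr <- target_enrichment(m, data$planted$drug_target,
                         n_perm = 1000, seed = 2)
enr$perm_fdr
#> [1] 0.007

lr <- patient_ppi_logrank(data$patients$mutations,
                          data$patients$clinical,
                          data$planted$survival_ppi)
lr
#>         ppi    chisq            p n_present n_absent
#> 1 G003_G015 58.88421 1.672286e-14       120       80
```

The top of the ranking is filled by interactions of the planted essential
hub genes (here G003/G005/G011/G015); the planted compound's target is
flagged at permutation FDR 0.007; and patients retaining the planted PPI
(tripled hazard) separate at log-rank p ≈ 2e-14.

A command-line wrapper covers the same workflow
(`inst/cli/ppiess simulate|score|mper|drug-assoc|diff-ess|survival`), or
call `ppi_cli(c("score", "--network", "net.sif", ...))` directly.

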