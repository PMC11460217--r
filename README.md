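# symptomnet

Network analysis of patient-reported symptom severities, and second-order
clustering of patients by their symptom *co-severity* structure.

Oncology cohorts (and comparable patient populations) report dozens of
concurrent symptoms on ordinal severity scales (0 = not reported … 4 =
very severe). Two questions drive the analysis this package implements,
aimed at biostatisticians and symptom-science researchers:

1. **Which symptoms hang together, and which drive the burden?** A
   regularized Gaussian graphical model (GGM) estimates the conditional
   dependence network: edge weights are partial correlations
   ρ<sub>ij</sub> = −K<sub>ij</sub>/√(K<sub>ii</sub>K<sub>jj</sub>) of a
   sparse precision matrix K fitted by the graphical lasso
   (max<sub>K</sub> log det K − tr(SK) − λΣ<sub>i≠j</sub>|K<sub>ij</sub>|)
   on nonparanormal-transformed severities, with λ chosen by the Extended
   Bayesian Information Criterion (γ = 0.5). Symptom clusters come from
   walktrap community detection; symptom importance from strength,
   closeness, and betweenness centralities plus their bridge variants
   (the same measures restricted to cross-cluster structure); accuracy and
   stability from case-resampling of the whole estimation path.
2. **Do patients fall into subgroups with distinct co-severity patterns?**
   Each patient's severity vector X becomes a concordance matrix
   XXᵀ/100; patients are compared by the Adjusted Rand Index between the
   discrete labelings their matrices induce on symptom-pair cells; the
   resulting similarity matrix is clustered with walktrap. Subgroup
   membership is then modelled by multinomial logistic regression on
   demographic/clinical covariates, with Bonferroni-corrected Wald tests,
   AIC, Cragg–Uhler pseudo-R², and a likelihood-ratio test against the
   intercept-only model.

Severity datasets of this kind are rarely public, so the package includes
a synthetic-cohort generator (Gaussian copula with planted block
correlations, planted patient subgroups, and covariates whose
subgroup-conditional distributions imply known multinomial log-odds) that
gives every stage a ground-truth recovery test. See the methods vignette
(`vignettes/symptom-networks.Rmd`) for the full model account.

## Worked example

Three planted symptom blocks, three patient subgroups with disjoint
dominant symptom constellations:

```r
library(symptomnet)

cohort <- generate_cohort(subgroup_cohort_spec(n_patients = 1000, seed = 1))

x   <- nonparanormal_transform(cohort$severity)
sel <- select_network(x, gamma = 0.5)
sel$network
#> <symptom_network> 20 nodes, 91 edges (lambda = 0.0269, gamma = 0.5, n = 1000)

clusters <- walktrap_communities(sel$network)
ari_partition(clusters, cohort$true_symptom_clusters)
#> [1] 0.9614604

sim       <- patient_similarity(cohort$severity)
subgroups <- detect_patient_subgroups(sim, runs = 11, seed = 1)
table(subgroups$assignment$labels)
#>   1   2   3
#> 320 342 338
min(subgroups$consistency)                            # 11 runs agree exactly
#> [1] 1
ari_partition(subgroups$assignment, cohort$true_subgroups)
#> [1] 0.9818641

cent <- centrality_table(sel$network, clusters)
head(cent[order(-cent$strength_z),
          c("node", "strength_z", "closeness_z", "betweenness_z")], 3)
#>    node strength_z closeness_z betweenness_z
#> 5   S05  0.7566910   0.7745536    0.90578619
#> 10  S10  0.7272995   0.5175235    0.01033216
#> 15  S15  0.6561886   0.4577638   -0.54071647
```

The network recovers the three planted 5-symptom blocks as communities
(ARI 0.96 against truth, with the five independent background symptoms
split off separately); the second-order clustering recovers the three
planted subgroups almost exactly (ARI 0.98), identically across all 11
randomized runs; and the highest-strength nodes sit inside the planted
blocks. `fit_multinomial(cohort$covariates, subgroups$assignment)` then
recovers the planted covariate effects (see `analysis/06_regression.R`
for the printed odds-ratio table).

## The analysis workflow

`analysis/` contains the numbered drivers of the full study on the
reference synthetic cohort; each is a thin script over the package
functions and writes its tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | reference cohort (n = 1000, 3 blocks, 3 subgroups, planted covariate effects) |
| `02_preprocess.R` | Shapiro–Wilk screen, topological-overlap redundancy, nonparanormal transform |
| `03_network.R` | EBIC-glasso network, walktrap clusters, (bridge) centralities |
| `04_stability.R` | 200 case resamples: edge intervals, cluster stability |
| `05_subgroups.R` | concordance/ARI similarity, patient subgroups, severity profiles, gated per-subgroup networks |
| `06_regression.R` | reference-group choice, multinomial regression, OR table |
| `07_consolidation.R` | redundant-pair consolidation under moderate couplings (32 → 31 variables) |

Run them in order from the repository root (`Rscript analysis/01_simulate.R`
…). Or run everything in one call through the orchestrator:

```r
report <- run_pipeline(
  pipeline_config(cohort = default_cohort_spec(1000), B = 200L, seed = 7L),
  out_dir = "results/pipeline"
)
```

which writes all artifacts plus a manifest and is byte-identical across
reruns with the same seed.

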