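# mirhubnet

Coexpression-network analysis of paired tumor/normal miRNA sequencing data
in two patient age groups, integrated with mRNA expression from the same
patients. The package targets the question: *which miRNAs sit at the centre
of the tumor coexpression network in early-onset disease, and which genes
do they travel with?* It is written for computational biologists analysing
matched miRNA/mRNA cohorts (the motivating design is early-onset vs
late-onset prostate cancer: 24 + 25 patients, tumor and matched normal
tissue per patient, two sequencing batches).

## The method

For each age group *g*:

1. **Normalize**: TMM scale factors on the miRNA counts, log2 CPM with
   pseudocount 0.5; quantile normalization for the mRNA intensities;
   parametric empirical-Bayes location/scale batch adjustment for both;
   mRNA samples with mean inter-sample Pearson correlation < 0.9 excluded.
2. **Paired moderated DE**: per feature, within-patient tumor − normal
   differences; empirical-Bayes variance moderation
   s̃² = (d₀s₀² + d s²)/(d₀ + d); moderated t with d₀ + d df, BH FDR.
   Strict regime |FC| ≥ 2 & FDR < 0.01 gives the headline lists; relaxed
   regime |FC| ≥ 1.5 & FDR < 0.05, pooled over groups, gives the shared
   feature list both networks are built from.
3. **Hard-threshold network**: Pearson similarity over the group's tumor
   samples; edge iff signed r ≥ τ. τ is selected by scanning a grid and
   comparing the graph's mean local clustering coefficient C(τ) against
   Erdős–Rényi graphs with matched node/edge counts Cᵣ(τ): τ* is the first
   local maximum of the (smoothed) curve C − Cᵣ.
4. **Hub ranking**: maximal cliques via Bron–Kerbosch;
   MCC(v) = Σ_{C ∋ v} (|C|−1)! in exact integer arithmetic; top 20 nodes
   per group are the hub miRNAs.
5. **Hub–mRNA correlation**: Pearson r between each hub and all genes; the
   significance cutoff r\* is the (1 − α) quantile of permutation-null
   |r| pooled over all hub × gene pairs (α = 0.002, 1000 permutations).
6. **Overrepresentation**: hypergeometric upper tail of each hub's
   coexpressed gene list against a GMT collection, expect = mK/N,
   ratio = k/expect, BH FDR per hub battery.

A seeded synthetic-data generator (`sim_config()`,
`generate_mirna_counts()`, `generate_mrna_matrix()`,
`generate_gene_sets()`) plants every structure this analysis assumes —
DE features, two hub-centred modules, hub-correlated genes, an enriched
gene set — together with the ground truth, so the whole pipeline is
testable against known answers.

## Worked example

```r
library(mirhubnet)

cfg <- pipeline_config(sim = sim_config(seed = 3), seed = 3)
run <- run_pipeline(cfg)
print(run)
#> mirhub_run
#>   strict DE: young 53, old 52 (union 60, shared 45)
#>   relaxed DE union (network feature list): 60
#>   young network: tau = 0.50, 39 nodes, 5 components, clustering 0.702
#>   young r_critical = 0.436; 19 significant enrichment rows
#>   old network: tau = 0.50, 32 nodes, 2 components, clustering 0.936
#>   old r_critical = 0.427; 20 significant enrichment rows

head(as.data.frame(run$networks$young$ranking), 3)
#>   rank  feature        mcc degree
#> 1    1 miR-0016 1916006400     14
#> 2    1 miR-0017 1916006400     14
#> 3    1 miR-0018 1916006400     14

run$correlation$young$battery[1, c("hub", "set", "overlap", "expect", "ratio", "fdr")]
#>        hub            set overlap expect    ratio          fdr
#> 1 miR-0001 PLANTED_PC_SET      32 2.8175 11.35759 1.553111e-28
```

Reading the output: the simulated cohort planted 53 young / 52 old DE
miRNAs (45 shared), which the strict regime recovers exactly; both group
networks select τ = 0.50, where the planted modules survive and noise edges
are gone; `miR-0016` — a planted hub — shares the top young MCC rank with
its module's near-clique neighbours; and the planted enriched gene set
(`PLANTED_PC_SET`) dominates the enrichment battery via the other planted
hub `miR-0001`: 32 of the list's genes fall in it against 2.8 expected by
chance (ratio 11.4).

On real data, replace `sim =` with `input_paths = list(counts = ...,
metadata = ..., mrna = ..., gmt = ...)` (TSV matrices, a metadata table
with `sample_id`, `patient_id`, `tissue`, `group`, `batch`, and a GMT
gene-set file). A thin CLI covering simulate/run/validate ships in
`inst/cli/mirhubnet`.

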