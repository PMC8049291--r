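# padex

Expression-pattern characterization of Parkinson's disease associated genes
(PAGs).

Genes implicated in Parkinson's disease fall into two groups — a small set of
disease-*causing* genes from familial studies and a larger set of *risk*
genes from GWAS meta-analyses — and a recurring question is whether, as a
set, they share a transcriptional signature: which tissues prefer to express
them, whether excitatory or inhibitory neurons express them more, how their
expression moves across brain development, and whether those developmental
programs track the age at which patients first show symptoms. `padex`
implements that four-stage characterization as a tested, reusable pipeline
for anyone working with curated gene sets against tissue-level, neuron-type
level, or developmental expression summaries. Because the original
consortium resources (tissue expression tables, single-nucleus atlases,
developmental transcriptomes, patient onset registries) are large external
downloads, the package ships seeded synthetic generators that reproduce the
*statistical structure* each stage assumes, so every stage is testable
end-to-end offline.

## Methods at a glance

* **Gene catalog.** Two curated symbol lists (21 causing, 89 risk genes; 3
  shared: *LRRK2*, *SNCA*, *VPS13C*; 107 total) with exact-symbol union and
  intersection semantics.
* **Tissue preference.** For each gene, tissues ranking in the top 50% of
  its per-tissue mean expression and passing the RPKM ≥ 1 expressed filter
  are its *preferential expression tissues*. Per tissue, over-representation
  of the gene set among preferential calls is tested one-sided with Fisher's
  exact test on the 2×2 table (set × preferential) against the expressed
  background universe: for counts *k* of *K* set genes and *n* of *N*
  universe genes, *p* = P(X ≥ k), X ~ Hypergeom(N, K, n); BH-adjusted
  p-values are reported alongside.
* **Neuron profile.** Per gene, the 45 inhibitory (GABAergic) per-type means
  are compared with the 24 excitatory (glutamatergic) per-type means by the
  Mann–Whitney/Wilcoxon rank-sum test (midranks; exact enumeration for
  small tie-free samples, else the tie-corrected, continuity-corrected
  normal approximation). Genes with p < α are labelled excitatory-higher or
  inhibitory-higher by the class medians; log2(mean + 1) is the display
  scale.
* **Spatiotemporal modules.** Expression is normalized per gene to
  log2(value / gene mean), then a weighted unsigned co-expression network is
  built with soft-threshold adjacency a<sub>ij</sub> = |cor(i,j)|^β (β = 7)
  and the unsigned topological overlap matrix
  TOM<sub>ij</sub> = (Σ<sub>u</sub> a<sub>iu</sub>a<sub>uj</sub> + a<sub>ij</sub>) /
  (min(k<sub>i</sub>, k<sub>j</sub>) + 1 − a<sub>ij</sub>). Modules are
  average-linkage clusters of 1 − TOM under a static cut (height 0.85,
  minimum size 10), summarized by their eigengene (first principal
  component), 12 time-node temporal profile (6 prenatal + 6 postnatal), 16
  brain-region spatial profile, and a prenatal-high / postnatal-high label.
* **Age at onset.** Genes with more than five patient records are binned by
  median age at onset — juvenile (≤ 30 y), early (30–50 y), late (> 50 y) —
  and cross-tabulated against module membership, with per-module medians
  and a descriptive rank-sum comparison of the two largest modules.

## Worked example

```r
library(padex)

catalog <- pdGeneCatalog()
catalog
#> GeneCatalog: 21 causing + 89 risk genes; 3 shared; 107 total
#>   shared: SNCA, LRRK2, VPS13C

## tissue preference on a simulated tissue table with a brain-elevated subset
sim <- simulateTissueMatrix(nGenes = 2000, nSignalGenes = 100, seed = 1)
enr <- enrichTissues(sim$experiment, sim$truth$signalGenes)
head(as.data.frame(enr)[, c("tissue", "k", "K", "n", "N", "p", "significant")], 3)
#>     tissue  k   K    n    N            p significant
#> 1 brain_08 95 100 1012 2000 2.349995e-23        TRUE
#> 2 brain_03 96 100 1046 2000 2.744451e-23        TRUE
#> 3 brain_04 95 100 1050 2000 7.625437e-22        TRUE

## developmental co-expression modules (planted 47/22 split)
dev  <- simulateDevelopmentMatrix(nGenes = 99, module1Size = 47,
                                  module2Size = 22, seed = 1)
norm <- normalizeFoldChange(dev$experiment)
mods <- summarizeModules(detectModules(buildNetwork(norm, power = 7)),
                         norm, dev$experiment)
mods
#> ModuleAssignment: 2 module(s), 30 unassigned of 99 genes
#>   M1: 47 genes (postnatal_high)
#>   M2: 22 genes (prenatal_high)

## onset association: module-1 genes have younger patients
aao   <- simulateAAO(dev$truth, seed = 1)
assoc <- associateModules(classifyOnset(aao), mods, aao)
round(assoc$median_of_gene_medians, 1)
#>         M1         M2 unassigned
#>       39.5       54.7       47.7
```

Interpretation: of the 2000 simulated genes, the 100 planted brain-elevated
genes call the 13 brain tissues preferential far more often than the ~50%
background rate (here 95 of 100 versus 1012 of 2000 for `brain_08`), so the
brain tissues dominate the significant list. The two planted developmental
programs are recovered exactly as a postnatal-rising module of 47 genes and
a prenatal-high module of 22, and patients with records on module-1 genes
have a median onset ~15 years younger than module-2 genes.

A thin command-line wrapper is available at `inst/scripts/padex.R`
(`run`, `catalog` and `simulate` subcommands over the same functions), and
`runPipeline()` orchestrates all stages from one YAML config.

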