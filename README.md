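# metabuffer

Functional redundancy lets a gut microbiome lose a large share of its taxa
while its *metabolic capacity* — the set of metabolic pathways the
community's pooled gene content can encode — stays almost intact.
`metabuffer` is an R package for quantifying that buffering in
amplicon-derived community data. It is aimed at microbial ecologists who
have a taxon-by-sample count table, a taxon-by-enzyme (EC) genome-content
table, and a pathway catalog, and who want to ask: *how much capacity
survives when taxa are lost, and through which redundancy mechanism?*

## What it computes

**Capacity partition.** For a community with relative abundances and genome
content, pathway presence is decided by minimal-set parsimony: a
minimum-cardinality pathway set covering every observed, mappable EC
(exact branch-and-bound up to 25 candidate pathways, greedy set cover
beyond, deterministic lexicographic tie-breaks), intersected with the
pathways whose full EC repertoire is present. The **total** set then splits
into

* **per-taxon** pathways — some present taxon carries every required EC on
  its own genome, and
* **obligately-shared** pathways — the complement: pathways only completable
  by pooling enzymes across two or more genomes,

with *variant classes* (distinct enzyme repertoires, same metabolites)
tracked on top. Per-taxon redundancy of pathway *p* is the number of
families that complete *p* alone.

**Community ecology.** Hill diversity D(q) = (Σ pᵢ^q)^(1/(1−q)) (richness,
Hill-Shannon, Hill-Simpson), Bray-Curtis and Sørensen dissimilarities, NMDS,
distance-based PERMANOVA with restricted permutations for repeated-measures
designs (individuals as exchangeable blocks), a multivariate dispersion
test, and BH-FDR for pairwise contrasts.

**Perturbation analysis.** Prevalence calls (present = detected in ≥ 25% of
a treatment × week window's samples), pathway fate classification between
baseline and end windows (retained / never / gained / lost, at pathway and
family level), and taxon-knockout simulations (`knockout_retention()`,
`buffering_curve()`) measuring the fraction of baseline capacity that
survives removal of taxa under random, rarity-biased, or abundance-biased
loss.

**Synthetic communities.** A calibrated generator
(`scenario_config()` / `simulate_community()`) reproduces the statistical
structure this analysis assumes — 144 families across 21 phyla with ~70% of
families below 1% mean relative abundance, 370 pathways with 32
obligately-shared and an 8% singleton rate among per-taxon pathways, weekly
repeated sampling, and diet perturbations that suppress 30% of families,
biased toward rare ones — so the whole pipeline is testable without any
sequencing data.

## Worked example

```r
library(metabuffer)
library(dplyr)

sim <- simulate_community(scenario_config(seed = 1))

# taxonomic effect of the diet perturbations at the final week
diversity_summary(sim$counts, sim$metadata, q = c(0, 2)) |> filter(week == 8)
#>   treatment  week     q mean_D  sd_D     n
#> 1 balanced      8     0  116.   2.88     7
#> 2 balanced      8     2   35.2  3.64     7
#> 3 cellulose     8     0   92    2.08     7
#> 4 cellulose     8     2   31.7  4.03     7
#> 5 protein       8     0   85.3  4.27     7
#> 6 protein       8     2   30.7  3.21     7

# community structure shifts with treatment (blocks = individuals)
d <- bray_curtis(sim$counts)
permanova(d, groups = sim$metadata$treatment,
          blocks = sim$metadata$individual, n_perm = 999, seed = 1)
#> Distance-based PERMANOVA
#>   pseudo-F(2, 165) = 25.2507, p = 0.001 (blocks, 999 permutations)

# capacity partition of the pooled community
prof <- community_capacity(sim$content, sim$counts, sim$catalog)
prof
#> <capacity_profile: pooled(168 samples)>
#>   total 370 | per-taxon 338 | obligately shared 32 (greedy cover)

redundancy_distribution(prof$incidence)$singleton_fraction
#> [1] 0.0917

# remove the 30% least-abundant families: capacity is buffered
removed <- sim$counts$taxon[order(rowSums(as.matrix(sim$counts[, -1])))][1:43]
knockout_retention(sim$content, sim$counts, sim$catalog, removed)$retention
#> [1] 1
```

Mean richness drops by roughly a fifth to a quarter in the perturbed
treatments (92 and 85 vs 116 effective families) and PERMANOVA separates
the treatments, yet removing the 43 rarest families leaves every one of the
370 pooled pathways encodable — taxonomic diversity and metabolic capacity
decouple. `run_pipeline()` chains all stages (filtering → diversity → beta
statistics → capacity → prevalence/fates/buffering) and writes the report
tables; `autoplot()` methods draw the diversity time courses, NMDS,
buffering curves, and the tan/white/red/black fate matrix. A thin CLI for
simulation and the full pipeline is in `inst/cli/metabuffer.R`.

The methods vignette
(`vignettes/metabolic-capacity-buffering.Rmd`) documents the capacity
model, the permutation schemes, the generator's calibration, and the
package's numerical conventions.

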