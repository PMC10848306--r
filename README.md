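# rumenTransmit

Vertical transmission of rumen bacteria from mother cows to their
offspring, and how stable the community's predicted functions are when its
composition is perturbed.

A subset of rumen bacterial taxa is *heritable* — their relative abundance
shows significant narrow-sense heritability (h²), i.e. host genotype
explains part of the variation. This package implements the downstream
analysis of a two-generation dairy-cow study built around a panel of 32
species-level heritable taxa and 674 nonheritable taxa:

* **Partition-wise compositional similarity.** For each mother–offspring
  pair, similarity is `1 − BC(x, y)` where
  `BC(x, y) = Σ|xᵢ − yᵢ| / Σ(xᵢ + yᵢ)` is the Bray–Curtis dissimilarity of
  the two profiles restricted to the heritable (or nonheritable) taxa.
* **Taxa-function stability.** A community composition `x` is repeatedly
  perturbed; both the original and perturbed compositions are projected
  into function space through a taxon×function gene-content matrix `G`
  (profile ∝ `Gᵀx`), and the functional shift `f` is regressed on the
  taxonomic perturbation magnitude `t` under the power law

  `f = t^b · e^(−a)`

  with attenuation `a` and buffering `b` estimated by OLS on the log–log
  scale. The area under the fitted response curve on `t ∈ [0, 1]` —
  `e^(−a)/(b + 1)` in closed form — summarizes the total expected
  functional shift: smaller AUC means a more stable community function.
* **Genotype association.** SNP genotype classes vs taxon abundances and
  volatile fatty acid (VFA) concentrations, tested with Kruskal–Wallis and
  tiered by Benjamini–Hochberg FDR (`< 0.01` significant, `0.01–0.05`
  suggestive), per trait across SNPs.
* **Co-abundance networks.** Spearman correlations among heritable taxa,
  keeping edges with `|ρ| > 0.4` and `P < 0.05` (strict), exported as a
  Cytoscape-importable edge list.
* **Synthetic paired-cohort generator.** Since the original sequencing
  cohorts are not redistributable, a calibrated generator reproduces their
  downstream structure — 254 mothers, 107 offspring, 17 pairs, the 32/674
  taxon partition, five causal SNPs acting on two key taxa
  (*Pseudoscardovia*, *p-251-o5*, h² = 0.79), VFA couplings, and a
  gene-content matrix in which heritable taxa are more functionally
  redundant — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(rumenTransmit)

co <- simulateCohort(synthParams(), seed = 2024)
m  <- cohortComponent(co, "mothers");  o  <- cohortComponent(co, "offspring")
pr <- cohortComponent(co, "pairs");    pt <- cohortComponent(co, "partition")

simH <- pairwiseSimilarity(m, o, pr, pt, "heritable")
simN <- pairwiseSimilarity(m, o, pr, pt, "nonheritable")
cmp  <- comparePartitions(simH, simN)
cmp$summary
#>          label  n      mean          se
#> 1    heritable 17 0.9216757 0.013967109
#> 2 nonheritable 17 0.8504861 0.003512739
cmp$test
#> Welch t: statistic = 4.94301, df = 18.016, p = 0.0001048
```

The heritable subset is transmitted more faithfully than the nonheritable
one (for this seed, 0.92 vs 0.85; the cohort-level means are calibrated to
0.94 and 0.85). The five causal SNPs are recovered by the association
scan:

```r
rec <- associateTraits(cohortComponent(co, "genotypes"), m,
                       traitList = c("Pseudoscardovia", "p-251-o5"))
head(rec[order(rec$fdr), c("snp", "trait", "statistic", "fdr", "tier")], 5)
#>                  snp           trait statistic      fdr        tier
#> 4 BovineHD1900005868 Pseudoscardovia      40.0 1.05e-08 significant
#> 7  ARS-BFGL-NGS-8960        p-251-o5      37.2 4.21e-08 significant
#> 6       BTB-01532239        p-251-o5      16.1 8.03e-04 significant
#> 3       BTB-00740910 Pseudoscardovia      15.1 8.92e-04 significant
#> 5 BovineHD1300021786 Pseudoscardovia      15.9 8.92e-04 significant
```

and the heritable sub-communities are functionally more stable (smaller
response-curve AUC) than the nonheritable ones:

```r
ids <- pairFrame(pr)$mother
m17 <- AbundanceTable(abundances(m)[ids, , drop = FALSE])
G   <- cohortComponent(co, "functions")
fh  <- cohortStability(m17, G, pt, "heritable",    seed = 1)
fn  <- cohortStability(m17, G, pt, "nonheritable", seed = 1)
compareStability(fh, fn)[, c("coefficient", "mean_a", "mean_b", "p_value")]
#>   coefficient mean_a mean_b  p_value
#> 1           a  0.647  0.205 1.29e-10
#> 2           b  1.013  1.002 5.23e-06
#> 3         auc  0.262  0.407 2.74e-13
```

`runPipeline(config)` chains all stages (simulate → similarity →
stability → associate → network) over a directory of TSV tables and
writes figure-ready outputs plus a run report; see `?runPipeline`.

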