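# col4gly

Genotype–phenotype analysis of glycine substitutions in the collagen IV
genes (*COL4A3*, *COL4A4*, *COL4A5*), for clinical geneticists and
variant-curation pipelines working on Alport syndrome.

Collagen IV α chains are built from Gly-Xaa-Yaa triplet repeats broken by
21–26 short non-collagenous (NC) interruptions, with NC termini retained.
Gly missense variants — the commonest pathogenic class — differ widely in
severity, and `col4gly` stratifies each variant by the three molecular
features that track severity:

* **molecular location**: exons 1–20 vs exon 21 to the carboxyl terminus;
* **collagenous location**: adjacent to an NC interruption/terminus
  ("NC boundary" Gly) or not, and position within the local collagenous
  region (amino end / carboxyl end / central);
* **substituting residue**: mildly (Ala/Ser/Cys) vs highly
  (Arg/Val/Glu/Asp/Trp) destabilising — exactly the residues reachable
  from a Gly codon by one nucleotide change.

Around the classifier the package provides: a maximum-entropy splice-site
screen (variants within 3 bases of a junction whose mutant score falls
more than 15% below wild type are excluded); family-registry extraction
and Kaplan–Meier / log-rank / Cox survival analysis of age at kidney
failure and hearing-loss diagnosis; logistic modelling of haematuria risk
with McFadden's pseudo-R²; and a population stage comparing observed vs
expected proportions of boundary-Gly variants under a neighbour-dependent
substitution-rate model, with the exact binomial test

$$P(X \ge k) = \sum_{j=k}^{n} \binom{n}{j} p_0^j (1-p_0)^{n-j},$$

plus X-linked allele/carrier arithmetic (allele total = hem + het +
2·hom; carriers = hem + het + hom).  Synthetic-data generators with known
ground truth make every stage testable without access to LOVD, the
100,000 Genomes Project or gnomAD.

## Worked example

```r
library(col4gly)

# a synthetic alpha5-like chain: 23 local collagenous regions, 460 Gly
arch <- read_architecture(
  system.file("extdata", "col4a5_synthetic_segments.tsv", package = "col4gly"),
  system.file("extdata", "col4a5_synthetic_exons.tsv", package = "col4gly"))

ann <- annotate_variant(arch, "Gly42Val")
ann
#> col4a5_synthetic_segments Gly42Val: nc_boundary (side amino), exon 2
#>   (exons 1-20), high destabilising, region 1

# survival: synthetic registry -> one observation per family -> Cox model
reg <- gen_registry(arch, n_families = 300, seed = 1)
obs <- build_family_observations(reg, endpoint = "kidney",
  covariates = c("is_carboxyl_block", "is_nc_boundary", "is_high_destab"))
km_fit(obs)
#> Kaplan-Meier: n=300, events=223, median 18 (95% CI 15, 22.2)
cox_fit(obs, c("is_carboxyl_block", "is_nc_boundary", "is_high_destab"))
#> Cox PH (Efron ties): n=300, events=223, LR p=2.227e-12
#>                term   coef    hr ci_low ci_high    se   p_wald
#> 1 is_carboxyl_block  0.344 1.411  1.074    1.85 0.139 1.35e-02
#> 2    is_nc_boundary -0.771 0.462  0.258    0.83 0.298 9.71e-03
#> 3    is_high_destab  1.003 2.727  2.001    3.72 0.158 2.15e-10

# population: observed 15/45 boundary variants vs 10.1% expected
exact_binomial(15, 45, 0.101, "greater")
#> [1] 2.067402e-05
allele_total(hem = 249, het = 442, hom = 7)   # X-linked allele counting
#> [1] 705
```

The Cox fit recovers the generator's log hazard ratios (0.1, −0.8, 0.7):
boundary variants carry roughly half the kidney-failure hazard
(HR 0.46), highly destabilising substitutions nearly triple it
(HR 2.7).  The binomial p-value shows that 15 boundary hits among 45
variants is far more than the ~10% expected under the substitution
model — boundary variants are over-represented in the general
population, consistent with their milder phenotype.

A thin command-line wrapper over the same functions is installed at
`inst/cli/col4gly.R` (`simulate` and `run` subcommands).

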