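# polybrix

Association mapping of soluble solids content (SSC, °Brix) in mixed-ploidy
clonal crops — blackberry-style germplasm panels of 4x–8x individuals —
using dominant presence/absence locus-allele markers.

High-ploidy berry crops lack the maps, populations and dosage-reliable
genotypes that ordinary QTL mapping needs. A practical alternative is to
sequence a targeted panel of high- and low-phenotype clones, code every
locus-allele as present/absent per sample, screen those binary markers
against the trait, and guard against population-structure artifacts with a
pair of nested linear models before committing alleles to assay design.
`polybrix` implements that pipeline, together with the surrounding
arithmetic of such a study: per-environment marker validation,
KASP-style flanking consensus templates, sequencing-versus-assay genotype
concordance, cross-genus syntenic-QTL intersection, and capture-bait
tiling/coverage accounting. A seeded cohort simulator with planted allele
effects makes the whole pipeline testable end to end.

## The model

For each locus-allele column `A` (1 = sample carries ≥ 1 copy):

1. Welch's t-test of per-sample mean SSC between carriers and
   non-carriers; Benjamini–Hochberg correction across all testable columns
   of one reference genome's table (α = 0.05).
2. Population groups from a DAPC-style procedure: PCA of the presence
   matrix, k-means on the retained components for k = 1…10, k chosen by
   `BIC(k) = n·log(WSS_k/n) + k·log(n)`.
3. Two OLS models per screen-significant allele:

       SSC = Group + Allele + Group×Allele + ε        (interaction test)
       SSC = Group + Allele-within-Group + ε          (within-group test)

   both tested by extra-sum-of-squares F against their reduced models.
   An allele is selected iff q ≤ α, the interaction is **not** significant,
   and the within-group term **is** — an association that is consistent
   across groups and holds within them.

Loci are filtered first: strictly less than 20% missing cells (a cell is
missing exactly when its read depth is zero) and 2–4 distinct observed
alleles.

## Worked example

Simulate a 60-sample tetraploid cohort with one planted 1.8 °Brix allele,
then run the discovery engine:

```r
library(polybrix)

cfg <- sim_config(n_samples = 60, ploidies = 4, n_loci = 300, n_groups = 2,
                  causal_alleles = data.frame(locus = 120, allele = 1,
                                              effect = 1.8),
                  seed = 42)
cohort <- simulate_cohort(cfg)
table  <- cohort_genotype_table(cohort)   # or write_cohort() + build_genotype_table()
table
#> <locus_gtable> 300 loci x 60 samples (9.9% missing)

res <- associate_alleles(table, mean_ssc(cohort), seed = 1)
res
#> <ssc_assoc>
#>   loci: 300 in -> 293 after filters
#>   locus-alleles: 844 encoded, 711 tested, 1 BH-significant, 1 selected (alpha = 0.05)

subset(res$records, selected,
       select = c(locus_id, allele, n_present, n_absent, effect, q, m1_p, m2_p))
#>    locus_id allele n_present n_absent effect       q  m1_p     m2_p
#>  Chr3:18000      C        31       24   1.74 7.3e-10 0.842 1.75e-13
```

The planted allele is recovered as the single selected marker: its 31
carriers average 1.74 °Brix more than non-carriers (the planted 1.8), the
group-by-allele interaction is null (p = 0.84, effect consistent across
both breeding groups) and the within-group association is decisive. The
inferred structure (`res$grouping`) found the two simulated groups:

```r
res$grouping
#> <structure_grouping> k = 2 (of 1..10), 45 PCs retained
```

Downstream, `validate_per_environment()` re-tests selected markers within
each location-year, `design_consensus()` emits the IUPAC-ambiguity
consensus template for assay design, and `concordance()` audits
sequencing-versus-assay genotype agreement. `run_ssc_pipeline()` chains
all stages into one seeded, hash-stamped run directory.

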