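---
title: "Mapping soluble-solids loci with dominant allele markers in autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping soluble-solids loci with dominant allele markers in autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cultivated blackberry and its relatives are high, variable polyploids
(4x--12x) with clonally propagated germplasm and thin genomic resources.
Standard biparental QTL mapping is impractical: no dense maps, no large
populations, and genotype calls whose dosage is uncertain. What breeders
need is a way to take targeted long-read sequence from a modest panel of
high- and low-phenotype clones and emerge with a handful of assayable
markers for a quantitative trait — here soluble solids content (SSC,
degrees Brix), the standard refractometer proxy for fruit sweetness.

`polybrix` implements that workflow end to end: mixed-ploidy genotype
tables, dominant locus-allele coding, a Welch + Benjamini-Hochberg screen,
population-structure correction with a pair of nested linear models,
per-environment marker validation, KASP-style consensus template design,
and the cross-genus syntenic-QTL arithmetic used to pick candidate regions
in the first place. A seeded simulator generates cohorts with the same
statistical structure so every stage is testable without external data.

## Dominant locus-allele markers

A locus in a polyploid VCF carries a multiset of allele calls per sample —
`0/0/1/1` for a tetraploid, `0/0/0/1/1/2` for a hexaploid. Estimating
dosage from read ratios is unreliable at moderate depth, so each
(locus, allele) pair is collapsed to a binary *presence/absence* marker:
a sample scores 1 if it carries at least one copy. This dominant coding
costs information but is robust to ploidy and depth, and it is the
established approach for association screens in complex autopolyploids
such as sugarcane.

Two consequences matter for interpretation:

* Presence probabilities are pushed toward 1 as ploidy rises
  (`1 - (1-f)^ploidy`), so rare-presence and rare-absence columns — classes
  of 3--8 samples out of 40 — are common, and in a *mixed*-ploidy panel
  presence correlates with ploidy itself.
* The columns of one locus are not independent: a biallelic locus yields
  two complementary-ish markers of the same polymorphism. For that reason
  the package's simulation studies count discoveries at the *locus* level;
  selecting the complementary allele of a planted causal allele marks the
  same polymorphism, not a false positive.

## The discovery procedure

1. **Table construction.** `build_genotype_table()` reads the VCF
   (via `vcfR`); any genotype containing a `.` is wholly missing (no
   partial-dosage imputation — the conservative choice when no rule is
   defensible). `apply_depth_missingness()` forces cells with zero read
   depth to missing, the rule used when depth, not the caller, defines
   what was observed.
2. **Filtering.** `filter_loci()` keeps loci with strictly less than 20%
   missing cells and 2--4 distinct observed alleles. The boundary is
   strict: a locus missing in exactly 20% of samples is removed.
3. **Screen.** `welch_screen()` performs a two-sided Welch t-test of
   per-sample mean SSC between carriers and non-carriers of every column,
   Welch--Satterthwaite degrees of freedom, columns with a class below 3
   samples or no variance excluded. `bh_adjust()` applies step-up FDR
   control over the testable columns of one reference genome's table —
   each genome's table is its own multiple-testing family.
4. **Structure.** `infer_structure_groups()` is a
   discriminant-analysis-of-principal-components style grouping: PCA on the
   mean-imputed presence matrix (columns with at least 20% missing dropped),
   the fewest components reaching 90% of variance retained, k-means with 50
   restarts for each candidate k, and
   `BIC(k) = n log(WSS_k / n) + k log(n)` minimised, ties to the smaller k.
   Published cluster labels can be supplied instead.
5. **Structure correction.** Every screen-significant allele is fit to
   two ordinary least-squares models:
   * Model 1: `SSC ~ Group + Allele + Group:Allele`; the interaction is
     tested against `Group + Allele` by an extra-sum-of-squares F-test.
     Significance means the allele's effect differs between groups —
     a structure-dependent association.
   * Model 2: `SSC ~ Group + Group:Allele` (allele nested within group)
     against `SSC ~ Group`, testing all within-group allele terms jointly.
     Significance means association beyond structure. With one group this
     reduces exactly to the pooled two-sample F (= t squared).

   An allele is **selected** iff its q-value is at most 0.05, its
   interaction is *not* significant (or undefined because there is a
   single group), and its within-group term *is* significant. Inestimable
   within-group terms never select. `associate_alleles()` runs steps 2--5
   and `model_tests_fast()` provides closed-form cell-mean equivalents of
   the two F-tests for genome-scale runs (equality with the `lm` route is
   property-tested to 1e-7).

## The simulator

`sim_config()` / `simulate_cohort()` generate cohorts with the structure
the analysis assumes: ~40 clonal samples of even ploidy 4x--8x, ~10^3
biallelic-to-tetraallelic loci, 2--4 groups with per-group
Dirichlet-drawn allele frequencies (concentration 0.5 by default —
strongly differentiated breeding programs, consistent with how distinct
the real programs are), dosage drawn per chromosome copy, phenotypes as
three juicing replicates in each of four location-year environments, and
missingness that is exactly "depth zero" at a configurable rate.

The phenotype model is
`baseline + env + group shift + dominant planted effects + N(0, residual_sd)`
with the residual drawn once per (sample, environment) — the biological and
genotype-by-environment noise that replicate juicing cannot average away —
plus optional replicate-level measurement noise (`rep_sd`, default 0 so
degenerate noise-free configurations are exact). With the default four
environments, per-sample mean SSC has standard deviation `residual_sd/2`.

Planted alleles come in two kinds: `causal_alleles` carry the same effect
in every group at equal carrier frequency (structure-independent);
`interaction_alleles` flip sign between groups and differ in carrier
frequency (0.25 vs 0.05 per copy), giving them the nonzero marginal effect
needed to reach the screen so the interaction test has something to catch.

What the simulator does *not* emulate: linkage disequilibrium (loci are
independent), pedigree relatedness, dosage-informative read ratios, and
allele-specific sequencing error. Passing tests therefore demonstrate the
statistical machinery under idealised sampling, not performance on any
particular real panel.

## Calibration studies and their design choices

The test suite runs three simulation studies whose designs deserve
explanation:

* **Null error control** uses unstructured (single-group) cohorts of 40
  samples. The size of an aggregate rejection rate is only interpretable
  against a binomial reference when tests are close to independent;
  structured cohorts add strong between-column dependence (thousands of
  columns shadow the group indicator), which changes the variance of the
  estimate without changing the per-test size. Even unstructured, the
  Welch approximation is measurably liberal for classes of 3--5 samples
  (about 0.08 and 0.06 at nominal 0.05) while essentially exact from class
  size 6 up; with dominant coding at n = 40 such columns are unavoidable,
  so the aggregate sits near 0.055 rather than 0.050. This is a property
  of Welch's test, not of the implementation — the suite also verifies
  exactness on the large-class subset and agreement with `t.test` to
  1e-10.
* **Parameter recovery** plants twenty structure-independent alleles with
  effects 0.5--2.0 Brix among ~2,000 null columns in a 96-sample
  tetraploid two-group panel (a uniform-ploidy validation panel is the
  standard design; in a mixed-ploidy panel polygenic load correlates with
  ploidy and with every presence column, which is a real phenomenon but a
  different experiment). Because loci are unlinked, the planted alleles
  themselves contribute polygenic variance `sum(e^2) * var(presence)` —
  about 2.8 Brix of standard deviation against a 0.75-Brix residual — so
  individual marginal tests compete against the other nineteen effects.
  Recall of individual planted loci is therefore intrinsically low in this
  design, and chance within-group correlations between structure-aligned
  null columns and large-effect carriers produce proxy discoveries that
  marginal BH plus the two models cannot fully remove (conditional
  multi-locus modelling would, but the procedure here is deliberately the
  simple marginal one). The suite reports both quantities honestly rather
  than redesigning the study around them.
* **Confounded-allele exclusion** plants five sign-flipping alleles and
  verifies the interaction screen removes them from the selected set in
  nearly all replicates.
* **Structure recovery** checks that the PCA + k-means + BIC grouping
  recovers k = 2, 3, 4 and the labels (up to permutation) on
  well-separated cohorts (Dirichlet concentration 0.1, 36 samples, 150
  loci) across 100 seeds per k.

Problem sizes throughout (cohort counts, replicate counts, loci per
cohort) are chosen so each study estimates its quantity to within a few
percent while the whole suite runs in minutes on one core.

## Marker validation and assay design

`validate_per_environment()` repeats the Welch + BH screen separately
within each location-year, the family being the markers tested in that
environment — environments are not corrected across, matching how
multi-environment marker validation is reported. Effects are carrier minus
non-carrier means; `marker_effect_sizes()` reports both pooled and
per-environment estimates, since either convention appears in practice.

`design_consensus()` builds the ungapped template an allele-specific PCR
vendor needs: the target allele written verbatim at its position, every
other SNP in the window IUPAC-ambiguity-coded over reference plus
alternates, and flanking indels *flagged* rather than encoded — an indel
within ~25 bp of the target is a known failure mode for these assays, and
a gapped template is not usable. The 50 bp default flank is configurable.

`concordance()` compares genotype strings as unordered multisets; with
`target_alleles` supplied it first collapses alleles to target-vs-other,
because a biallelic competitive assay cannot distinguish two different
non-target alleles and must not be read as dosage. On the packaged
13-sample comparison panel this reproduces exactly the published
concordance pattern (11 of 13, with the two discordant samples being
homozygous-target assay calls at heterozygous sequencing positions);
the naive multiset rule would count three additional samples discordant
merely for carrying rare non-target variants the assay reads as reference.

## Syntenic QTL intersection and bait arithmetic

`find_conserved_qtl_regions()` reports a cross-genome synteny block as a
conserved trait region when QTL intervals from at least two distinct
genomes overlap its member segments (1-based inclusive, one shared base
suffices, no minimum overlap fraction). Intervals live in `GenomicRanges`
with genome-prefixed seqnames so cross-genome coordinates can never
collide. `tile_baits()` reproduces capture-bait accounting: exons under
50 nt removed, 80-nt baits at 2X tiling (40 nt step) with a terminal bait
flush to the exon end, sub-bait-length exons getting one short flagged
bait, and coverage percentages rounded half-up to one decimal.

## Numerical and degenerate-input choices

* Ties in the BIC curve and exact-zero within-cluster sums of squares
  resolve to the smallest k; a zero-variance matrix short-circuits to one
  group.
* Welch statistics are computed by column-vectorised moment sums with
  variances clamped at zero; columns with both class variances zero are
  untestable (`NA`) rather than infinite.
* The fast model tests centre the phenotype before forming sums of squares
  to avoid catastrophic cancellation in near-null columns.
* Partial genotypes, inconsistent per-sample ploidy, out-of-range allele
  indices and malformed depth tables raise locus-labelled errors early.
* All randomness in a simulation flows from one integer seed with a fixed
  draw order; two runs of any seeded entry point are bitwise identical.

## Known limitations

Dominant coding discards dosage and with it real power; mixed-model
(kinship) correction, haplotype phasing, LD-aware proxy control and
permutation-based thresholds are all out of scope. The Welch screen's
small-class liberality and the proxy-discovery behaviour described above
are inherent to the marginal single-marker design at this panel size and
should be kept in mind when reading its output on real data.
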