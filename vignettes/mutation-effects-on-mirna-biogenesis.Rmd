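---
title: "Deciding whether a miRNA gene mutation disrupts biogenesis"
author: "mirMutImpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether a miRNA gene mutation disrupts biogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirMutImpact)
```

## The problem

Somatic mutations in microRNA genes — the ~60–90 nt pre-miRNA hairpin and
its immediate flanks — are usually dismissed as variants of unknown
significance because, unlike coding variants, there is no genetic code to
predict their consequences. Yet miRNA biogenesis depends on the hairpin's
structure and on sequence motifs at the DROSHA and DICER1 cleavage sites,
so even a single substitution can change how much mature miRNA is made,
where the nucleases cut (the isomiR profile), or which arm of the duplex
becomes the dominant mature strand.

`mirMutImpact` implements a statistical screen for these three endpoints.
Given a mutation table, allele-resolved isomiR read tables, and normalized
expression matrices, it classifies each eligible mutation as affecting (or
not) the miRNA level, the isomiR profile, and the 5p/3p strand balance,
using two complementary comparisons:

* **within-sample** — mutant versus wild-type allele in the same tumor
  sample (possible only for mutations inside a mature miRNA, where the
  variant is visible in the reads); and
* **cross-sample** — the single mutated sample versus the wild-type cohort
  of the same cancer type.

## Coordinate frame and isomiR taxonomy

All positions use hairpin (n.) coordinates: n.1 is the first pre-miRNA
nucleotide, the 5' flank is numbered −25…−1 (no zero) and the 3' flank
L+1…L+25. Subregion labels (`flank5`, `duplex5p`, `seed5p`, `loop`,
`duplex3p`, `seed3p`, `flank3`) come from the annotated mature spans, never
from the raw number: everything 5' of the 5p mature start is `flank5` and
everything 3' of the 3p mature end is `flank3`, even when that position is
still inside the annotated hairpin. The seed is mature positions 2–8 of
each arm.

Reads are classified by the signed shifts of their ends against the
canonical mature ends, positive meaning a downstream (3'-ward) shift; a
read with `shift5 = +1` is one nucleotide *shorter* at its 5p end. The
signs of `(shift5, shift3)` give exactly nine basic classes in 5p|3p
notation (`0|0` is the canonical isomiR); reads carrying nontemplated 3'
additions form a tenth class, `(nt)`, used by the cross-sample profile
comparison. A published figure in the source literature of this method
family uses the opposite sign parenthetical in one sentence; this package
fixes the convention above (methods definition) everywhere and documents
it rather than guessing at the discrepant reading.

```{r taxonomy}
classLabels("ten")
isomirClass(shift5 = 1, shift3 = -1, nontemplate = FALSE)
```

## Eligibility

Before any testing, nine dataset-level exclusions remove mutations whose
effect cannot be measured cleanly: redundant multicopy genes, multiple
mutations in one gene and sample, indels longer than 4 nt, samples without
(or with multiple) small-RNA datasets, genes with an undefined mature arm,
genes with no reads in the mutated sample, genes dominated by ambiguously
mapping reads, and mature-region mutations missing from the external
variant catalog used by the read mapper (supplied as a flag so the package
stays self-contained). The catalog has no published numeric rule for
"dominated by ambiguous reads"; the default here is > 50% of the gene's
reads in the mutated sample, configurable in `datasetExclusions()`.

Each experiment then applies its own read-support minimum (50 total reads;
50 reads per allele; 10 RPM; 20 RPM per strand; 50 total reads). All
exclusions are reported with reason codes rather than silently dropped.

## The five experiments

**Allelic miRNA level.** The mutant-allele fraction among miRNA reads is
compared with the mutant fraction among DNA reads by a two-sided Fisher
exact test; the effect size is
$\log_2 \mathrm{FC} = \log_2(f^{RNA}_{mut} / f^{DNA}_{mut})$, with a
Haldane 0.5 correction applied to the fold change (never the test) when a
cell is zero. A call requires adjusted p < 0.05 and |log2FC| ≥ 1. The
adjustment method is Benjamini–Hochberg by default (the source method
states only "adjusted"); Bonferroni is available by configuration.

**Allelic isomiR profile.** The 2×9 allele-by-class count table, with a
pseudocount of 5 added to every cell, is tested by Pearson's chi-square;
the effect size is Cramer's V = √(χ²/N) computed on the same pseudocounted
table (for internal consistency; the source is silent on the totals used).
A call requires adjusted p < 10⁻¹¹ and V > 0.2; V bins of <0.1, 0.1–0.2,
0.2–0.4, >0.4 label the association strength. `pairwiseProfileV()`
reproduces the control analysis showing that same-allele profiles from
different samples stay below the 0.2 threshold while mutant-vs-wild-type
pairs exceed it.

**Cohort level, profile distance, and strand balance** share one engine
(`cohortCompare()`): a one-sample t test of the wild-type values against
the mutated sample's value (the only orientation consistent with a
one-sample test when there is a single mutated sample; two-sided), a
z-score with a two-sided normal p (sidedness is not stated in the source;
two-sided is the conservative choice), and the Tukey 1.5·IQR outlier rule.
Bonferroni correction uses the number of mutations tested in the same
experiment within the run.

* Level: values are log2(RPM+1); log2FC is computed on the log scale
  against the mean of the log-transformed wild-type levels (a raw-ratio
  variant is exposed in code for comparison). Call: Bonferroni t p < 0.05
  ∧ z p < 0.05 ∧ |log2FC| > 1 ∧ outlier.
* IsomiR profile: ten-class RPM-weighted profiles; the reference is the
  arithmetic per-class mean over wild-type samples (not leave-one-out —
  each wild-type distance is computed to that same mean, which biases
  wild-type distances slightly low at small cohorts; at n ≈ 50 the bias is
  a 1/n shrinkage). The statistic is the L1 distance, bounded by 2. Call:
  Bonferroni t ∧ z ∧ distance > 0.2, one test per strand that passes the
  20-RPM filter. Because two strands can be tested per mutation with no
  cross-arm correction, the mutation-level "significant in at least one
  strand" roll-up has roughly twice the per-test false-positive rate; the
  per-test rate is the calibrated quantity.
* Strand balance: B = log2((c5p+1)/(c3p+1)) on raw counts; the effect size
  is the 5p-fraction change in percentage points, with the "10% change"
  rule read as 10 percentage points (the stricter, plainer reading; the
  reference example, 99.7% → 65%, satisfies either). Call: Bonferroni t ∧
  z ∧ |Δf5p| > 10 points ∧ outlier.

Mutations called in at least one experiment are rolled up as *functional*
(`functionalCalls()`), and `functionalEnrichment()` tests whether
functional mutations are overrepresented among homozygous ones.

## Precursor stability

`stabilityRecords()` folds the wild-type and mutant extended precursors
(hairpin + 25-nt flanks; `mutateSequence()` applies substitutions,
deletions ≤ 4 nt, duplications, insertions) and reports
ddG = dG(mut) − dG(wt), positive values destabilizing. Folding is a
pluggable contract: `viennaFoldBackend()` calls RNAfold for real
minimum-free-energy estimates when the executable is available, while
`ladderFoldBackend()` is a deterministic complementarity-ladder proxy —
explicitly *not* a free-energy model — so that every downstream statistic
(`ddgCohortTests()`: paired t of dG(mut) vs dG(wt), Welch t of ddG for
functional vs remaining mutations; Student's by option) is exercised
reproducibly on any machine. Absolute ddG values are therefore
backend-dependent and only comparisons computed with one backend are
meaningful.

## The synthetic cohort generator

Because the original tumor data cannot be redistributed, the package ships
a generative model (`simulateCohort()`) that emulates the statistical
structure the experiments assume, with known injected truth:

* gene expression: log-normal baseline across genes (default meanlog
  log 1000 RPM, sdlog 1) with log-normal sample noise (sdlog 0.5,
  a 50%-scale coefficient of variation typical of tumor cohorts);
* isomiR class counts: Dirichlet-multinomial per sample and arm
  (concentration 300 around a canonical-heavy ten-class template), giving
  realistic overdispersion beyond multinomial noise;
* arm balance: Beta-distributed per-sample 5p fraction (default mean 0.8,
  concentration 200);
* alleles: the mutant allele contributes VAF·λ of the gene's output, so
  the expected mutant read fraction is VAF·λ/(1−VAF+VAF·λ); DNA reads are
  Binomial at depth 100;
* effects: a level multiplier λ, a class shift moving a stated mass
  between two classes of the mutant allele's template (an allele-level L1
  distance of exactly twice the mass), and a strand shift setting the
  mutant allele's 5p fraction. Ambiguous reads are added at a small rate
  to exercise the exclusion logic.

These distributions are the simulator's stated model — they are not
claims about tumor data. What passing tests show is that the pipeline's
callers are calibrated (≤ 5% false calls on nulls) and sensitive (≥ 90%
recovery of the injected effects) *under this model*; real cohorts add
batch effects, normal-tissue contamination and expression landscapes the
generator does not attempt to reproduce, so real-data sensitivity will be
lower, as the screening design itself anticipates by preferring
specificity.

The strand-flip validation scenario mirrors a documented extreme case: a
cohort whose 5p arm carries ~99.7% of reads, and a mutated sample observed
at ~65% despite a DNA VAF of only 0.19. A pure within-allele reallocation
cannot produce that observation (the mixture bound at VAF 0.19 is ~93%),
so the scenario models what the observation implies — a mutant allele that
both flips strands (f5p = 0.05) and raises its output (λ = 2.5), which
reproduces the observed sample fraction. This is the package's modelling
choice for an under-determined published observation.

Problem sizes used in the shipped validation suite — cohorts of 50
wild-type samples, 200 null mutations for error-rate checks and 100
replicates per injected effect — were chosen as the smallest sizes at
which the binomial uncertainty on a 5% rate is clearly below the
acceptance margins.

## Numerical choices and edge cases

* Two-sided exact p: sum of hypergeometric probabilities ≤ that of the
  observed table (the common convention; exact two-sided p-values are
  definition-dependent). Degenerate tables (a zero margin) return p = 1.
* Zero cohort variance or cohorts smaller than 3 are flagged
  (`degenerate_cohort`, `cohort_too_small`) and never produce a call.
* Profiles with zero total weight raise `empty_profile` rather than
  returning NaN fractions.
* Class-label order is fixed (canonical first) for stable serialization;
  all result writers produce deterministic TSV so identical seeds yield
  byte-identical bundles.
* End shifts beyond ±10 nt are rejected at the boundary of the read
  tables, matching the shift range the upstream validation experiments
  define as isomiRs.

## Known limitations

* The ladder folding stub orders stability changes only roughly; any
  scientific ddG statement requires the RNAfold backend.
* Aggregate results that depend on the original tumor cohorts (headline
  mutation counts, the mean ddG of all tested mutations) are out of scope:
  they require data this package deliberately does not bundle.
* Batch correction of expression matrices is upstream of this package;
  matrices are taken as already normalized.
* The within-sample tests are blind to homozygous mutations (there is no
  wild-type allele to compare against) — a structural limit of
  allele-resolved designs, handled by the cross-sample experiments.
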