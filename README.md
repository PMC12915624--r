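# mirMutImpact

Statistical screening of somatic mutations in microRNA genes for effects
on miRNA biogenesis. For each mutation, the package asks three questions
against allele-resolved small-RNA sequencing data:

1. does the mutation change the **level** of the mature miRNA,
2. does it change the **isomiR profile** — the precision of DROSHA/DICER1
   cleavage, read off the distribution of 5'/3' end shifts, and
3. does it change the **5p/3p strand balance** of the precursor's two arms?

It is written for computational biologists working with tumor cohorts
(mutation tables plus isomiR-resolved read counts, e.g. isoMiRmap output)
who need reproducible, threshold-explicit calls of "this mutation damages
this miRNA gene" with auditable exclusion reasons.

## The statistics at the core

IsomiRs are classified by the signs of their end shifts against the
canonical miRBase ends (5p|3p notation; `0|0` canonical, nine basic
classes, plus `(nt)` for nontemplated 3' additions). Two complementary
comparisons are implemented:

**Within a mutated sample** (mutation visible in the reads):

- level: Fisher's exact test of mutant-allele fractions at the RNA versus
  DNA level, log2FC of the two fractions; call at adjusted p < 0.05 and
  |log2FC| ≥ 1;
- isomiR profile: Pearson chi-square on the pseudocounted 2×9
  allele-by-class table with Cramer's V = sqrt(chi2/N); call at adjusted
  p < 1e-11 and V > 0.2.

**One mutated sample versus the wild-type cohort** of the same cancer
type, sharing one engine — one-sample t test (cohort against the mutated
value), z-score, Tukey 1.5·IQR outlier rule:

- level on log2(RPM+1), call at Bonferroni t p < 0.05 ∧ z p < 0.05 ∧
  |log2FC| > 1 ∧ outlier;
- isomiR profile via the L1 distance (range 0–2) to the mean wild-type
  ten-class profile, call at distance > 0.2 plus the t and z criteria;
- strand balance B = log2((c5p+1)/(c3p+1)), call at a > 10
  percentage-point change of the 5p fraction plus t, z and outlier.

Around the tests sit the eligibility module (nine dataset-level exclusion
criteria and per-experiment read minima, all reported with reason codes),
a precursor-stability module (ddG = dG_mut − dG_wt against a pluggable
folding backend; RNAfold when available, a deterministic stub otherwise),
and a Dirichlet-multinomial cohort simulator with injectable effects that
makes every stage testable without access to protected tumor data.

## Worked example

Simulate a 50-sample cohort with three known effects — a 64-fold level
drop in a homozygous mutation, a 40%-mass isomiR class shift, and a
strand flip (mutant allele f5p 0.05, output ×2.5, DNA VAF 0.19) — and run
the full pipeline:

```r
library(mirMutImpact)

cfg <- simulationConfig(n_wt_samples = 50, n_genes = 3)
effects <- list(
  effectSpec("DEMO_LEVEL",  "SIMG001", "MUTS1", vaf_dna = 1,
             level_multiplier = 1/64, homozygous = TRUE),
  effectSpec("DEMO_ISOMIR", "SIMG002", "MUTS1", vaf_dna = 0.5,
             class_shift = list(from = "0|0", to = "+|0", mass = 0.4)),
  effectSpec("DEMO_STRAND", "SIMG003", "MUTS2", vaf_dna = 0.19,
             level_multiplier = 2.5, strand_shift = 0.05))
sim <- simulateCohort(cfg, effects, seed = 7)
res <- runPipeline(sim$annotations, sim$isomirs, sim$expression,
                   sim$mutations)
res
#> MirnaPipelineResult
#>   mutations: 3 input, 3 eligible
#>   exp1: 2 tested, 1 called
#>   exp2: 2 tested, 0 called
#>   exp3: 3 tested, 1 called
#>   exp4: 4 tested, 2 called
#>   exp5: 2 tested, 1 called
#>   functional mutations: 3
```

The cohort level test recovers the injected 64-fold drop (log2FC ≈ −6,
z ≈ −8.5, an IQR outlier), and only that mutation:

```r
res$exp3[, c("mutation_id", "log2fc", "t_p_bonf", "z", "outlier", "call")]
#>   mutation_id  log2fc t_p_bonf       z outlier     call
#> 1  DEMO_LEVEL -6.2484 5.47e-48 -8.4840    TRUE decrease
#> 2 DEMO_ISOMIR  0.0119 1.00e+00  0.0152   FALSE       ns
#> 3 DEMO_STRAND  0.9647 1.09e-13  1.4628   FALSE       ns
```

The strand-balance test sees the mutated sample's 5p fraction fall from
~80% to 50% (−27 points) and calls it, while the class-shift mutation
(which leaves arm totals alone) stays negative:

```r
res$exp5[, c("mutation_id", "f5p_mut", "delta_f5p", "z", "call")]
#>   mutation_id f5p_mut delta_f5p      z  call
#> 1 DEMO_ISOMIR   0.804      3.31  0.858 FALSE
#> 2 DEMO_STRAND   0.500    -26.73 -6.100  TRUE
```

Cohort-level summary statistics follow the same printed conventions as
the run reports; for example, the homozygosity enrichment of functional
mutations:

```r
r <- functionalEnrichment(20, 88, 67, 615)
#> fold enrichment 2.1 (22.7% vs 10.9%), Fisher p = 0.003
```

A command-line demo wrapping the same calls is installed at
`inst/scripts/run-demo.R`
(`Rscript run-demo.R --seed 7 --out demo-dir`).

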