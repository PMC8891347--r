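---
title: "Designing and evaluating SNP panels for intra-specific hybrid-class assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating SNP panels for intra-specific hybrid-class assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridpanel)
```

## The problem

When an anadromous and a freshwater-resident form of the same fish species
spawn in the same river — as sockeye salmon and kokanee do in lakes of the
Columbia basin — their offspring and later-generation hybrids are
morphologically hard to tell apart, yet their proportions matter for stock
assessment and for judging the outcome of reintroduction programs.
Conventional marker sets can separate pure stocks from "hybrids" but not the
advanced classes (F2 and first backcrosses), whose genotype distributions
sit close to the pure parental ones. A few hundred highly differentiated
SNPs, genotyped by multiplexed amplicon sequencing (GT-seq), provide enough
information to assign individuals to six *genotype-frequency classes*: the
two pure forms, F1, F2, and the two first backcrosses.

`hybridpanel` implements that whole workflow as testable R code: a
synthetic RAD-like data generator (so every stage can be exercised without
any external download), per-locus population-genetic statistics, the
candidate-locus filter chain, a Mendelian simulator of the six classes, a
Bayesian class assigner in deterministic and MCMC modes, assignment power
evaluation, and cohort composition analysis.

## The class model

Each class is described by a triple $\varphi = (\varphi_{00}, \varphi_{01},
\varphi_{11})$: the probability that the two gene copies at a locus
descend, respectively, both from population 0 (kokanee, in the motivating
system), one from each population, or both from population 1 (sockeye).
Mendelian segregation fixes these triples:

| class | $\varphi_{00}$ | $\varphi_{01}$ | $\varphi_{11}$ |
|-------|------|------|------|
| pure0 | 1 | 0 | 0 |
| pure1 | 0 | 0 | 1 |
| F1    | 0 | 1 | 0 |
| F2    | 1/4 | 1/2 | 1/4 |
| BC0 (F1 × pure0) | 1/2 | 1/2 | 0 |
| BC1 (F1 × pure1) | 0 | 1/2 | 1/2 |

With alternate-allele frequencies $p_0, p_1$ in the two populations and
$q = 1 - p$, the genotype probabilities under a class are the mixture over
copy origins, e.g.

$$P(g = 1 \mid \varphi) = 2\varphi_{00} p_0 q_0 +
  \varphi_{01}(p_0 q_1 + q_0 p_1) + 2\varphi_{11} p_1 q_1 .$$

Assignment multiplies these probabilities over (non-missing) loci, applies
a class prior (uniform by default), and normalizes. `assign_plugin()` does
exactly this with smoothed point-estimate frequencies — a deterministic,
exactly reproducible surface that is convenient for testing and fast
enough for thousands of individuals. `assign_gibbs()` is the MCMC
counterpart mirroring how NEWHYBRIDS is usually run with known reference
populations: per sweep it redraws allele frequencies from their Beta
posteriors given the reference genotypes (Jeffreys prior), latent class
labels for the test individuals, and mixture proportions from a flat
Dirichlet updated by the test labels only. The reference individuals act
purely as frequency informers — the "z/s flag" semantics — and never enter
the mixture. Defaults are a burn-in of 10,000 sweeps followed by 50,000
retained sweeps. On informative panels the two modes agree on virtually
every max-posterior call; disagreement is concentrated on borderline
F1/F2 individuals whose posteriors straddle 0.5.

Two numerical choices matter here. First, reference allele frequencies are
smoothed with a pseudocount (default 0.5 per allele class):
$(x + 0.5) / (2n + 1)$. Without smoothing, a locus fixed in a reference
sample would annihilate the likelihood of any test individual carrying the
other allele there. Second, missing genotypes contribute a factor of 1 to
the likelihood (marginalized by omission), and an individual with no
called loci gets the prior back, with a tie flag. Posterior ties are broken
by the fixed class order pure0, pure1, F1, F2, BC0, BC1.

## The filter chain

Candidate loci from a RAD-seq screen of the two reference collections pass
through, in order:

1. **Quality**: call rate ≥ 60% in *both* populations, pooled minor allele
   frequency strictly > 0.05.
2. **Homeolog screen**: salmonids carry a whole-genome duplication; a
   collapsed paralog pair mimics a SNP with excess heterozygosity. A locus
   is removed only when the signature (negative $F_{is}$ or
   $H_{obs} > 0.5$) appears in *both* populations; a one-population
   signature is more likely sampling noise. An undefined $F_{is}$
   (monomorphic sample) counts as "no signature" — conservative keep,
   flagged.
3. **Hardy–Weinberg**: exact test (full enumeration of heterozygote
   configurations given the allele counts, two-sided) per population;
   removal when p < 0.05 in either population. The source workflow did
   not state its alpha or whether tests were pooled; per-population tests
   at 0.05 are the package default and both are configurable.
4. **Tag position**: the SNP must sit on base pairs 40–70 (inclusive,
   1-based) of its RAD tag so both flanks can hold a primer.
5. **Ranking**: survivors are ordered by two-population Weir–Cockerham
   $\theta$ (the variance-components $a/(a+b+c)$ estimator, computed per
   locus) and truncated to the top 650. Ties are broken lexicographically
   by locus id and flagged.
6. **Linkage pruning**: pairs in genotypic linkage disequilibrium lose
   their lower-$\theta$ member, iterated to a fixed point, then the list
   is truncated to 600 candidates.

The linkage test deserves its own paragraph. The original workflow used
GENEPOP's exact test; we use a log-likelihood-ratio (G) statistic on the
3×3 genotype table with a permutation null — the same null hypothesis with
a simpler, fully seeded contract. Two details are easy to get wrong.
*Within-population testing*: on the pooled sample, two unlinked loci that
are both strongly differentiated are strongly correlated (in the extreme,
oppositely fixed loci have $r = 1$), so a pooled test would
preferentially prune exactly the loci the panel exists for. Like GENEPOP,
`ld_prune()` therefore tests each pair within each population and combines
the two p-values with Fisher's method. *Prescreening*: testing all
~200,000 pairs of 650 candidates at $\alpha = 0.05$ without correction
would remove thousands of loci on chance significance alone (and is
computationally disproportionate). The pruner therefore permutation-tests
only pairs whose within-population genotype correlation reaches
$r^2 \ge 0.8$ — calibrated to the near-duplicate loci the filter targets
(≥ 95% genotype identity gives $r^2 \approx 0.9$) and above the noise
quantiles of $r^2$ at reference sample sizes of 20–35.

Stage counts are conserved by construction: each stage's survivors are the
next stage's input, and each removed locus records the first stage that
removed it. `model_primer_dropout()` abstracts the wet-lab multiplex
optimization (three iterative test libraries in the original workflow)
as three modes: a seeded random subset (e.g. 350 of 600), a named drop
list (e.g. the 258 loci lost to primer interactions, leaving 342), and a
read-share rule removing loci that exceed 2% of total reads. No
amplification chemistry is modelled.

## The synthetic data generator

`simulate_rad_dataset()` emulates the statistical structure the pipeline
assumes, not the biology of any particular lake:

* Per locus, an ancestral frequency is drawn uniformly on [0.1, 0.9]
  (avoiding degenerate monomorphic loci) and the two population
  frequencies from the Balding–Nichols Beta
  $\mathrm{Beta}\!\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$, giving a
  unimodal $\theta$ distribution with a high-divergence tail. The default
  $F = 0.15$ produces pairwise $\theta$ around 0.25 with outliers up to
  ~0.8 at 3,000 loci.
* Diploid genotypes are binomial draws; loci monomorphic in both samples
  are redrawn; missing calls are masked uniformly at 5% by default.
* 25 locus pairs are near-duplicates (≥ 95% genotype identity) to give
  the linkage pruner something real to find, and 50 loci are forced
  all-heterozygote in both populations to exercise the homeolog screen.
* Tags are 90 bp (a typical RAD tag length) with the SNP position uniform
  on the tag; sample sizes default to 20 and 35 diploids, matching the
  reference collections of the motivating system.

Defaults were fixed once, on field-realism grounds, and the generator is
deterministic given its seed. What the generator does **not** emulate:
genotyping error, allelic dropout, read-depth structure, physical linkage
beyond duplicated tags, within-population substructure, and — importantly
— the empirical divergence profile of any real sockeye/kokanee dataset.
Real RAD screens of such systems offer tens of thousands of candidate
loci whose outlier tail is shaped by divergent selection; a 3,000-locus
Balding–Nichols pool is a deliberately modest stand-in. Passing tests on
synthetic data therefore demonstrate correctness of the machinery and
realistic relative behaviour (which classes are hard, how power decays
with threshold), not field performance of any particular panel.

That caveat has a measurable consequence. Running the full chain on the
default conditions (3,000 loci, $F = 0.15$, n = 20/35) leaves roughly
550–600 candidates after the position window, and the top-342 panel then
spans $\theta$ from ~0.8 down to ~0.05. Simulated performance on that
panel — min confusion diagonal ~0.92–0.95, F1/F2 power at the 0.9
threshold ~0.76–0.89 — sits a few points below the figures reported for
real panels of comparable size, whose loci are drawn from a much larger
and more divergent pool. The same pipeline at 10,000 synthetic loci
reaches ≥ 0.99 on every diagonal, which is the cleanest evidence that the
gap is a property of the synthetic pool, not of the method. Since the
evaluation cohorts are simulated from the same smoothed frequencies the
classifier uses, the plug-in assigner is Bayes-optimal for the generating
model, and no implementation change can close the gap at those
conditions.

## Hybrid-class simulation

`simulate_class_individuals()` performs explicit pedigree crossing per
individual: parents are drawn from Hardy–Weinberg equilibrium at the
reference frequencies (by default the same smoothed point estimates the
assigner uses), F1 = pure0 × pure1, F2 = F1 × F1, backcrosses = F1 × pure,
and gametes segregate independently per locus. Independence is justified
because the panel is linkage-pruned; recombination machinery along
chromosomes is intentionally not reproduced, so the simulator cannot
produce the correlated ancestry blocks that physically linked markers
would show. Later generations (B3+) and selfing are out of scope. Whether
the original simulations drew parents from observed reference genotypes or
from estimated frequencies is not stated in the sources we model; we chose
estimated frequencies, which makes the evaluation self-consistent with the
assignment model, and kept the raw (pseudocount-0) frequency route
available — empirically the difference on evaluation metrics is within
seed noise.

## Evaluation conventions

At threshold $t$ an individual is assigned iff its maximum posterior is
$\ge t$. Per class: accuracy = correct assignments / all assignments to
the class; efficiency = correct assignments / true class size; power =
accuracy × efficiency (an identity maintained to machine precision).
A class receiving no assignments at a high threshold has *undefined* (not
zero) accuracy; curves carry `NA` there. Type I error is the fraction of
known pure individuals max-assigned to any hybrid class; Type II the
mirror. The default threshold grid is 0.50–0.95 in steps of 0.05, and the
default evaluation cohort is 100 individuals per class, with 1,000 per
class used for the design-stage informativeness check — sizes chosen to
match how such panels are conventionally evaluated.

## Cohort analysis

`stock_composition()` turns max-posterior calls into per-year counts,
proportions, the hybrid fraction, and the advanced-hybrid share (F2 +
backcrosses among hybrids). Individuals with more than 25% missing
genotypes (strict inequality) are removed first. Within-year equality of
the six class proportions is tested with a Pearson goodness-of-fit
statistic (df = 5); across-year homogeneity of a single class with a
chi-square on the years × (class, not-class) table (df = years − 1). Both
tests also offer seeded Monte-Carlo p-values, because the source analyses
named Fisher-style exact tests while printing chi-square statistics; the
chi-square is the default report. Fork-length differences across assigned
classes use one-way ANOVA with Tukey HSD post-hoc comparisons.

## Reproducibility

Every stochastic function takes an explicit integer seed; `run_pipeline()`
derives per-stage seeds from one global seed and stamps them into its
artifacts, so a configuration reruns byte-identically. The permutation
G-test uses its own seeded generator in compiled code and is reproducible
across platforms.

## Known limitations

* Six classes only; no B3+, no admixture proportions, no lineage-sorting
  categories beyond generation 2.
* Biallelic SNPs only; multi-allelic records are skipped on input.
* The Gibbs sampler treats loci as independent given class and
  frequencies, like the plug-in mode; it adds frequency uncertainty, not
  linkage modelling.
* Synthetic calibration of "highly differentiated" is a tunable parameter
  of the generator, not a reproduction of any empirical panel (see the
  generator section above).
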