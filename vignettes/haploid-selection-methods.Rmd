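---
title: "Methods: comparing purifying selection between haploid- and diploid-expressed genes"
author: "hapsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing purifying selection between haploid- and diploid-expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsel)
```

## The scientific problem

The masking theory predicts that purifying selection is more efficient on
genes expressed in a haploid stage: a deleterious allele in a haploid cell is
always exposed to selection, while in a diploid cell a partially recessive
allele can hide in heterozygotes. Conifers offer a clean test system: the
megagametophyte, the maternally derived nutritive tissue of the seed, is a
long-lived haploid tissue, and genotyping it gives phased haploid genomes for
free. `hapsel` implements the complete inference chain for contrasting the
strength of purifying selection between genes specifically expressed in a
haploid tissue and genes specific to diploid tissues of the same trees:
variant QC with dual-ploidy paralog masking, 0-fold/4-fold degeneracy
annotation, the tau tissue-specificity index, nucleotide diversity with
invariant sites, folded site frequency spectra (fSFS), and a gamma
distribution of fitness effects (DFE) under a two-epoch demography, compared
across gene sets through the overlap of the fitted shape-parameter
distributions.

The pipeline operates on standard inputs (VCF with per-genotype GQ/DP and
invariant sites, FASTA + GFF3 gene models, a TSV expression matrix). Because
the raw capture data of the motivating study design are not shipped, a
synthetic-data module generates every input with known ground truth; all
statistical guarantees quoted below are verified by the test suite on those
synthetic data.

## Dual-ploidy paralog masking

Haploid tissue cannot be heterozygous. Collapsed paralogs - two diverged
gene copies mapped onto one reference locus - therefore betray themselves
when the same haploid reads are genotyped in diploid mode: both copies pile
up at one site and the caller reports heterozygotes. `detect_paralog_sites()`
flags every site with two or more heterozygous diploid-mode calls (missing
genotypes never count), and `build_mask()` surrounds each flagged site with
a 150-bp window, merged when windows overlap. The window is centred: the
site plus 75 bp on each side (151 positions in total). A one-sided window
would be an equally defensible reading of a "150-bp window around the SNP";
centring matches the "surrounding" semantics and is the convention adopted
here.

`apply_filters()` then processes the haploid-mode call in a fixed order:
mask removal, variant-type filters (indels, complex alleles, more than two
alleles), genotype-level masking at GQ > 20 and DP > 10 (strict: a genotype
with GQ = 20 or DP = 10 exactly is set missing), site-level missingness
(sites with more than 20% missing genotypes are dropped), and finally an
AN/AC recomputation from the surviving genotypes. The operation is
idempotent, and the test suite verifies AN/AC against brute-force recounts.

## Degeneracy, tau, and gene sets

A coding position is 4-fold degenerate when all three possible substitutions
are synonymous and 0-fold when none is; degeneracy is evaluated per position
with the standard genetic code rather than with a codon-family table, which
handles the irregular families (isoleucine, the serine split) uniformly.
Minus-strand genes are evaluated on the reverse complement, CDS fragments
are joined in translation order with the GFF phase honoured, and positions
covered by annotations that disagree are dropped. Only 0-fold (selected) and
4-fold (neutral proxy) positions are carried forward.

Tissue specificity uses the tau index over `N` tissues,

$$\tau = \frac{\sum_{i=1}^{N} (1 - x_i / \max x)}{N - 1},$$

which is 0 for uniform expression, 1 for single-tissue expression, and
invariant to rescaling. Genes with `tau >= 0.8` (inclusive) form the
per-tissue specific sets, assigned to their arg-max tissue; the `all_genes`
set keeps every gene. Two robustness subsets mirror the follow-up contrasts
usually run on such data: genes with tau strictly above the within-set
median, and genes with expression level up to and including the within-set
median. "Expression level" is defined here as the value in the assigned
(maximum) tissue; the alternative (mean across tissues) changes the subset
only for genes with uneven minor-tissue expression, and the max-tissue
definition is the one a tissue-specific contrast naturally conditions on.
When tissues carry replicate libraries they should be collapsed to
per-tissue means before tau, since the index is defined on one value per
tissue.

## Diversity with invariant sites and missing data

Per gene and per degeneracy class, nucleotide diversity is the ratio of sums

$$\pi = \frac{\sum_s AC_s\,(AN_s - AC_s)}{\sum_s \binom{AN_s}{2}}$$

over variant *and* invariant sites, where `AN` is the number of non-missing
alleles. Sites with `AN < 2` contribute nothing and nothing is renormalised
per site, so missing data down-weight a site instead of biasing the
estimate; the estimator equals exhaustive pairwise-difference averaging
(verified in the tests by exact comparison on random instances). The
per-gene `pi0/pi4` ratio is reported only for genes with both estimates
positive and at least 50 combined sites (configurable; small simulated
cohorts use a lower cut), and per-set summaries are means of per-gene ratios
with standard errors `SD/sqrt(N genes)`.

Watterson's theta and Tajima's D are computed from the fSFS downsampled to
16 alleles, with D reported as 0 and flagged when nothing segregates, so
that summary tables can always be laid out.

## Folded SFS construction

Sites monomorphic for the alternate allele (`AN = AC`) differ from the
reference assembly but are invariant within the cohort; their `AC` is set to
0 before SFS construction. Each retained site with `AN >= n` is then
independently downsampled without replacement to `n` alleles - a
hypergeometric draw of the alternate count, folded to the minor-allele count
(ties at `n/2` go to the shared central bin). With 20 haploid samples,
target sizes 16-20 correspond to tolerating 20% down to 0% missing
genotypes. The default of 200 replicate downsamplings per size mirrors the
resampling convention of SFS-based DFE studies; per-site independent
redraws keep replicates exchangeable, and each replicate seed derives from
one master seed. Bin sums are conserved across replicates at fixed `n` by
construction.

## The DFE engine

The 0-fold DFE is modelled as a gamma distribution of deleterious effects
(shape `beta`, mean magnitude `E(s)`), additive within diploids
(heterozygote effect `s/2`), with a two-epoch demography as nuisance: an
ancestral population at stationarity, rescaled to effective size
`ne1 = 100` (the customary rescaling of SFS-based DFE tools), switching to
relative size `nu = N2/N1` for `t2` generations.

Expected spectra come from the Poisson random field. For an epoch at
stationarity the expected density of segregating sites at population
frequency `x` under genic selection has Wright's closed form

$$f(x) \propto \frac{1 - e^{-2\gamma(1-x)}}{(1 - e^{-2\gamma})\,x(1-x)},
\qquad \gamma = N_e s,$$

which reduces to `1/x` neutrally. The sample expectation is obtained by
integrating `f` against the binomial sampling kernel with a composite
8-point Gauss-Legendre rule (geometric panels from `1e-9` to 0.1 covering
the boundary layer that strong selection creates near zero, linear panels
above). This evaluates the neutral folded spectrum to ~1e-8 relative error,
far inside the 1% engine tolerance the tests enforce. A discrete
Wright-Fisher transition grid of `2 * ne1 * nu` gene copies is used *only*
for the transient second epoch: the stationary density is discretised onto
the grid binomially, propagated `t2` generations towards the (rescaled)
post-change equilibrium, and projected to the sample hypergeometrically.
An all-grid engine was evaluated first and rejected: at a feasible grid size
its discrete-sampling bias in the singleton class (2% at 400 copies) exceeds
the neutral-limit tolerance, while the quadrature path is both exact at
stationarity and an order of magnitude faster.

Numerical conventions worth knowing:

* the transient grid snaps to multiples of 8 copies and `t2 > 16` to a
  geometric ladder of about 8% relative resolution, so likelihood searches
  revisit cached expectations; `t2 >= 2 * (2 ne1 nu)` is treated as fully
  re-equilibrated;
* the likelihood is an independent Poisson per folded bin, bin 0 included
  (bin 0 is the site total minus the expected segregating mass);
* the neutral fit profiles the mutational scale out in closed form (the
  Poisson MLE is `S / sum(phi)` because the bins sum to the fixed site
  total), locates `(nu, t2)` on a coarse grid and polishes by Nelder-Mead;
  a tie-break of a few hundredths of a log-likelihood unit pulls plateaued
  fits towards the stationary model, making the reported nuisance
  parameters deterministic without influencing any genuinely informative
  comparison;
* the gamma DFE is integrated over 64 geometric classes of `Nes` spanning
  `1e-4` to `1e4` plus an explicitly neutral class for the sub-grid tail;
  mass above the top class is invisible in the SFS and correctly ends up in
  bin 0;
* the selected fit starts from the conventional initial values
  (`beta = 0.5`, `E(s) = 0.1`, `t2 = 50` generations for the neutral fit)
  with jittered restarts under a fixed seed, so fits are deterministic.

One design decision deserves emphasis. With folded data at `n = 16`, a
fully free 0-fold mutational scale creates a likelihood ridge between
`beta`, `E(s)` and the scale: simulation showed the median recovered shape
drifting by up to a factor of two at weak selection. The 0-fold and 4-fold
sites of a gene share a mutation rate, so by default the selected-class
scale is tied to the fitted neutral per-site rate times the number of
0-fold sites (`tie_scale = TRUE`, with a `mu_ratio` knob for unequal
rates); this restores identifiability, and the recovery tests (median shape
within 30% of truth over the full `beta x Nes` grid at 100,000 sites) pass
with margin. The free-scale variant remains available.

Fitted DFEs are summarised as gamma mass over the conventional scaled
classes `Nes` in {0-1, 1-10, 10-100, >100}, scaled by the most recent
epoch's effective size (`ne1 * nu`); the ancestral size is an equally
defensible choice and changes only the labelling of the class boundaries,
not the fitted distribution.

## Comparing gene sets

Per gene set, each SFS replicate gets its own demography and DFE fit
(refitting the demography per replicate propagates its uncertainty into the
spread of the shape parameter). The distributions of the fitted shape
across replicates are compared pairwise with a kernel-density overlap: both
samples are smoothed with a common Silverman bandwidth computed on the
pooled sample, evaluated on a shared 512-point grid extended three
bandwidths beyond the pooled range, renormalised, and the overlap is the
trapezoid integral of the pointwise minimum, in percent. The statistic is
symmetric and bounded by construction; on unit normals two means apart it
reproduces the closed form `2*Phi(-1) = 31.7%` within Monte-Carlo error.
Non-converged replicates are excluded before the overlap, with counts
reported.

## What the synthetic data do and do not emulate

The generator reproduces the *structure* of the study design: 20 haploid
samples from one panmictic population, per-genotype GQ/DP (shifted-Poisson
and negative-binomial; the study reports no empirical distributions, so
these families are conventions, not estimates), independent missingness up
to 20%, collapsed paralogs injected as diverged duplicate copies that are
heterozygous in diploid-mode calls, a five-tissue expression matrix (one
haploid tissue first) whose tau values are hit exactly by construction,
0-fold coding positions segregating under the ground-truth gamma DFE (so
the diversity ratio and the fitted DFE have a known answer) while all other
positions are neutral, and fSFS pairs Poisson-distributed around the
engine's expectation under a known gamma DFE and two-epoch demography. Default parameters are the study
conditions where stated (20 samples, theta 0.005 - also the variant-caller
prior -, tau threshold 0.8, filters GQ > 20 / DP > 10 / 20% missing, 150-bp
windows, 200 resamplings to 16-20 alleles, DFE initials) and documented
conventions elsewhere.

It does **not** emulate read-level artefacts (mapping error, base-quality
correlation), linkage (sites are exchangeable given the frequency
spectrum), selection on linked sites (background selection enters real
diversity data but not the generator), population structure, or codon usage
bias (GC content of simulated genes hovers near 50%). Passing tests
therefore demonstrate correctness of the *inference machinery* under the
stated model, not robustness of the biology to those unmodelled features.

## Problem sizes used by the checks

The test suite and the acceptance script run at desk scale, chosen once:
cohorts of 20-24 genes for pipeline-level checks, 100,000 sites per class
and 20 stochastic replicates per setting for DFE recovery, 200 replicates
for the resampling and Tajima's D calibration checks, and a 120-gene cohort
with 8 DFE replicates per gene set in the acceptance run. The methods are
size-agnostic; these numbers keep a complete verification run comfortably
on one CPU.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_samples = 20, n_genes = 120, gene_length = 450,
                  flank = 30, seed = 1)
truth <- ground_truth(cfg, beta = 0.5, Es = 0.1)
res <- run_pipeline(cfg, truth = truth, dfe_reps = 8, min_sites = 30,
                    gene_sets = c("megagametophyte", "bud", "all_genes"))
res$summary_table
res$beta_overlap
```

## Known limitations

* Folded spectra only; no ancestral-state polarisation (deliberate - the
  motivating design lacks a reliable outgroup), hence no estimate of the
  adaptive fraction.
* Additivity is assumed throughout the DFE; dominance would change the
  diploid-set DFEs and is exactly the effect the haploid/diploid contrast
  is designed to expose, not something the engine corrects for.
* The demographic nuisance is a single size change; more elaborate
  histories are absorbed only approximately.
* `detect_paralog_sites()` needs the duplicate copies to diverge; identical
  collapsed copies are invisible to the dual-ploidy signal (as they are to
  the original approach).
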