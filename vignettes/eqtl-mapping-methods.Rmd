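---
title: "Methods: eQTL mapping in experimental backcrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL mapping in experimental backcrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the numerical choices
and the simulation design behind `eqtlcross`, in the spirit of the
methods sections of the established expression-analysis packages. It
states no empirical result beyond what the package's tests and the
`scripts/acceptance.R` run themselves compute.

## Study design and data flow

The package addresses genetical-genomics studies in livestock
backcrosses: a BC1 animal is the offspring of an F1 boar and a
purebred sow, so it carries on average 25% of the sire-breed genome,
all of it on the paternal haplotype. Expression of a candidate-gene
panel is measured by real-time qPCR; genotypes come from a genome-wide
SNP panel. The pipeline is

raw Cq → relative quantities → NQ → (log2 where needed) →
sex/backcross screening → mixed-model genome scans → eSNPs → eQTL
intervals → cis/trans labels and hotspots → imprinting test →
co-expression network.

## qPCR quantification

For each assay, the standard curve is the least-squares line of Cq on
log10(relative quantity) over a dilution series (≥ 3 points). The
amplification efficiency is `E = 10^(-1/slope) - 1`; a slope of
−3.3219 corresponds to perfect doubling (E = 1). Unknowns are
interpolated as `10^((Cq - intercept)/slope)` and technical replicates
averaged on the quantity scale.

Reference-gene stability uses the geNorm idea reduced to its core: the
stability value *M* of a candidate is the mean, over the other
candidates, of the per-sample SD of the pairwise log2 quantity ratio.
The `n_refs` (default 2) most stable candidates normalize the targets:
NQ is the target quantity over the geometric mean of the selected
references. NQ is defined only up to a per-gene multiplicative
constant — the dilution series fixes relative, not absolute, scale —
which cancels in every downstream test (correlations, F-tests, R²,
mixed-model p-values are all scale-free in this sense).

Normality is assessed per gene by the Shapiro–Wilk test at α = 0.05;
failing genes are log2-transformed wholesale, and the per-gene flag
travels with the expression matrix. A constant gene leaves the test
undefined; such genes are flagged with a warning and left untouched
rather than transformed.

## Sex and genetic-background screening

The screening model is the additive two-factor linear model
`value ~ sex + backcross` with no interaction; each factor is tested
by the marginal (type-II) F-test obtained by comparing against the
model without that factor. The F statistic is computed directly from
the two residual sums of squares and clamped at zero, so a response
that is exactly orthogonal to a factor yields F = 0 and p = 1 rather
than a 0/0. With a single cohort the model reduces to `value ~ sex`,
whose F equals the square of the pooled t statistic. Stars follow the
conventional 0.05/0.01/0.001 thresholds.

## The kinship mixed model

Relatedness is summarized by the genomic relationship matrix built
from mean-imputed, allele-frequency-centered dosages, scaled by
`sum(2 p (1 - p))` (VanRaden's first method). This scaling puts
entries on the familiar relatedness scale (self ≈ 1, full sibs ≈ ½).
Scale is irrelevant to inference — it is absorbed by the variance
ratio — so this choice is purely for interpretability. The matrix is
symmetrized and its eigenvalues clipped at zero; a matrix with
eigenvalues below −1e−8 (relative) is rejected.

Each gene is scanned with

y = Wα + xβ + u + ε, u ~ N(0, σ²_g K), ε ~ N(0, σ²_e I),

where W holds intercept, sex, and backcross dummies (sex only in
single-cohort mode). With K = U D Uᵀ computed once per scan, rotating
by Uᵀ turns the covariance into σ²_e (λD + I) with λ = σ²_g/σ²_e. The
per-SNP profile likelihood over λ is maximized on the bracket
[1e−5, 1e5]:

1. a 41-point log-spaced grid is evaluated for **all SNPs at once** —
   for each grid λ, the covariates are QR-residualized out of the
   weighted data and every SNP's GLS fit follows from two column sums;
2. Brent's method (tol 1e−6 on log λ) refines within the two grid
   intervals flanking each SNP's best grid point, with the bracket
   endpoints kept as candidates when the grid optimum is terminal.

The grid-then-refine initialization was chosen over warm-starting from
the null-model ratio: it cannot be trapped when a SNP's optimum is far
from the null ratio, and the vectorized grid makes it faster in R than
per-SNP warm starts. The Wald statistic β̂²/se² is referred to χ²₁,
with σ̂² = RSS/n under ML.

**A boundary ridge of the ML profile.** The centered GRM always has
the constant vector in its null space, and the intercept fits that
rotated coordinate exactly. As a consequence the plain ML profile
gains a slow `½ log λ` ridge toward the upper bracket; when the
genetic fraction of variance is high this ridge (capped by the
bracket) attracts the estimate to λ = 1e5, and on rare null datasets
an individual SNP can escape upward. The bounded bracket keeps the
statistic finite and type-I error calibrated (verified by simulation
in the test suite), and ML remains the default. `scan_gene(...,
likelihood = "REML")` offers the restricted likelihood, whose
`−log|XᵀV⁻¹X|` term cancels the ridge exactly; REML is also the
convention GEMMA uses for its Wald test. Under K ∝ I both variants
reduce to ordinary least squares for every λ, which the tests exploit
as an exact oracle.

Missing dosages are mean-imputed per SNP both in the GRM and at scan
time, and SNPs exceeding 5% missingness at scan time are skipped with
a warning. QC beforehand keeps SNPs with MAF ≥ 0.05 and missingness
≤ 0.05 (both bounds inclusive).

Multiple testing is controlled per scan by Benjamini–Hochberg
q-values, implemented from the step-up definition
`q(i) = min_{j≥i} p(j)·m/j` and verified against `p.adjust` in the
tests; Storey's π₀-scaled variant is available. Variance explained by
a single SNP is the partial R²,
`(RSS_reduced − RSS_full)/RSS_reduced`, i.e. relative to
covariate-adjusted expression variance.

## Intervals, labels, hotspots

eSNPs are SNPs with q strictly below 0.05 (0.10 is the customary
suggestive tier). Per gene and chromosome, sorted eSNPs belong to one
interval while consecutive gaps are < 10 Mb; a gap of exactly 10 Mb
splits. Interval size is `end − start` in bp — the convention that
reproduces published interval tables, and the one degenerate case
(a two-SNP interval at a single position) has size 0. Merging precedes
the SNP-count filter (≥ 2 SNPs joint, ≥ 3 single-cohort), so the
filter sees true member counts. A member SNP is *cis* when it lies on
the target gene's chromosome within 1 Mb of the nearest gene edge
(distance 0 inside the gene, bound inclusive); interval labels are
cis / trans / cis-trans by whether all, none, or some members are cis.
Annotation windows widen intervals by 1 Mb per side, floored at
position 1.

Hotspots are connected components of the per-chromosome overlap graph
of trans-labelled intervals (closed-interval overlap: at least one
shared base pair; an adjacency tolerance is configurable, default 0)
that target at least two distinct genes; the hotspot span is the
component union, which is contiguous by construction. Mixed cis/trans
intervals can be included via the `labels` argument; the default
follows the strict trans reading.

## Parent-of-origin analysis

At a biallelic focal SNP, homozygous offspring resolve trivially. A
heterozygous offspring resolves when the sire is homozygous (paternal
allele = sire's allele) or, failing that, when the dam is homozygous
(paternal allele = the allele the dam cannot have given);
double-heterozygous trios remain ambiguous — no grandparental phasing
is attempted, mirroring the attrition such studies report. Offspring
carrying an allele absent from both typed parents are flagged as
Mendelian errors and excluded. The deduction is checked exhaustively
against transmission enumeration and against the simulator's stored
phase.

The imprinting test fits a one-way model on the four ordered
genotypes; the primary contrast averages the paternal-A groups against
the paternal-G groups, with its t-based p-value reported. The compact
letter display derives from pairwise Welch tests at 0.05, unadjusted —
the display is descriptive, matching how such figures are annotated.
An AIC comparison of the paternal-indicator model against the additive
dosage model is reported alongside, since a purely additive effect
leaves the two heterozygote classes indistinguishable.

## PCIT network

For every gene trio (x, y, z), first-order partial correlations are
computed; the trio tolerance ε is the mean of the three
partial-to-direct ratios, and the x–y edge is flagged when
`|r_xy| < |ε·r_xz|` and `|r_xy| < |ε·r_yz|`. An edge is kept iff no
trio flags it. Trios containing a perfect correlation have undefined
partials and are skipped with a warning. One behavioural subtlety
worth knowing: the flag requires *both* inequalities, so an edge whose
partial correlation is exactly zero is still retained when its direct
correlation is strong relative to ε times the explaining legs (e.g.
r = 0.81 explained by two 0.9 legs survives, while 0.25 explained by
two 0.5 legs is removed). Displayed edges additionally satisfy
|r| ≥ 0.6 in magnitude with the sign preserved, and isolated nodes are
dropped; it is this displayed network that separates block structure
cleanly, and the raw-filter and displayed-network behaviours are both
pinned down in the tests. The threshold applies to the raw Pearson
correlation, not the partial.

## The synthetic-data generator

`simulate_population()` emulates the three-backcross design: a few
purebred sires, per-cohort F1 males, and BC1 offspring of F1 males
with unique purebred dams. Founder allele frequencies are drawn per
breed from configurable Beta distributions (default uniform), so
breeds differ and some loci segregate in only a subset of cohorts;
planted loci can pin per-breed frequencies (e.g. 0.9 in the sire
breed vs 0.1 in the dam breeds, a strongly breed-divergent causal
region). Meiosis follows a uniform 1 cM/Mb map with Poisson crossover
counts and uniform positions (Haldane, no interference); the package
tracks full phase, so the paternal haplotype of every BC1 animal — and
hence imprinting ground truth and the sire-breed genome fraction — is
known exactly.

Expression is generated on the natural-log scale as gene mean + sex
shift + cohort shift + planted SNP effects + block factors + polygenic
term + residual, then exponentiated; planted additive effects act
through a causal locus that is either a directly genotyped SNP
(`scope = "focal"`) or the mean dosage of a small cluster of adjacent
markers (an untyped regulator tagged by its neighbours), and imprinted
effects act through the indicator of a paternally inherited counted
allele. Effect sizes are solved from requested variance fractions
(PVE) against the **covariate-residualized** predictor variance, and
the non-SNP components (block factors, polygenic term, residual) are
constructed orthogonal to each gene's planted predictors and to the
sex/cohort design, each scaled to its exact target SD. Requested PVEs
are therefore realized exactly in-sample, so parameter-recovery tests
measure estimator error, not generator Monte Carlo noise. The default
co-expression block uses a shared latent factor at variance fraction
0.7, i.e. within-block correlations around 0.7 — strong enough to
survive the |r| ≥ 0.6 display filter, as the lipogenic clusters such
studies report do.

The qPCR layer draws per-assay efficiencies in (0.9, 1.05] and curve
intercepts in Cq units, applies a shared per-sample loading factor
(what reference normalization removes), adds Gaussian technical noise
(default SD 0.15 Cq), and emits five-point four-fold dilution
standards per assay, plus two stable reference assays and one
deliberately unstable pseudo-reference that the stability screen
should discard.

What the generator does **not** emulate: founder-haplotype linkage
disequilibrium (LD arises only from the cross design and breed
divergence, so local marker correlation is far weaker than on a real
dense panel — planted multi-SNP clusters stand in for that density),
selection, X-chromosome dosage, genotyping error, and plate/batch
structure in the qPCR layer. Passing recovery tests therefore
demonstrates correctness of the estimators under the cross design, not
robustness to every artefact of real data.

## Problem sizes

The default `desk` profile (3 × 60 animals, 3 chromosomes × 500 SNPs,
12 genes) keeps a full pipeline run near a minute and is what the
examples use. The test suite's recovery studies use 355 animals with
reduced SNP panels (120–200 markers over two or three chromosomes) and
3 × 40–50 animals for the imprinting and hotspot replicates — sizes
chosen so that 100–200 replicate studies remain comfortable on one
core while keeping the statistical questions (power at PVE 0.70,
interval geometry, hotspot overlap) at the scale of the emulated
study. The `full` profile mirrors the emulated study's dimensions
(114/122/119 animals, 18 autosomes, 38,426 SNPs) and runs a single
gene scan on a desk machine.

## Known limitations

* The NQ scale is defined up to a per-gene constant; absolute
  expression levels between genes are not comparable.
* The ML boundary ridge described above means per-SNP λ estimates at
  1e5 should be read as "predominantly genetic", not as point
  estimates; use REML where λ itself is of interest.
* Cross-platform genotype harmonization is out of scope: the package
  expects one pre-harmonized SNP panel.
* The interval filter and the 10 Mb merge rule are heuristics
  inherited from the study design the package emulates; both constants
  are arguments, not assumptions.
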