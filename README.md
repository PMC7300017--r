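# eqtlcross

Expression QTL mapping for experimental livestock backcrosses, from raw
qPCR fluorescence summaries to annotated eQTL intervals, trans-eQTL
hotspots, parent-of-origin tests and co-expression networks.

The package targets the *genetical genomics* design used in pig
resource populations: a small panel of candidate genes (here,
lipid-metabolism genes in muscle) measured by real-time qPCR across
several hundred animals from backcross cohorts (BC1 = F1 boar x
purebred sow, 25% sire-breed genome), genotyped on a genome-wide SNP
panel. It provides every computational stage of such a study:

* **qPCR quantification** — relative standard curve method: per assay a
  least-squares line of Cq on log10(quantity) gives the PCR efficiency
  `E = 10^(-1/slope) - 1`; unknowns are interpolated, technical
  replicates averaged on the quantity scale, candidate reference genes
  ranked by a geNorm-style stability value *M*, and the normalized
  quantity (NQ) is the target quantity over the geometric mean of the
  selected stable references. Genes failing a Shapiro–Wilk normality
  check (p < 0.05) are log2-transformed.
* **Fixed-effect screening** — per-gene means ± SEM by sex and cohort
  with marginal F-tests from the additive model `NQ ~ sex + backcross`.
* **Kinship-aware association scans** — per gene, the linear mixed
  model `y = Wα + xβ + u + ε`, `u ~ N(0, σ²_g K)`, with `K` the
  VanRaden centered genomic relationship matrix. `K` is
  eigendecomposed once; the per-SNP variance ratio `λ = σ²_g/σ²_e` is
  maximized by bounded search on `[1e-5, 1e5]` (log-scale grid plus
  Brent refinement, ML by default, REML available); each SNP gets a
  Wald test `β̂²/se² ~ χ²₁`, Benjamini–Hochberg q-values per scan, and
  a partial-R² variance-explained (PVE) estimate.
* **eQTL intervals** — significant eSNPs (q < 0.05) on a chromosome are
  merged while consecutive SNPs are < 10 Mb apart; intervals with ≥ 2
  SNPs (joint analysis; ≥ 3 for single-cohort scans) are kept, labelled
  *cis* (every member SNP within 1 Mb of the target gene), *trans*, or
  *cis/trans*, and widened by ±1 Mb for annotation export.
* **Hotspots** — overlapping trans intervals that regulate ≥ 2 distinct
  genes form a hotspot (connected components of the per-chromosome
  overlap graph).
* **Imprinting** — the paternal allele at a focal SNP is deduced from
  trio genotypes (homozygous offspring trivially; heterozygotes via a
  homozygous parent; double-heterozygous trios stay ambiguous), and a
  paternal-expression model contrasts paternal-A against paternal-G
  ordered genotypes with a compact letter display.
* **PCIT co-expression networks** — every gene trio's first-order
  partial correlations set a data-driven tolerance ε; an edge survives
  only if no trio flags it, and displayed edges additionally satisfy
  |r| ≥ 0.6 (sign preserved). Networks are exported as edge-list TSV
  and GraphML.
* **Synthetic three-backcross studies** — `simulate_study()` generates
  pedigreed cohorts (founder breeds with per-breed Beta allele
  frequencies, Haldane meiosis at 1 cM/Mb, full phase tracking),
  plants cis/trans/imprinted effects with exactly realized variance
  fractions, adds co-expression blocks, and emits raw Cq tables with
  dilution-series standards — plus a machine-readable truth file, so
  every stage above can be tested by parameter recovery.

Standard formats are supported throughout: PLINK `.ped/.map`, VCF 4.x
(via `vcfR`), and TSV for expression, pedigree, gene positions, Cq
tables and all result tables.

## Worked example

```r
library(eqtlcross)

cfg <- sim_config(profile = "desk", seed = 42)   # 3 x 60 animals, 1500 SNPs
st  <- simulate_study(cfg)                        # genotypes + raw qPCR

qp <- qpcr_quantify_study(st$qpcr$cq,
                          reference_candidates = c("REFA", "REFB", "REFU"))
qp$stability
#>   assay         M
#> 1  REFA 0.4470558
#> 2  REFB 0.4502324
#> 3  REFU 0.7314921          # the unstable pseudo-reference is discarded

pop   <- st$population
study <- eqtl_study(qp$expression, pop$pedigree, pop$genotypes,
                    pop$map, pop$genes)
study
#> eQTL study (3BCs mode): 12 gene scans, 37 eSNPs (q < 0.05), 7 intervals, 1 hotspots

study$intervals[, c("gene", "chr", "start_bp", "end_bp", "n_snps", "label", "top_pve")]
#>  gene chr  start_bp    end_bp n_snps     label   top_pve
#>   G01   2   8596140  23933063      5 cis/trans 0.4904285
#>   G03   1  16268784  17888178      3     trans 0.1007677
#>   ...
study$hotspots
#>  chr span_start span_end n_genes           genes n_intervals
#>    1   23119244 40609994       4 G03,G04,G05,G06           4
```

The imprinted cis-eQTL planted on gene `G01` is recovered as the
`cis/trans` interval on chromosome 2 (its top SNP explains ~49% of the
measured expression variance through allele dosage; the deduced
paternal allele explains ~68%, close to the planted 70%), and the
shared trans-regulator planted for `G03`–`G06` surfaces as the
chromosome 1 hotspot carrying all four genes.

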