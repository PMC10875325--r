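---
title: "Methods: mitonuclear linkage-disequilibrium analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitonuclear linkage-disequilibrium analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitolink` scans for statistical associations between mitochondrial variants
and nuclear SNPs within a species. This vignette is the package's account of
the underlying models, the parameters that matter, the numerical choices, and
what the synthetic validation does and does not establish.

## 1. The heteroplasmy phenotype

Plant mitochondria are highly polyploid within a cell, so a mitochondrial
variant is not a diploid genotype but a *fraction*: at site $s$ in individual
$i$, the phenotype is the reference-allele read fraction

$$y_{is} = \frac{\text{reads supporting the reference allele}}
                {\text{total reads at } s},\qquad y_{is}\in[0,1],$$

computed from the VCF `AD` field after filtering. Zero-coverage or masked
observations are missing (`NA`), never zero — a zero would fabricate a
measured allele frequency of 0. An optional binary recoding maps
$y < 0.05 \mapsto 0$, $y > 0.95 \mapsto 1$ and everything else (genuinely
heteroplasmic individuals) to missing; the same thresholds define the
heteroplasmy classification (`exclusively_heteroplasmic_alt` for variants
whose alternative allele is seen but never reaches a homoplasmic state),
because raw read ratios are never exactly 0 or 1 at finite depth and the
operational meaning of "homoplasmic" therefore needs a tolerance; reusing
the binarization bounds keeps one pair of thresholds for both purposes.

## 2. Mitochondrial variant filtering

False mitochondrial variants arise mainly from reads that cross-map between
repeated tracts of the mitochondrial genome or between the mitochondrial
genome and nuclear insertions of mitochondrial DNA (numts). The filter
cascade, in order:

1. **Biallelic / missingness** — multi-allelic sites removed; sites with
   more than `max_missing = 0.40` missing genotype calls removed (boundary
   inclusive: exactly 40% is retained).
2. **Depth** — sites whose mean sample depth exceeds
   `depth_factor = 1.5` times the genome-wide average are removed (a
   multi-copy symptom); per-sample observations with fewer than
   `min_reads = 4` reads are set missing, after which the missingness rule
   is re-checked.
3. **Region masks** — sites inside exact repeated tracts
   ($\ge$ `min_homology = 100` bp, either strand) of the mitochondrial
   reference, or inside tracts shared ($\ge$ 100 bp) with the nuclear or
   plastid genome, are removed. A user BED adds further masks.

Every removal is attributed to the first filter that caught the site, and the
report conserves counts (removed + kept = input).

Two interpretation choices are documented here because the procedure can be
read in more than one way:

* *Genome-wide average depth* is computed as the mean over called sites of
  the per-site mean sample depth — a VCF carries no per-base genome
  coverage. A precomputed genome mean can be supplied instead
  (`genome_mean`), which also makes a re-run of the cascade on its own
  output exactly stable.
* *The 4-read rule* is applied per sample-observation (set missing), not per
  site: the phenotype is per-sample, and at ~100x depth a site-level sum
  would essentially never bind.
* *Repeat/homology detection* uses exact maximal matches found by k-mer
  identity with $k$ equal to the length threshold: a position lies in a
  repeat of length $\ge k$ exactly when one of its covering $k$-windows
  occurs elsewhere, so the union of duplicated windows equals the union of
  maximal repeats. This is deterministic and dependency-free; scored,
  mismatch-tolerant homology (as a BLAST-style search would report) is out
  of scope, and a user-supplied BED can stand in where that matters. The
  detector is quadratic-memory-free but holds all windows in memory, which
  is fine for organelle-scale genomes (hundreds of kb), not for full nuclear
  chromosomes.

## 3. The kinship mixed model

Population structure induces spurious mitonuclear associations: both the
mitochondrial haplotype and nuclear allele frequencies track subpopulation
membership. The engine therefore fits, per mitochondrial phenotype,

$$y = X\beta + u + e,\qquad u \sim N(0, \sigma_g^2 K),\qquad
  e \sim N(0, \sigma_e^2 I),$$

with $K$ the identity-by-state kinship
$K_{ij} = 1 - \tfrac{1}{2m}\sum_s |g_{is} - g_{js}|$ over filtered SNPs
(per-SNP mean imputation of missing dosages), the convention of the standard
EMMAX kinship tool; a centered (VanRaden) relationship matrix is available
behind `method = "centered"`. The IBS sum is evaluated with a
genotype-category indicator decomposition, turning the $O(n^2 m)$ loop into
a handful of BLAS products (seconds at $n = 300$, $m = 5{,}000$).

Variance components are estimated by REML, profiled over
$\delta = \sigma_e^2/\sigma_g^2$: one eigendecomposition of $S K S$ (with $S$
the residual maker of $X$) reduces the restricted likelihood to a scalar
function of $\delta$, maximized on a 100-point grid over
$\log_{10}\delta \in [-5, 5]$ with local refinement; grid-edge optima are
flagged (`boundary`), which is the expected outcome for a trait with no
genetic component. Each nuclear SNP is then tested under the **EMMAX
approximation**: variance components fixed at the null fit, one rotation by
$\Sigma^{-1/2}$, and an added-regressor test per SNP — a two-sided $t$ with
$n - q - 1$ degrees of freedom (documented so exact p-values are
reproducible; no asymptotic normal). Missing genotypes are mean-imputed per
SNP; SNPs with no residual genotype variance are reported as skipped. No
covariates beyond the intercept and no principal components are used — the
kinship term is the stratification control. The same linear model is applied
to continuous, binarized and indel-derived phenotypes alike; with only the
kinship as covariate structure this is the pragmatic choice, and the binary
re-analysis is a robustness check, not a separate model.

Nuclear SNPs enter the scan after their own filter: missingness > 40% or
MAF < 0.05 removed (strict inequalities).

## 4. Signals, genes, enrichment

A **signal** is a run of SNPs with $-\log_{10}(p) > 6$ (strictly greater;
the threshold exceeds a Bonferroni-style bound on the effective number of
independent SNPs in typical panels), spanned by its left- and right-most
members. The definition fixes a signal's span but not when two
above-threshold runs are distinct; `max_gap` (default 1 Mb) makes that
explicit — above-threshold SNPs separated by more than `max_gap` start a new
signal. Both behaviors discussed for the summary counts (merge vs. split)
are reachable through this one parameter. Genes are attached by whole-gene
interval overlap with the signal span (genes encompassed by the peak, not
exon-level overlap), the lead SNP is the member with minimal p (ties to the
smaller position), and its host gene is flagged as the primary candidate.
Per-dataset summaries report de-duplicated gene counts and their percentage
of the annotated gene universe. Term enrichment is a one-sided
hypergeometric upper tail per term with Benjamini-Hochberg adjustment; term
databases are external inputs (a plain gene-to-term table), not shipped.

## 5. Diversity and Ka/Ks contrasts

Windowed nucleotide diversity follows vcftools `--window-pi` semantics:
per-site $\pi_s = 2 c_0 c_1 / (n(n-1))$ over non-missing allele copies,
window value = sum of site values divided by the window length in bp
(monomorphic positions dilute), 100 kb windows sliding by 10 kb by default.
Gene-level diversity for the target/background contrast is, by default, the
mean of windows overlapping the gene span (switchable to site-level
aggregation within the gene; the window-to-gene mapping is a genuinely open
choice and both are provided). Group contrast is a two-sided Wilcoxon
rank-sum test, exact for combined $n \le 30$ without ties, normal
approximation with tie and continuity correction otherwise.

Ka/Ks uses the Nei-Gojobori (1986) counting estimator between a
majority-rule consensus CDS (ties keep the reference; length-changing
alleles are skipped with a warning, as they would shift the frame) and an
aligned outgroup CDS: synonymous site counts averaged over both sequences,
multi-hit codons classified by averaging over all substitution pathways
(orderings through premature stops excluded when any stop-free ordering
exists), Jukes-Cantor correction of both proportions, and an explicit
undefined flag when $K_s = 0$. NG86 was chosen over likelihood codon models
because it is fully specified by counting rules and therefore testable by
exhaustive enumeration; the GUI tools commonly used for this step offer
several estimators without a stated default.

## 6. RNA-editing detection

C-to-U editing appears in RNA-seq variant calls as C>T on the transcribed
strand: genomic C>T inside `+`-strand genes, genomic G>A inside `-`-strand
genes. The caller keeps sites that are (i) variant-called in **all**
biological replicates of a condition (presence in the per-replicate call
sets — 3 replicates by default), (ii) absent from matched whole-genome
sequencing calls (which would mark a genomic SNP), and (iii) of the correct
strand-aware substitution class; sites outside annotated genes have no
defined transcribed strand and are excluded. Sites are annotated as
CDS/intron/other, and CDS sites get a codon position computed on spliced
coordinates honouring GFF3 phase. Editing efficiency is edited reads over
covering reads, averaged unweighted across replicates; a site with zero
coverage in any replicate is flagged not-quantifiable. Differential editing
between conditions uses an absolute mean-difference threshold (default
0.10) rather than a formal test: with three replicates per condition a test
has essentially no power, so the decision rule is the effect size itself,
configurable and reported per site. Whether intron efficiencies should use
spliced or unspliced read support is not resolvable from variant tables
alone; the caller quantifies whatever read support the upstream caller
reported.

## 7. The synthetic study population

The generator reproduces the statistical structure the analysis assumes, at
the scale used throughout validation:

* **Panel**: 300 individuals in 3 equal subpopulations, Balding-Nichols
  subpopulation frequencies with $F_{st} = 0.3$ (crop panels are strongly
  structured; this is deliberately a hard case for stratification control),
  5,000 nuclear SNPs with ancestral MAF uniform on $[0.05, 0.5]$ and 2%
  missingness.
* **Phenotypes**: 20 mitochondrial variants; true fraction =
  $\mathrm{clip}(\mu + \beta g_{\text{causal}} + \text{polygenic} +
  \varepsilon,\,0,\,1)$ with $\mu = 0.5$, $\beta = 0.2$ per causal allele
  copy on one designated variant, a polygenic term with covariance
  proportional to the realized kinship scaled to contribute 50% of the
  non-causal variance (`heritability_background = 0.5`, a typical polygenic
  background; it is also what makes the identity-kinship scan inflate, so
  the correction is genuinely exercised), and $\varepsilon$ with
  `noise_sd = 0.05`. Clipping on the raw fraction scale mirrors the
  phenotype's definition as a read ratio; no logit transform.
* **Read counts**: depth $\sim$ Poisson(100) per site and individual (the
  resequencing panels this emulates average ~100-200x on the mitochondrial
  genome), reference reads binomial at the true fraction; depth 0 is a
  missing observation.
* **Causal SNP**: planted on the SNP nearest the panel midpoint with
  realized MAF $\ge 0.10$ and missingness $\le 0.20$
  (`choose_causal_snp()`). Under $F_{st} = 0.3$, drift can push a blindly
  indexed SNP below the MAF filter, which would make the recovery
  experiment vacuous — the planted condition is a *testable common* causal
  SNP.
* **Genomes**: random sequence with exact planted repeat pairs and a numt
  tract copied into a nuclear decoy; flanking bases are forced to mismatch
  so each planted tract is maximal by construction and the truth mask is
  exact. Variant positions avoid planted tracts (a caller would not report
  variants inside masked regions).
* **Editing data**: per-replicate binomial edited-read counts at planted
  strand-aware sites, plus four decoys that each exercise one exclusion
  rule (WGS-shared, non-C-to-U class, wrong strand, missing from one
  replicate).

What the generator does **not** emulate: linkage disequilibrium between
nuclear SNPs (SNPs are conditionally independent given the subpopulation),
sequencing error and strand bias, indel alleles, mapping artifacts beyond
the planted exact tracts, inexact (diverged) repeats, and selection. Passing
tests therefore establish the *statistical engine* — calibration under
stratification, recovery of a planted effect, exactness of the counting
estimators — not robustness to alignment pathology or LD-induced signal
smearing in real panels.

## 8. Numerical choices and degenerate inputs

* Intervals are handled as GRanges/IRanges (1-based inclusive) throughout —
  the R/Bioconductor convention; the 0-based half-open BED convention is
  confined to the BED reader/writer and covered by round-trip tests.
* REML: eigenvalues of the projected kinship clipped at 0; the kinship
  itself is symmetrized and negative eigenvalues (possible for IBS matrices)
  clipped at 0, with a warning beyond $-10^{-6}$; constant phenotypes,
  missing values, and non-PSD kinships are hard errors.
* p-values: computed as $2\,P(T > |t|)$ with underflow guarded; reported
  $-\log_{10}(p)$ uses the log-scale tail directly so extreme signals do not
  saturate.
* Wilcoxon: exactness switches off in the presence of ties.
* Filter cascade on empty tables returns empty reports rather than erroring
  (an all-removed first stage must not kill the run); an all-zero depth
  table is an error.
* Demo problem sizes: the `micro` preset (n = 120, 800 SNPs, 6 variants)
  is used in unit tests; the full study conditions (n = 300, 5,000 SNPs,
  20 variants; 50-seed recovery) run in the acceptance suite. These sizes
  keep every simulation comfortably in the seconds-to-a-couple-of-minutes
  range while leaving Monte-Carlo bands well separated from their
  thresholds.

## 9. Known limitations

* Exact-match repeat masking misses diverged repeats/numts; supply a BED
  from a scored aligner where this matters.
* The EMMAX approximation under-corrects for very large per-SNP effects
  (variance components are not re-estimated per SNP) — the standard
  trade-off of the approach it follows.
* One linear model serves continuous and binary phenotypes; no
  liability-scale model for the binary recoding.
* Signal counting depends on `max_gap`; summary counts are only comparable
  across runs with the same value.
* The differential-editing rule is an effect-size threshold, not a test;
  with more replicates a formal test would be preferable.
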