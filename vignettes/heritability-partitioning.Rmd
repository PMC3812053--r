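---
title: "GREML heritability, genomic partitioning, and genetic correlation for case-control traits"
author: "snpher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GREML heritability, genomic partitioning, and genetic correlation for case-control traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpher)
```

## The model

`snpher` estimates the proportion of variance in disease liability that is
captured jointly by genotyped SNPs, and partitions that estimate across
genomic strata. The underlying model is the standard GREML mixed model
(Yang et al. 2010, 2011): with standardized genotypes
$w_{ij} = (x_{ij} - 2p_i)/\sqrt{2p_i(1-p_i)}$, the phenotype is

$$ y = X\beta + g + e, \qquad g \sim N(0,\, \sigma^2_g A), \qquad
   e \sim N(0,\, \sigma^2_e I), $$

where $A$ is the genetic relationship matrix (GRM) with entries
$A_{jk} = \frac{1}{M}\sum_i w_{ij} w_{ik}$ (the diagonal uses GCTA's
inbreeding-adjusted form). Variance components are estimated by restricted
maximum likelihood with average-information (AI) updates, and
$h^2_{obs} = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$.

For a dichotomous trait analyzed on the observed 0/1 scale, $h^2_{obs}$ is
converted to the narrow-sense heritability of an underlying standard-normal
liability. Individuals are affected when liability exceeds
$T = \Phi^{-1}(1-K)$ for population prevalence $K$; with sample case
fraction $P$ and $z = \phi(T)$, the ascertainment-corrected transformation
(Lee et al. 2011) is

$$ h^2_{liab} = h^2_{obs} \cdot \frac{K^2(1-K)^2}{z^2\,P(1-P)}. $$

The factor does not depend on $h^2_{obs}$, so standard errors scale by the
same constant. At $K = P = 0.5$ it reduces to $\pi/2$; at $K = 0.008$ with
$P = 617/4733$ it is $\approx 1.156$.

Partitioned analyses split the SNP panel into disjoint strata (chromosome,
minor-allele-frequency bin, or annotation masks such as genic/eQTL
membership), build one GRM per stratum, and fit all components jointly:

$$ \mathrm{Var}(y) = \sum_j \sigma^2_{g_j} A_j + \sigma^2_e I . $$

Joint fitting is what makes the per-stratum attributions meaningful: any
overlap in signal between strata is resolved inside one likelihood rather
than double-counted across separate models. Shares of total are reported
against the summed genetic components of the same joint model.

The bivariate model stacks two traits measured on disjoint samples that
share a SNP panel. The genetic covariance enters through the cross-sample
GRM blocks; the residual covariance is structurally zero because no
individual carries both traits. The genetic correlation is
$r_g = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ with a delta-method
standard error from the inverse AI matrix. Because the liability transform
rescales both traits linearly, $r_g$ is the same on the observed and
liability scales.

Heritability can also be expressed as a sibling relative risk: relatives
sharing a fraction $a$ of additive variance have liability correlation
$\rho = a\,h^2_{liab}$, the recurrence risk is
$K_R = P(L_2 > T \mid L_1 > T)$ from the bivariate-normal upper orthant at
correlation $\rho$, and $\lambda = K_R/K$.

## Quality control

Variance-component models accumulate small per-SNP artifacts into large
global biases, so the package implements the stringent screens appropriate
for this analysis class, in a fixed order: SNP call rate and
monomorphism; differential case/control missingness (two-sided Fisher exact,
p < 0.05); Hardy-Weinberg exact test (p < 0.05; the exact conditional test
without mid-p correction, on the pooled sample by default — both pooled and
controls-only modes are available because published pipelines differ);
platform/batch association (per-SNP logistic regression of platform on
dosage plus ten GRM principal components, p < 0.001, with non-convergent or
separated fits treated as failures); sample call rate (>= 99.9%); and
greedy relatedness pruning at pi-hat > 0.05, operationalized on the GRM
off-diagonal (on unlinked common SNPs this coincides in expectation with
PLINK-style IBD estimates). `run_qc()` iterates the SNP- and sample-level
passes to a fixed point, so the recorded filters are self-consistent on the
final analysis set and a second invocation drops nothing. When batch
artifacts are so pervasive that the PCs themselves separate the platforms,
the platform scan falls back to the unadjusted regression with a warning
rather than failing every SNP.

## The synthetic-data generator

All validation is by parameter recovery on data the generator produces,
so what the generator does — and does not — emulate matters.

* **Genotypes** are biallelic, in Hardy-Weinberg equilibrium, and in
  linkage equilibrium, with allele frequencies drawn from a configurable
  spectrum supported on (0.001, 0.5]. The `maf_binned()` spectrum mirrors
  a GWAS array's occupancy of the six standard MAF bins
  (0.001–0.05, …, 0.4–0.5).
* **Causal effects** are drawn per partition on the standardized-genotype
  scale, i.e. with equal expected variance per causal SNP regardless of
  frequency (the implicit MAF coupling of the GRM estimator itself). The
  drawn vector is rescaled so each partition's summed squared effects equal
  its variance share exactly; each replicate's truth therefore equals the
  architecture's nominal values rather than a noisy draw around them.
* **Phenotypes** follow the liability-threshold model: liability is the
  genetic value plus an independent normal residual with total variance 1,
  and cases are individuals above $\Phi^{-1}(1-K)$. The population is
  generated in chunks (default 10,000 individuals, at most 100 chunks)
  until the case quota is met; controls are reservoir-sampled uniformly
  from the unaffected. Genotypes at non-causal SNPs are independent of the
  phenotype and are drawn only for the ascertained individuals — an exact
  shortcut, not an approximation.
* **Bivariate traits** share a causal set whose effect pairs come from a
  bivariate normal; the two raw draws are orthonormalized so the realized
  effect-vector correlation equals the preset $r_g$ exactly.
* **Platform artifacts** resample a random fraction of SNPs in one
  platform group at a shifted allele frequency, the artifact class the QC
  screens are designed to catch.

Shipped presets encode the architectures studied in the Tourette
Syndrome / obsessive-compulsive disorder heritability literature:
`TS_GLOBAL` (liability $h^2 = 0.58$ at $K = 0.008$), `OCD_GLOBAL`
(0.37 at 0.025), `OCD_EARLY` (0.43 at 0.025), MAF-profile presets with a
rare-bin (MAF 0.001–0.05) share of 21% (TS) or 0% (OCD), genic shares of
53% / 40%, and a bivariate preset with $r_g = 0.41$. Default causal counts
(500 for global presets, 60 per MAF bin, 250 per genic stratum) are chosen
so every partition is comfortably polygenic at a 5,000-SNP panel; recovery
is insensitive to this choice (checked at 500 vs 5,000 causal SNPs).

What the generator does **not** emulate: linkage disequilibrium,
population structure and demographic history, genotyping error beyond the
platform artifact, the X chromosome, and dominance or epistasis. Passing
recovery tests therefore validate the estimator chain under its own model
assumptions; they do not certify behavior under LD or stratification,
which real-data pipelines must address with the QC and PC machinery.

## Numerical choices

* **AI-REML.** Components start at $\sigma^2_p/(m+1)$; one EM warm-up step
  precedes AI (Newton-type) updates; steps are halved whenever they would
  leave the positive-definite cone or decrease the restricted likelihood.
  Convergence requires a log-likelihood change below $10^{-6}$ and a
  maximum relative parameter change below $10^{-8}$, within 100
  iterations. Components are floored at $10^{-6}\sigma^2_p$; boundary hits
  are flagged and reproduce the `0.000001 (se …)` style of estimates that
  null analyses produce. Standard errors come from the inverse AI matrix,
  heritabilities and shares via the delta method.
* **Single-GRM fast path.** With one GRM the model is fitted in the GRM's
  eigenbasis, making each iteration linear in $n$; eigendecomposition is
  also reused across phenotype permutations. The dense multi-GRM path and
  the eigen path maximize the same likelihood (tested to $10^{-6}$).
* **Likelihood-ratio tests.** A genetic variance tested at its zero
  boundary uses the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$,
  i.e. $p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})$; the plain $\chi^2_1$
  p-value is reported alongside because published analyses have used both
  conventions. The $r_g = 0$ test uses $\chi^2_1$ two-sided with the
  one-sided halving also reported.
* **Orthant probabilities** for sibling risk use adaptive quadrature on
  one margin (relative tolerance $10^{-10}$), checked against the
  $\arcsin$ closed form and Monte-Carlo sampling.
* **MAF bins** are half-open $(lo, hi]$; a MAF exactly on an edge falls in
  the lower bin; SNPs at or below the lowest edge (0.001) are excluded and
  reported. Empty bins warn and are dropped from the joint fit with a
  notice; bins with fewer than 50 SNPs warn but are fitted.
* **Allele frequencies** for GRM standardization are always computed on
  the analysis sample (cases and controls pooled), matching the default
  behavior of the field's reference implementation.

## Validation studies and their sizes

The package validates itself by recovery at a working size of $n = 2000$
individuals and $M = 5000$ independent SNPs with at least 10 replicates
per study — large enough that the GRM-based sampling error
($\mathrm{se}(h^2_{obs}) \approx \sqrt{2M}/n \approx 0.05$) leaves
replicate means accurate to $\approx 0.02$, and small enough that the full
battery runs in minutes on one core. Case fractions mirror the published
designs they emulate (e.g. 617/4733 for the TS-like configuration).

## Known limitations

* **Ascertainment attenuation of REML.** Under strong case-control
  enrichment, likelihood-based GREML on the 0/1 scale underestimates
  liability heritability even after the Lee transformation; moment-based
  estimators (Haseman-Elston / PCGC regression, Golan et al. 2014) do not
  share this bias. The effect grows with $h^2$, with enrichment $P/K$, and
  is visible in this package's own recovery studies: at the TS-like design
  ($h^2 = 0.58$, $K = 0.008$, $P \approx 0.13$) the REML chain recovers
  $\approx 0.51$–0.52 on average (about 11% low) while a Haseman-Elston
  cross-check on identical replicates recovers 0.58. Milder designs
  (e.g. $h^2 = 0.37$ at $K = 0.025$) are close to unbiased at this sample
  size. The package deliberately reports what the REML pipeline produces —
  that is the estimator whose behavior it documents; ratio quantities
  (partition shares, $r_g$) are essentially unaffected because the
  attenuation cancels.
* Genetic-correlation estimates at $n_1 = n_2 = 1000$ carry large standard
  errors (0.15–0.3 per replicate); replicate means are correspondingly
  noisy.
* The QC platform scan tests one SNP at a time; it is not a substitute for
  ancestry matching, which is assumed to have happened upstream.
* No support for dosage/imputation formats, X chromosome, LD-aware or
  dominance GRMs, or more than two traits in the bivariate model.

## References

* Yang J, Benyamin B, et al. (2010) Common SNPs explain a large proportion
  of the heritability for human height. *Nat Genet* 42:565–569.
* Yang J, Lee SH, Goddard ME, Visscher PM (2011) GCTA: a tool for
  genome-wide complex trait analysis. *Am J Hum Genet* 88:76–82.
* Lee SH, Wray NR, Goddard ME, Visscher PM (2011) Estimating missing
  heritability for disease from genome-wide association studies.
  *Am J Hum Genet* 88:294–305.
* Golan D, Lander ES, Rosset S (2014) Measuring missing heritability:
  inferring the contribution of common variants. *PNAS* 111:E5272–E5281.
* Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact tests of
  Hardy-Weinberg equilibrium. *Am J Hum Genet* 76:887–893.
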