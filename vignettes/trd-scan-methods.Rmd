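---
title: "Scanning for maternal transmission ratio distortion with ungenotyped sires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for maternal transmission ratio distortion with ungenotyped sires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdscan)
```

## The problem

Transmission ratio distortion (TRD) is the deviation of allele transmission
from a heterozygous parent to its offspring away from the Mendelian 0.5
expectation. Maternal TRD — distortion acting through the dam's meioses,
oocyte competition, or early zygotic selection — can be screened for
genome-wide when dams and their offspring are SNP-genotyped. The design this
package targets is common in livestock populations: each family is a
dam–daughter pair, the sire is *not* genotyped, and all that is known about
him is which of two source populations (labelled `E` and `R`) he came from.
Sire effects therefore cannot be estimated per family; instead each sire
population is summarized by one allele frequency per SNP, and any paternal
distortion is absorbed into that frequency. What remains identifiable — and
what the scan tests — is distortion in the *maternal* transmissions.

## The model

At a biallelic SNP with alleles A1 and A2 (A1 being the major allele after
recoding), genotypes are coded as counts of A1. An offspring genotype is the
sum of one maternal and one paternal allele:

* a dam of genotype 2 (A1A1) transmits A1 with probability 1, a dam of
  genotype 0 with probability 0;
* a *heterozygous* dam transmits A1 with probability $0.5 + \alpha$, where
  $\alpha \in (-0.5, 0.5)$ is the distortion parameter and $\alpha = 0$ is
  Mendelian segregation;
* the ungenotyped sire contributes A1 with probability $\pi_E$ or $\pi_R$
  according to his population.

The three offspring genotype probabilities given the dam genotype are the
products of these allele probabilities (`offspring_probs()`). A SNP's data
reduce to a $3 \times 3 \times 2$ table of family counts indexed by dam
genotype, offspring genotype and sire population (`transmission_counts()`),
and the log-likelihood is the corresponding multinomial sum
(`trd_loglik()`). The full model has three parameters
$(\alpha, \pi_E, \pi_R)$; the null model fixes $\alpha = 0$. Significance is
assessed SNP by SNP with the standard likelihood ratio test on one degree of
freedom — only $\alpha$ is constrained under the null — followed by
Benjamini–Hochberg FDR control across the scanned SNPs.

Only families with a heterozygous dam carry information about $\alpha$.
Homozygous-dam families still matter: they anchor the sire frequencies, and
it is against that anchor that an excess of A1 (or A2) transmissions from
heterozygous dams becomes detectable. This interplay has a sharp consequence
discussed under *Limitations*.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\alpha$ bound | box constraint on the distortion estimate | $\pm 0.495$ | keeps every transmission probability strictly positive so the likelihood stays finite on the whole box; extreme distortion is reported as $\pm 0.495$ rather than a degenerate $\pm 0.5$ |
| `min_maf` | minor allele frequency floor (strict `>`) | 0.05 | monomorphic and near-monomorphic SNPs carry no transmission signal |
| `min_consistency` | family consistency floor (strict `>`) | 0.75 | fraction of families complete *and* Mendelian-compatible; heavy inconsistency flags genotyping error |
| `min_dam_het` | dam heterozygosity floor (strict `>`) | 0.20 | only heterozygous dams inform $\alpha$; below this the estimate rests on a handful of families |
| `fdr_level` | discovery threshold on q-values | 0.05 | conventional FDR control level |

All filter comparisons are strict inequalities, so a SNP sitting exactly on
a threshold is removed; the boundary semantics are tested explicitly.
"Family consistency" counts a family only if both members are genotyped
*and* the pair is Mendelian-compatible (an A1A1 dam cannot have an A2A2
offspring). Complete-but-incompatible pairs have zero likelihood under any
parameter value, so they are excluded both from the consistency numerator
and from the fitted counts, and reported; this is the stricter of the two
readable definitions and is the package's deliberate choice.

Major-allele recoding pools all non-missing calls of all loaded individuals
(dams and offspring of one dam-variety analysis) when deciding which allele
is A1; ties at exactly 0.5 go to the lexicographically smaller allele label.
This keeps one sign convention across the scan: negative $\alpha$ always
means excess transmission of the minor allele. The convention is purely
presentational — the likelihood is exactly invariant under relabeling
$(\alpha, \pi) \to (-\alpha, 1 - \pi)$, an invariance the test suite asserts
to $10^{-10}$.

X-chromosome SNPs are treated like autosomal ones. This is correct when all
offspring are daughters (the design here): a dam–daughter transmission is
diploid and the sire contributes one X allele at frequency $\pi$. Panels
with male offspring would violate this and are not supported.

## Fitting

With $\alpha$ fixed, the likelihood separates by sire population into two
concave one-dimensional problems, so the null fit is two Brent searches
(`fit_trd_null()`). The full fit (`fit_trd_full()`) maximizes over the box
by gradient ascent on reparameterized coordinates — a scaled `tanh` map for
$\alpha$ and a logit map for each $\pi$, which makes the box implicit — with
analytic gradients, backtracking line search, and convergence when the
relative log-likelihood gain drops below $10^{-10}$ (at most 10,000
iterations). Five deterministic restarts guard against flat or multimodal
surfaces; one restart is anchored at the null solution, which guarantees
$\ln L_{\text{full}} \ge \ln L_{\text{null}}$ by construction. The best
restart is polished by coordinate-wise golden-section sweeps on the raw
scale — exact here because the log-likelihood is concave in each coordinate
separately. Exact ties between restarts go to the smallest $|\alpha|$. The
test suite verifies the fitted optimum against an exhaustive grid search at
step 0.001 over all three parameters (the grid collapses to two
$\alpha \times \pi$ surfaces because of the separation noted above).

Degenerate inputs are handled explicitly: a sire population with no counted
families has its $\pi$ dropped from the parameter vector (the LRT keeps one
degree of freedom — only $\alpha$ is constrained); a SNP with no
heterozygous-dam family is flagged non-estimable, reported with missing test
fields, and excluded from the FDR correction's denominator. The LRT
statistic is clipped at zero; no boundary-mixture correction is applied,
a deliberately plain choice that can only make the test conservative near
the $\alpha$ bounds.

The fit consumes no random numbers — restarts are a fixed design — so scan
results are bit-for-bit reproducible and independent of SNP order, which the
suite asserts by scanning permuted panels and by running the command-line
tool twice and comparing output bytes.

## The simulator

`simulate_families()` runs the generative model forward: dam genotypes from
Hardy–Weinberg proportions at a chosen frequency, maternal alleles at
$0.5 + \alpha$ from heterozygous dams, paternal alleles at $\pi_E$ or
$\pi_R$, independent per-call missingness. Sires are never materialized —
only the transmitted allele matters to the model. The default family design
is 97 `E`-sired and 32 `R`-sired families (an Entrepelado-dam panel;
`cross_design()` scales this 97:32 mix, or the 57:61 Retinto-dam mix, to any
total). Power and calibration studies in the tests use 250 families split
188:62 by the same proportions, 0.5 allele frequencies unless a scenario
requires otherwise, and sample sizes of 150–2000 SNPs chosen to keep each
study a few minutes at most.

The simulator emits allele labels so that major-allele recoding may or may
not flip each SNP, exactly as with real data. True parameters refer to the
*simulated* orientation; parameter-recovery checks therefore fit on that
fixed orientation, while a separate check verifies the sign convention
through the full recoding path (a rare allele that is over-transmitted comes
out as negative $\alpha$).

What the simulator does **not** emulate: linkage disequilibrium between
SNPs (every SNP is independent), genotyping error (only missingness),
related dams, multi-generation pedigrees, or selection on the sampled
offspring. Passing tests therefore demonstrate correctness of the
estimator and the pipeline under the model's own assumptions, not
robustness to the correlated noise of a real array panel.

## Limitations

* **Small-sample inflation of the LRT.** The $\chi^2_1$ reference is an
  asymptotic law. The package's own calibration tooling
  (`null_calibration()`, also run by `scripts/acceptance.R`) measures the
  empirical type-I error at $p < 0.05$: at 250 families it comes out
  slightly above nominal (around 0.05–0.065 depending on the Monte-Carlo
  seed), the familiar $O(1/n)$ likelihood-ratio inflation, and settles onto
  the nominal 0.05 by roughly a thousand families. The chi-square
  distributional test in the suite is accordingly run at 1000 families,
  where the asymptotic regime applies. At desk-scale family counts the raw
  p-values near the threshold should be read with this mild inflation in
  mind; q-value control in the scans the suite runs remains effectively
  clean (zero-to-two false discoveries in 2000 null SNPs).
* **A knife-edge confound at $\pi = 0.5$.** For heterozygous dams at
  $\pi = 0.5$, the score vectors for $\alpha$ and $\pi$ are collinear, and a
  panel consisting *only* of heterozygous-dam families of one sire
  population cannot distinguish maternal distortion from a shifted sire
  frequency at all. Identifiability in practice comes from homozygous-dam
  families anchoring $\pi$. This is why the dam-heterozygosity filter has a
  floor rather than a demand for maximal heterozygosity, and why power
  studies here simulate mixed dam genotypes.
* **FDR method.** Benjamini–Hochberg is the default; a Storey-type
  rescaling by an estimated true-null proportion is available
  (`fdr_qvalues(method = "storey")`) but the plug-in estimate is noisy at
  the scan sizes the simulator produces, so it stays behind a flag.
* **Dams must be genotyped.** Families with an ungenotyped dam are excluded
  per SNP; there is no imputation or pedigree reconstruction.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_families(200, n_families = cross_design(250, "E"),
                         alpha = c(rep(-0.35, 5), rep(0, 195)),
                         dam_freq = 0.3, seed = 1)
res <- trd_scan(sim$table, sim$families)
manhattan_table(res)
summary <- write_results(res, "scan.results.tsv")
```

The same pipeline is exposed as a command-line tool (see
`system.file("cli", "trdscan", package = "trdscan")`), reading PLINK text or
VCF genotypes plus a three-column family file, and writing the results
table, the filter report and a log.
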