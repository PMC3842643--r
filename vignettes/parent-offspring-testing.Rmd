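---
title: "Parent-offspring testing with monomorphic SNP loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-offspring testing with monomorphic SNP loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snptrio)
```

## The model

Consider a population derived from a cross of two fully inbred parents and
genotyped on a fixed panel of biallelic SNPs. At a locus where both parents
are homozygous for the same allele — a *monomorphic* locus — Mendelian
inheritance admits exactly one genotype in any true descendant: homozygous
for the shared allele, whatever the recombination history. Monomorphic loci
therefore carry no linkage information but maximal parentage information,
and on typical fixed panels they are the majority of markers.

Each progeny call at a monomorphic locus is scored by the number of its
alleles equal to the shared parental allele: 2 (both parental), 1 (one
parental, one foreign) or 0 (no parental allele — including a heterozygote
of two distinct foreign alleles, which carries zero parental alleles and is
scored 0 under the same counting rule). Writing $a$, $b$, $c$ for the
numbers of loci scored 2, 1 and 0, the similarity of an offspring to its
parents is

$$S \;=\; \frac{2a + b}{2(a + b + c)},$$

the fraction of the offspring's alleles, over scored monomorphic loci, that
are parental. $S$ is an exact rational with denominator $2(a+b+c)$,
computed in integer arithmetic and rendered to floating point only for
reporting, so no tolerance questions arise in the statistic itself. It is
invariant under locus reordering and under swapping the parent labels, and
adding a score-2 locus can never decrease it (nor a score-0 locus increase
it).

A true offspring has $S = 1$ up to genotyping error. Under a symmetric
per-allele miscall rate $\varepsilon$ the expected population mean is
$1 - \varepsilon$, since each miscall at a monomorphic locus removes
exactly one parental allele. Contaminated individuals fall much lower: an
outcross carrying one parental gamete and one gamete from an unrelated
genome sharing a fraction $p$ of alleles at monomorphic loci has
$E[S] = (1+p)/2$; a seed mixture (entirely unrelated) has $E[S] = p$.
Typical within-crop allele sharing of $p \approx 0.6$ puts outcrosses near
0.8 and mixtures near 0.6 — both cleanly separated from true lines at the
recommended thresholds.

## Edge-case policy

Three situations require explicit decisions because the scoring rule does
not define them:

* **A parent missing or heterozygous at a locus.** The locus is *excluded*
  from both the monomorphic and polymorphic sets, with the reason recorded.
  The scoring table is defined only for identical homozygous parents, and a
  heterozygous call in a supposedly inbred parent is an anomaly the report
  should surface, not silently score. Classification counts
  (monomorphic/polymorphic/excluded) are always reported so the excluded
  mass is visible.
* **A missing progeny call at a monomorphic locus.** It enters none of
  $a$, $b$, $c$; it is tallied separately ($m$) and the denominator
  shrinks. Treating assay failure as score 0 would conflate missing data
  with evidence of non-parentage. An offspring with *no* scored loci gets
  an undefined $S$ (reported as `NA`, never 0) and is always flagged, under
  a distinct reason: parentage cannot be certified without data.
* **The threshold boundary.** `flag_variants()` defaults to the strict rule
  $S < t$ (an individual exactly at the threshold is retained), with the
  inclusive rule $S \le t$ available via `rule = "inclusive"`. Published
  usage mixes both conventions, so the choice is a visible argument rather
  than a silent behaviour.

## Input handling

Calls are normalized to a canonical unordered two-letter form (`"AG"`,
alleles sorted; missing is `NA`). Accepted input encodings are two-letter
strings, slash/pipe-separated pairs, single letters for homozygotes, and
IUPAC ambiguity codes for the six biallelic heterozygotes; normalization is
idempotent. The on-disk dialect is tab-separated, markers in rows, missing
as `"--"`; the transposed orientation is accepted and internalized. VCF
import (through `vcfR`) resolves GT indices against REF/ALT, skips
multiallelic records with a counted warning, coerces half-missing genotypes
to missing, and keeps positions 1-based as in the VCF standard. Duplicate
identifiers, ragged rows and unparseable tokens are hard errors naming the
offending row and column: silent repair of a genotype file is worse than a
failure.

## The simulator

`simulate_ril_population()` generates the data the test needs to be
verifiable end to end: a bi-parental population advanced by single-seed
descent, with ground-truth labels for every line. Defaults emulate a
soybean-style study design — 1,536 markers on 20 chromosomes, 37% of loci
polymorphic between the parents (so `round(0.37 * 1536) = 568` polymorphic
and 968 monomorphic loci), 150 lines, four generations of selfing from the
F1 (F5 plants, residual heterozygosity $(1/2)^4 \approx 6.25\%$ per
initially heterozygous locus in expectation).

Meiosis places a Poisson number of crossovers per chromosome (mean
`recombination`, default 1.0) at uniform positions, without interference:
interference changes the spatial pattern of recombination but not the
similarity statistic, which never looks at polymorphic loci, so the
simplest crossover model suffices. Contaminant genomes are homozygous and
agree with the shared parental allele at each monomorphic locus
independently with probability `sharing`; this independence is what gives
the closed-form expected similarities used in tests. Genotyping error
flips each progeny allele to the locus's other assay allele with
probability `error_rate`; parents are exempt, since the panel's parental
alleles define the scoring reference.

Everything is a deterministic function of the configuration's single
`seed`: reruns are bit-identical, and tests of stochastic quantities fix
the seed and check closed forms within three binomial standard errors.

What the simulator deliberately does **not** emulate: segregation
distortion and selection during inbreeding, linkage disequilibrium within
the contaminant genome (real unrelated lines share alleles in blocks, not
independently per locus), locus-specific or asymmetric error rates, and
multi-family pedigrees. Passing tests therefore demonstrate the
correctness of the statistic and its implementation under the stated
model, not robustness to every failure mode of real assay data — on real
data the similarity distribution should always be inspected (e.g. with
`similarity_histogram()`) before fixing a threshold.

## The QTL demonstration

To show why variant removal matters, `single_factor_scan()` regresses a
trait on an additive genotype code at each parentally polymorphic locus:
0/1/2 copies of the parent-2 allele, ordinary least squares, $R^2 =
\mathrm{SSR}/\mathrm{SST}$, $F$ on $(1, n-2)$ degrees of freedom. The
additive coding was chosen over a group-means ANOVA because the two are
identical when only two genotype classes are present (the typical case in
advanced inbred lines) while remaining well defined for residual
heterozygotes; with one regressor $R^2$ equals the squared Pearson
correlation, an identity the test suite checks against `stats::lm`. Calls
carrying a non-parental allele are undefined under the biparental coding
and are dropped per marker with a logged count, as are lines without
phenotype records. Markers with fewer than three usable lines or fewer
than two genotype classes are reported as not testable rather than given a
degenerate fit. No multiple-testing correction is applied in the scan
output — the scan reports raw variance explained; a Bonferroni bound is a
reporting choice left to the caller.

`compare_across_thresholds()` repeats the scan after excluding flagged
lines at each threshold (plus a threshold-0 baseline with no exclusion).
`simulate_phenotype()` plants a QTL of chosen effect and noise
(`noise_sd_for_r2()` inverts the variance decomposition $R^2 = \beta^2
\sigma_g^2 / (\beta^2 \sigma_g^2 + \sigma^2)$ for a target $R^2$) and
optionally shifts the phenotypes of contaminated lines, reproducing the
expected pattern: contaminants add genotype-independent variance, so
excluding them raises the planted QTL's $R^2$.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (flagging) | 0.90 / 0.95 / 0.99 reported | similarity below which a line is a putative variant; 0.90–0.95 is the recommended working range, 0.99 is stringent |
| `rule` | `"strict"` | boundary convention, $S<t$ vs $S\le t$ |
| `polymorphic_fraction` | 0.37 | fraction of panel loci polymorphic between parents |
| `generations_of_selfing` | 4 | F1 to F5; residual heterozygosity $(1/2)^g$ |
| `recombination` | 1.0 | expected crossovers per chromosome per meiosis |
| `error_rate` | 0 | per-allele miscall probability; purely a test instrument |
| `sharing` (contamination) | — | contaminant allele agreement $p$ at monomorphic loci |

## Problem sizes and determinism

Unit and property tests run on reduced designs (typically 400 markers, 10
chromosomes, 40 lines) where binomial standard errors are still tight
enough to pin the closed forms; the end-to-end checks run at the full
default design (1,536 markers, 150 lines), which simulates in a few
seconds. All stochastic tests fix their seeds, and every workflow function
is a pure function of (inputs, configuration, seed), so any reported file
can be regenerated byte for byte.

## Known limitations

The test assumes two inbred, correctly identified parents; it cannot
distinguish which parent an outcross involved, localize Mendelian errors
per locus, or compute likelihood-based parentage assignments (exclusion
probabilities, LOD scores) — those are different instruments. Thresholds
are user choices, not estimated cutpoints: no mixture model is fitted to
the similarity distribution. Multiallelic markers, phased data and
polyploid calls are out of scope.
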