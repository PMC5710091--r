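---
title: "Quantile-based allele-frequency thresholds: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-based allele-frequency thresholds: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afquantile)
```

## The problem

A Mendelian-disease sequencing study produces thousands of candidate
variants, most of them harmless. Public variant databases (1000 Genomes,
gnomAD-style catalogs) are used to shrink that list: a candidate already
present in the database is presumed too common to cause a rare disease and
is removed. Two conventions dominate practice. The *absence approach*
removes any candidate found in the database at any frequency; the *static
approach* removes candidates above a fixed frequency (1% for autosomal
recessive disease, 0.1% for autosomal dominant). Both can discard the true
causal variant, because disease-causing alleles do reside in databases —
recessive alleles hide in healthy heterozygotes, penetrance is incomplete,
phenotypes can be mild or late-onset. This is *variant database
contamination*, and a causal variant removed by a filter is an
irrecoverable false negative.

The quantile-based approach replaces the fixed cutoff with a threshold
derived from what we actually know: the disease prevalence, the mode of
inheritance, the penetrance and detectance of the locus, how the database
was sampled, and how large it is.

## The model

### From prevalence to allele frequency

At a bi-allelic locus in Hardy-Weinberg equilibrium with mutant-allele
frequency $q$ (and $p = 1 - q$), genotype frequencies are
$p^2, 2pq, q^2$. Write $P_{pt} = P(\text{phenotype} \mid \text{genotype})$
for penetrance and $P_{dt} = P(\text{genotype} \mid \text{phenotype})$ for
detectance (the fraction of cases attributable to this locus; $P_{dt} < 1$
encodes genetic heterogeneity). The per-locus genetically affected fraction
is

$$D = \frac{P_d \, P_{dt}}{P_{pt}},$$

and inverting the genotype model gives

$$\text{AR:}\quad q = \sqrt{D}, \qquad
  \text{AD:}\quad q = 1 - \sqrt{1 - D},$$

which reduce to the classical $q = \sqrt{P_d}$ and
$q = 1 - \sqrt{1 - P_d}$ under full penetrance and no heterogeneity. At
equal prevalence a dominant allele is far rarer than a recessive one,
since every carrier is a case. Heterogeneity is handled by treating causal
loci as mutually exclusive within an individual — for rare disease the
probability of being in a disease state at two unlinked loci is
negligible. Models with $D \ge 1$ are rejected as infeasible at
construction rather than silently mapped to $q$ near 1.

`prevalence_from_q()` is the exact forward model
($P_d = P_{pt} q^2 / P_{dt}$ for AR,
$P_{pt}(2pq + q^2)/P_{dt}$ for AD), kept as a first-class operation so the
inversion can be validated by round trip; the suite checks the identity to
a relative $10^{-12}$ over 1,000 random feasible models.

### Sampling situations

Databases built from consenting, legally competent adults selectively
exclude (severely) diseased individuals. The package distinguishes
sampling from the whole population (*situation a*), where the database
allele frequency is governed by $q$ itself, from sampling restricted to
non-diseased individuals (*situation b*). For situation b, renormalizing
the HWE genotype classes over the non-diseased fraction gives

$$\text{AR:}\quad q' = \frac{pq + q^2(1 - P_{pt})}{1 - P_{pt} q^2},
\qquad
\text{AD:}\quad q' = \frac{q (1 - P_{pt})}{1 - P_{pt}(2pq + q^2)}.$$

With full penetrance these collapse to $q' = q/(1+q)$ (AR: the allele
survives only in heterozygotes) and $q' = 0$ (AD: every carrier is a case
and is excluded). The renormalization uses only the locus-specific
diseased fraction; under heterogeneity, cases caused by other loci are a
negligible share of the excluded individuals, consistent with the
mutual-exclusivity approximation. These situation-b forms were derived
here from HWE first principles; they reproduce the published worked result
for this regime (the 1-in-a-million recessive example below), and
$q' \le q$ always — a property test in the suite.

### The threshold and the flag

The mutant-allele count $\Phi$ among the $2c$ chromosomes of a database of
$c$ diploid individuals is $\mathrm{Binomial}(2c, q_{\text{eff}})$,
with $q_{\text{eff}}$ equal to $q$ or $q'$ by situation (sampling $2c$
alleles i.i.d. is equivalent to sampling $c$ HWE genotypes for the allele
count). The threshold $T_v$ is the standard lower quantile — the smallest
$k$ with $P(\Phi \le k) \ge 0.95$ at the default level — so
$P(\Phi > T_v) \le 0.05$: a truly causal variant exceeds $T_v$ in at most
5% of databases. Only database variants *strictly above* $T_v$ are used to
remove candidates; a candidate exactly at $T_v$ survives, and the same
strictness convention is applied to the static cutoffs for consistency.
The quantile convention is pinned down by the worked example below (a
"largest $k$ with CDF $< $ level" convention would give 2/100, not 3/100).

Method 2 inverts the logic for variants already in a database with a
claimed disease association: `flag_probability()` computes
$P(\Phi \ge \text{count})$, and a value at or below $\alpha = 0.05$ flags
the genotype–phenotype claim for re-examination — the variant is too
common for its proposed model. Tail probabilities are reported raw, with
the number of tests attached to the report; whether and how to adjust for
multiplicity is left to the caller, since flagging is a triage step rather
than a confirmatory test.

```{r worked}
m <- disease_model(1e-4, "AR", situation = "a")
q_from_prevalence(m)
predict(m, individuals = 50)
flag_probability(2, 0.01, 50)
```

A database variant seen twice in 100 chromosomes has tail probability
0.26 under this model — no evidence against the disease model.

### Numerical choices

* Binomial CDF and quantile are evaluated exactly through R's incomplete
  beta implementation (`pbinom`/`qbinom`); no normal or Poisson
  approximation anywhere. The regime of interest is small $q$ with large
  $2c$, where an approximation can shift $T_v$ by whole counts. The test
  suite cross-checks both against exhaustive log-space pmf summation for
  all $2c \le 30$ over a $q$ grid at $10^{-12}$.
* Published allele frequencies are rounded discretizations of counts, so
  comparisons are done on the count scale when a record carries a count
  consistent with the database size (`count > tv_count`, no float ties);
  frequency-only records use the frequency scale. Frequencies convert to
  counts by rounding half away from zero (`frequency_to_count()`), so
  f = 0.0004 over 5,008 chromosomes recovers count 2.
* The AD prevalence inversion is computed directly as
  $1 - \sqrt{1 - D}$; no series expansion.
* Matching between candidate and database records is exact on
  (chrom, pos, ref, alt) in VCF 1-based coordinates. Indels are not
  normalized or left-aligned — a known limitation; both inputs must share
  a representation.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `prevalence` | $P_d$, per-individual disease risk | — | required; when given as a range, pass the upper bound (`prevalence_from_range()`): a higher $P_d$ raises $T_v$, which is conservative against false negatives |
| `inheritance` | AR / AD | — | required |
| `penetrance` | $P_{pt}$ | 1 | reduced penetrance *inflates* $q$ and so raises $T_v$ |
| `detectance` | $P_{dt}$ | 1 | heterogeneity *deflates* the per-locus $q$; 1 = naive single-locus analysis, the usual a-priori choice since the number of loci is unknown |
| `situation` | a / b | a (`disease_model`); b (`tv_table`) | b fits consent-restricted human catalogs; the lookup-table default follows that use case |
| `level` | quantile level | 0.95 | the conventional 95% quantile; $P(\Phi > T_v) \le 0.05$ |
| `alpha` | flagging significance | 0.05 | mirrors `1 - level` |
| static cutoffs | fixed thresholds | 0.01 AR / 0.001 AD | the conventional rule of thumb, kept for comparison |

## The worked example at 1000 Genomes scale

A recessive disease with prevalence 1 in 1,000,000, analyzed naively (no
heterogeneity) against a database of 2,504 individuals restricted to
non-diseased donors:

```{r miller}
mb <- disease_model(1e-6, "AR", situation = "b")
predict(mb, individuals = 2504)
```

$q = 10^{-3}$, $q' = q/(1+q)$, and the 95% threshold is 9 copies out of
5,008 chromosomes — $T_v \approx 0.0018$. A known causal variant present
at f = 0.0004 (2 copies) sits below $T_v$ and survives quantile
filtering, while the absence approach would have discarded it.

## What the simulation module emulates — and what it does not

`simulate_causal_counts()` and `evaluate_approaches()` draw database
allele counts from the same binomial model the thresholds are computed
from, i.i.d. across replicates; `simulate_database()` adds a neutral
frequency spectrum to measure how much of a database remains available
for filtering at each threshold. This validates internal consistency: the
quantile approach's false-negative rate is bounded by $1 - \text{level}$
*by construction*, and the Monte-Carlo acceptance check (grid of
prevalences $10^{-3}$–$10^{-6}$, sizes 50–2,504, both situations,
$10^5$ replicates per cell) confirms the implementation honors that
bound. The generator does **not** emulate linkage disequilibrium,
sequencing error or allelic drop-out, population stratification, or
non-HWE structure — so passing tests show the method is correctly
implemented and calibrated under its own assumptions, not that those
assumptions hold in any particular real database. With real data the user
must supply a population-matched database (e.g. restricting 1000G to the
relevant ancestry) and trust its genotype quality.

The toy fixture written by `make_toy_fixture()` fixes only the causal
variant's frequency (f = 0.02 in 100 chromosomes) and the
retain/remove pattern across the three approaches; the other database
frequencies are synthetic values above $T_v$, documented in the fixture's
README.

## Design choices where the design was open

* **Lookup-table grids.** The published supplementary cut-off tables were
  not available to compare against; the package's grids follow the
  documented figure ranges (prevalence $1/n$, $n = 1000$ to $100{,}000$
  in steps of 1000; sizes 50–10,000 including 2,504) and are fully
  overridable. Cells report the frequency to 4 significant digits plus
  the exact integer count, and infeasible cells are `NA` with a footnote
  rather than aborting the table.
* **Situation default for tables.** Situation b, because the intended
  consumers are thresholds against consent-restricted public human
  catalogs; per-call overrides are a single argument.
* **Complex disorders.** `complex_joint_leq_prob()` implements the
  product-of-CDFs approximation for $k$ independent common loci. It is
  deliberately exposed as a separate, documented-as-approximate operation
  and is not wired into the filtering path: the mutual-exclusivity
  assumption that justifies the Mendelian machinery is exactly what
  complex disorders violate.
* **Problem sizes in the suite.** The oracle cross-check runs exhaustively
  only for $2c \le 30$ where summation is exact to $10^{-12}$; the
  Monte-Carlo guarantee uses $10^5$ replicates per grid cell, enough to
  resolve the 0.05 bound to $\pm 0.002$ (3 standard errors).

## Known limitations

* Autosomal modes only; no X-linked or compound-heterozygote models.
* No variant normalization, liftover, annotation, or multi-sample
  genotype handling; no downstream segregation or consequence filters.
* Prevalence is taken as error-free; a 20-fold prevalence underestimate
  translates directly into an undersized threshold.
* Flagging identifies variants whose database frequency is inconsistent
  with their proposed model; it cannot say *why* (wrong association,
  wrong prevalence, reduced penetrance, wrong inheritance, sequencing
  artifact) — that requires follow-up.
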