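# afquantile

Quantile-based allele-frequency thresholds for Mendelian-disease variant
filtering and flagging.

## The problem

Sequencing studies of rare Mendelian disease use public variant databases
to shrink their candidate lists: a candidate already catalogued is presumed
too common to be causal. The two standard conventions — remove every
candidate present in the database (*absence approach*), or remove
candidates above a static 1% (recessive) / 0.1% (dominant) frequency
(*static approach*) — ignore that truly disease-causing alleles do reside
in databases, at frequencies governed by the disease prevalence, the mode
of inheritance, the penetrance and the way the database was sampled.
Filtering with the wrong cutoff silently discards the causal variant.

`afquantile` computes the cutoff the disease model actually implies. With
prevalence *P<sub>d</sub>*, penetrance *P<sub>pt</sub>* and detectance
*P<sub>dt</sub>*, the per-locus affected fraction is
*D = P<sub>d</sub> P<sub>dt</sub> / P<sub>pt</sub>* and Hardy-Weinberg
inversion gives the population mutant-allele frequency

- autosomal recessive: *q = √D*
- autosomal dominant: *q = 1 − √(1 − D)*

If the database was built only from non-diseased individuals ("situation
b"), *q* is renormalized to *q′* over the non-diseased genotype classes
(for a fully penetrant recessive trait, *q′ = q/(1+q)*). The allele count
Φ of the causal variant among the *2c* chromosomes of a *c*-individual
database is then Binomial(*2c*, *q* or *q′*), and the threshold **Tv** is
its 95% quantile: the smallest count *k* with *P(Φ ≤ k) ≥ 0.95*. Only
database variants **strictly above** Tv are safe to filter with — a causal
variant exceeds Tv in at most 5% of databases. The same model flags
database-resident "disease-causing" variants that are improbably common
for their claimed disease model, via the tail probability
*P(Φ ≥ observed count)*.

## Worked example

A recessive disease affecting 1 in 10,000, against a database of 50
individuals sampled from the whole population:

```r
library(afquantile)
m <- disease_model(1e-4, "AR", situation = "a")
q_from_prevalence(m)
#> [1] 0.01
predict(m, individuals = 50)
#> Quantile-based allele-frequency threshold
#>   q (effective):    0.01
#>   database:         50 individuals (100 chromosomes)
#>   quantile level:   0.95
#>   Tv count:         3
#>   Tv frequency:     0.03 (3/100)
```

The expected population allele frequency is *q* = 0.01, and in 100
chromosomes the 95% quantile of the allele count is 3 — so Tv = 0.03.
A causal variant may legitimately appear in the database at up to 3% by
sampling variability; only variants above 3% should be used to remove
candidates. On the bundled toy fixture (7 candidates, 5 in the database,
the causal one at f = 0.02):

```r
paths <- make_toy_fixture(tempdir())
db   <- load_database(paths[["database"]], individuals = 50)
cand <- load_candidates(paths[["candidates"]])
r <- filter_candidates(cand, db, "quantile", model = m, individuals = 50)
r[, c("id", "in_database", "db_frequency", "retained")]
#>     id in_database db_frequency retained
#> 1 var1        TRUE         0.35    FALSE
#> 2 var2        TRUE         0.10    FALSE
#> 3 var3       FALSE           NA     TRUE
#> 4 var4        TRUE         0.02     TRUE
#> 5 var5        TRUE         0.08    FALSE
#> 6 var6       FALSE           NA     TRUE
#> 7 var7        TRUE         0.45    FALSE
```

The causal variant (var4, f = 0.02 < Tv) survives; the absence and static
1% approaches would both have removed it. Flagging runs the model the
other way:

```r
flag_probability(2, 0.01, 50)
#> P(count >= 2 | q = 0.01, 2c = 100) = 0.2642
```

Seeing the allele twice in 100 chromosomes has probability 0.26 under the
model — no reason to doubt the genotype–phenotype claim. Values ≤ 0.05
flag a variant for re-examination.

Also provided: `tv_table()` / `write_tv_table()` for threshold lookup
tables over prevalence × database-size grids, `evaluate_approaches()` for
Monte-Carlo false-negative comparison of the three approaches,
`flag_database_variants()` for batch flagging, and a command-line
interface:

```sh
./exec/afquantile threshold --prevalence 1/1000000 --inheritance AR \
    --individuals 2504 --situation b
# q_population: 0.001
# q_effective: 0.000999
# Tv_count: 9
# Tv_frequency: 0.001797 (9/5008)
```

See `vignettes/quantile-thresholds.Rmd` for the model's derivation,
assumptions and design notes.

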