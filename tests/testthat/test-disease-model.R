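test_that("prevalence maps to allele frequency via the HWE closed forms", {
  # AR: q = sqrt(Pd); AD: q = 1 - sqrt(1 - Pd) under full penetrance
  expect_equal(q_from_prevalence(disease_model(1e-4, "AR")), 0.01)
  expect_equal(q_from_prevalence(disease_model(1e-6, "AR")), 0.001)
  expect_equal(q_from_prevalence(disease_model(0.0199, "AD")), 0.01)
  # reduced penetrance inflates q: D = Pd * Pdt / Ppt
  expect_equal(
    q_from_prevalence(disease_model(1e-4, "AR", penetrance = 0.25)), 0.02)
  # forward check of the penetrance example: Pd = Ppt * q^2
  expect_equal(0.25 * 0.02^2, 1e-4)
  # heterogeneity (detectance < 1) deflates the per-locus q
  expect_equal(
    q_from_prevalence(disease_model(1e-4, "AR", detectance = 0.25)), 0.005)
})

test_that("model validation rejects infeasible and out-of-range parameters", {
  expect_error(disease_model(0, "AR"), "prevalence")
  expect_error(disease_model(1, "AR"), "prevalence")
  expect_error(disease_model(-0.1, "AR"), "prevalence")
  expect_error(disease_model(0.5, "AR", penetrance = 0), "penetrance")
  expect_error(disease_model(0.5, "AR", penetrance = 1.5), "penetrance")
  expect_error(disease_model(0.5, "AR", detectance = 0), "detectance")
  # per-locus case fraction D = Pd*Pdt/Ppt >= 1 is infeasible
  expect_error(disease_model(0.5, "AR", penetrance = 0.4), "infeasible")
  expect_error(disease_model(0.9, "AD", penetrance = 0.5), "infeasible")
  expect_error(disease_model(0.5, "XX"), "arg")
})

test_that("genotype frequencies follow Hardy-Weinberg", {
  expect_equal(genotype_freqs(0.01),
               c(hom_wild = 0.9801, het = 0.0198, hom_mut = 0.0001))
  expect_equal(genotype_freqs(0), c(hom_wild = 1, het = 0, hom_mut = 0))
  expect_equal(genotype_freqs(0.5),
               c(hom_wild = 0.25, het = 0.5, hom_mut = 0.25))
  expect_error(genotype_freqs(1.2), "q")
  # sums to one across a q sweep
  for (q in seq(0, 1, by = 0.05)) {
    expect_equal(sum(genotype_freqs(q)), 1, tolerance = 1e-12)
  }
})

test_that("situation-b sampling removes mutant alleles, never adds them", {
  # AR full penetrance: q' = q/(1+q); cross-check by renormalizing the
  # non-diseased genotype classes p^2 and 2pq over 1 - q^2
  m <- disease_model(1e-6, "AR", situation = "b")
  q <- 0.001
  expect_equal(effective_sampling_freq(q, m), q / (1 + q))
  p <- 1 - q
  expect_equal(effective_sampling_freq(q, m),
               (p * q) / (p^2 + 2 * p * q), tolerance = 1e-12)
  # AD full penetrance: every carrier is diseased and excluded
  mad <- disease_model(1e-4, "AD", situation = "b")
  expect_equal(effective_sampling_freq(0.2, mad), 0)
  # situation a is the identity
  ma <- disease_model(1e-4, "AR", situation = "a")
  expect_identical(effective_sampling_freq(0.01, ma), 0.01)
  # bound: q_effective <= q for random models in either situation
  set.seed(42)
  for (i in 1:200) {
    mod <- disease_model(runif(1, 1e-8, 0.05),
                         sample(c("AR", "AD"), 1),
                         penetrance = runif(1, 0.05, 1),
                         situation = sample(c("a", "b"), 1))
    q <- q_from_prevalence(mod)
    expect_lte(effective_sampling_freq(q, mod), q)
  }
})

test_that("prevalence_from_q inverts q_from_prevalence exactly", {
  expect_equal(prevalence_from_q(0.01, disease_model(0.5, "AR")), 1e-4)
  expect_equal(prevalence_from_q(0.01, disease_model(0.5, "AD")), 0.0199)
  set.seed(7)
  for (i in 1:500) {
    ppt <- runif(1, 0.1, 1)
    pdt <- runif(1, 0.1, 1)
    # keep the per-locus case fraction D = Pd*Pdt/Ppt inside (0, 1)
    mod <- disease_model(runif(1, 1e-9, min(0.5, 0.9 * ppt / pdt)),
                         sample(c("AR", "AD"), 1),
                         penetrance = ppt, detectance = pdt)
    q <- q_from_prevalence(mod)
    expect_equal(prevalence_from_q(q, mod), mod$prevalence,
                 tolerance = 1e-12)
  }
})

test_that("allele frequency is monotone in the epidemiological parameters", {
  for (mode in c("AR", "AD")) {
    # increasing in prevalence
    qs <- vapply(10^seq(-7, -2, by = 0.5),
                 function(pd) q_from_prevalence(disease_model(pd, mode)),
                 numeric(1))
    expect_true(all(diff(qs) > 0))
    # increasing in detectance
    qs <- vapply(seq(0.1, 1, by = 0.1), function(d)
      q_from_prevalence(disease_model(1e-4, mode, detectance = d)),
      numeric(1))
    expect_true(all(diff(qs) > 0))
    # decreasing in penetrance
    qs <- vapply(seq(0.1, 1, by = 0.1), function(p)
      q_from_prevalence(disease_model(1e-4, mode, penetrance = p)),
      numeric(1))
    expect_true(all(diff(qs) < 0))
  }
  # dominant alleles are far rarer than recessive ones at equal prevalence
  for (pd in 10^seq(-6, -1)) {
    expect_lt(q_from_prevalence(disease_model(pd, "AD")),
              q_from_prevalence(disease_model(pd, "AR")))
  }
})

test_that("prevalence ranges resolve to the upper bound", {
  expect_equal(prevalence_from_range(1 / 50000, 1 / 10000), 1e-4)
  expect_error(prevalence_from_range(0.1, 0.01), "low")
})

test_that("model methods report and predict consistently", {
  m <- disease_model(1e-4, "AR")
  expect_output(print(m), "autosomal recessive")
  s <- summary(m)
  expect_equal(s$q_population, 0.01)
  expect_output(print(s), "q \\(population\\)")
  tv <- predict(m, individuals = 50)
  expect_s3_class(tv, "tv_threshold")
  expect_equal(tv$tv_count, 3L)
  expect_equal(tv$q_population, 0.01)
  # simulate draws counts within range and restores RNG state
  set.seed(1); before <- .Random.seed
  x <- simulate(m, nsim = 50, seed = 9, individuals = 50)
  expect_identical(.Random.seed, before)
  expect_true(all(x >= 0 & x <= 100))
  expect_identical(x, simulate(m, nsim = 50, seed = 9, individuals = 50))
})
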