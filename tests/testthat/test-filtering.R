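toy_setup <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- make_toy_fixture(dir)
  list(candidates = load_candidates(paths[["candidates"]]),
       database = load_database(paths[["database"]], individuals = 50),
       model = disease_model(1e-4, "AR", situation = "a"),
       paths = paths)
}

test_that("the three approaches reproduce the toy scenario's pattern", {
  s <- toy_setup()
  absence <- filter_candidates(s$candidates, s$database, "absence")
  static <- filter_candidates(s$candidates, s$database, "static",
                              model = s$model)
  quant <- filter_candidates(s$candidates, s$database, "quantile",
                             model = s$model, individuals = 50)
  # causal variant 4 (f = 0.02): removed by absence and static 1%,
  # retained by the quantile threshold Tv = 0.03
  expect_equal(absence$id[absence$retained], c("var3", "var6"))
  expect_equal(static$id[static$retained], c("var3", "var6"))
  expect_equal(quant$id[quant$retained], c("var3", "var4", "var6"))
  expect_equal(attr(quant, "tv")$tv_frequency, 0.03)
  expect_equal(unique(quant$threshold), 0.03)
})

test_that("candidates absent from the database are always retained and a
           common allele is always removed", {
  db <- variant_frame(c(100, 200), count = c(50, 1), frequency = c(0.5, 0.01))
  cand <- variant_frame(c(100, 300))
  m <- disease_model(1e-4, "AR")
  for (ap in c("absence", "static", "quantile")) {
    r <- filter_candidates(cand, db, ap, model = m, individuals = 50)
    expect_true(r$retained[r$pos == 300])       # not in database
    expect_false(r$retained[r$pos == 100])      # f = 0.5 beats any threshold
    expect_equal(r$rationale[r$pos == 300], "not in database")
  }
})

test_that("removal needs frequency strictly above the threshold", {
  # a candidate sitting exactly at Tv survives
  db <- variant_frame(100, count = 3, frequency = 0.03)
  cand <- variant_frame(100)
  m <- disease_model(1e-4, "AR")
  r <- filter_candidates(cand, db, "quantile", model = m, individuals = 50)
  expect_true(r$retained)
  r2 <- filter_candidates(cand, db, "static", static_cutoff = 0.03)
  expect_true(r2$retained)
})

test_that("static cutoff defaults follow the mode of inheritance", {
  db <- variant_frame(100, count = NA, frequency = 0.005)
  cand <- variant_frame(100)
  # 0.5% is under the AR default 1% but over the AD default 0.1%
  r_ar <- filter_candidates(cand, db, "static",
                            model = disease_model(1e-4, "AR"))
  r_ad <- filter_candidates(cand, db, "static",
                            model = disease_model(1e-4, "AD"))
  expect_true(r_ar$retained)
  expect_false(r_ad$retained)
  expect_equal(r_ar$threshold, 0.01)
  expect_equal(r_ad$threshold, 0.001)
})

test_that("the quantile approach requires a model and database size", {
  db <- variant_frame(100, frequency = 0.02)
  cand <- variant_frame(100)
  expect_error(filter_candidates(cand, db, "quantile"), "model")
})

test_that("absence retains a subset of what static and quantile retain", {
  set.seed(11)
  m <- disease_model(1e-4, "AR")
  for (rep in 1:20) {
    db <- simulate_database(40, 50,
                            freq_spectrum = function(n)
                              stats::rbeta(n, 0.3, 3),
                            seed = rep)
    cand <- db[sample(nrow(db), min(10, nrow(db))),
               c("chrom", "pos", "ref", "alt")]
    kept <- lapply(c("absence", "static", "quantile"), function(ap) {
      r <- filter_candidates(cand, db, ap, model = m, individuals = 50)
      paste(r$chrom, r$pos)[r$retained]
    })
    expect_true(all(kept[[1]] %in% kept[[2]]))
    expect_true(all(kept[[1]] %in% kept[[3]]))
  }
})

test_that("flagging reports the tail probability per database record", {
  s <- toy_setup()
  fl <- flag_database_variants(s$database, s$model, 50)
  # the causal variant seen twice in 100 chromosomes is unremarkable
  v4 <- fl[fl$id == "var4", ]
  expect_equal(round(v4$tail_probability, 2), 0.26)
  expect_false(v4$flagged)
  # the high-frequency synthetic variants are wildly inconsistent with the
  # 1-in-10,000 recessive model
  expect_true(all(fl$flagged[fl$id != "var4"]))
  expect_equal(attr(fl, "n_tests"), 5L)
})

test_that("flagging edge cases: absent allele never flags, a fixed allele
           under a rare model always does", {
  m <- disease_model(1e-4, "AR")  # q = 0.01
  db0 <- variant_frame(100, count = 0, frequency = 0)
  fl0 <- flag_database_variants(db0, m, 50)
  expect_equal(fl0$tail_probability, 1)
  expect_false(fl0$flagged)
  # all 100 chromosomes mutant: closed-form pmf q^(2c) = 1e-200
  dbf <- variant_frame(100, count = 100, frequency = 1)
  flf <- flag_database_variants(dbf, m, 50)
  expect_equal(flf$tail_probability, 1e-200, tolerance = 1e-6)
  expect_true(flf$flagged)
})

test_that("database availability counts strictly-above-threshold records", {
  db <- variant_frame(1:4, frequency = c(0.005, 0.02, 0.2, 0.6))
  expect_equal(database_availability(db, 0), 1)
  expect_equal(database_availability(db, 1), 0)
  expect_equal(database_availability(db, 0.01), 0.75)
  expect_equal(database_availability(db, 0.02), 0.5)  # strict inequality
  expect_error(database_availability(db[0, ], 0.01), "empty")
})

test_that("lower prevalence lowers Tv and frees more of the database", {
  db <- variant_frame(1:50, frequency = seq(0.002, 0.1, length.out = 50))
  avail <- vapply(10^seq(-3, -6), function(pd) {
    tv <- predict(disease_model(pd, "AR"), individuals = 2504)
    database_availability(db, tv$tv_frequency)
  }, numeric(1))
  expect_true(all(diff(avail) >= 0))
})

test_that("reports serialize deterministically with a self-describing
           header", {
  s <- toy_setup()
  r <- filter_candidates(s$candidates, s$database, "quantile",
                         model = s$model, individuals = 50)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_report(r, f1)
  write_report(filter_candidates(s$candidates, s$database, "quantile",
                                 model = s$model, individuals = 50), f2)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(any(grepl("^# model: prevalence=1e-04 inheritance=AR", lines)))
  expect_true(any(grepl("^# threshold: Tv=3/100", lines)))
  # the data rows round-trip
  back <- utils::read.table(f1, header = TRUE, sep = "\t",
                            comment.char = "#")
  expect_equal(nrow(back), 7L)
  expect_equal(sum(back$retained), 3L)

  fl <- flag_database_variants(s$database, s$model, 50)
  f3 <- withr::local_tempfile()
  write_report(fl, f3)
  expect_true(any(grepl("^# tests: 5", readLines(f3))))
})
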