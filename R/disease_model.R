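#' Specify a Mendelian disease model
#'
#' Constructs the epidemiological prior used throughout the package: disease
#' prevalence, mode of inheritance, penetrance, detectance and the database
#' sampling situation. The model links the population disease prevalence
#' \eqn{P_d} to the mutant-allele frequency \eqn{q} at a single bi-allelic
#' locus under Hardy-Weinberg equilibrium, and downstream to the expected
#' allele count of the disease-causing variant in a variant database.
#'
#' Penetrance \eqn{P_{pt} = P(\mathrm{phenotype}\mid\mathrm{genotype})} and
#' detectance \eqn{P_{dt} = P(\mathrm{genotype}\mid\mathrm{phenotype})} enter
#' through the per-locus genetically affected fraction
#' \eqn{D = P_d \, P_{dt} / P_{pt}}, which must be below 1 for the model to be
#' feasible. Detectance below 1 models genetic heterogeneity: only a fraction
#' of cases is attributable to the locus under study, and causal loci are
#' treated as mutually exclusive (the probability that one individual is in a
#' disease state at two unlinked loci is negligible for rare disease).
#'
#' The sampling situation describes how database individuals relate to the
#' population: `"a"` means individuals were sampled at random from the whole
#' population; `"b"` means only non-diseased individuals could be sampled
#' (as with consent-restricted cohorts such as 1000 Genomes), which
#' selectively removes mutant alleles.
#'
#' @param prevalence Disease prevalence \eqn{P_d}, a probability in (0, 1).
#'   Use [prevalence_from_range()] if the literature reports a range.
#' @param inheritance `"AR"` (autosomal recessive) or `"AD"` (autosomal
#'   dominant).
#' @param penetrance \eqn{P_{pt}} in (0, 1]; default 1 (full penetrance).
#' @param detectance \eqn{P_{dt}} in (0, 1]; default 1 (no genetic
#'   heterogeneity).
#' @param situation `"a"` (whole-population sampling) or `"b"` (non-diseased
#'   individuals only); default `"a"`.
#'
#' @return An object of class `"disease_model"`.
#'
#' @examples
#' # Fully penetrant recessive disease affecting 1 in 10,000
#' m <- disease_model(1e-4, "AR")
#' q_from_prevalence(m)   # 0.01
#' summary(m)
#'
#' # Miller syndrome style model: very rare, database excludes cases
#' disease_model(1e-6, "AR", situation = "b")
#' @seealso [q_from_prevalence()], [tv_threshold()], [predict.disease_model()]
#' @export
disease_model <- function(prevalence,
                          inheritance = c("AR", "AD"),
                          penetrance = 1,
                          detectance = 1,
                          situation = c("a", "b")) {
  if (!identical(inheritance, c("AR", "AD"))) {
    inheritance <- toupper(as.character(inheritance))
  }
  inheritance <- match.arg(inheritance, c("AR", "AD"))
  if (!identical(situation, c("a", "b"))) {
    situation <- tolower(as.character(situation))
  }
  situation <- match.arg(situation, c("a", "b"))

  check_probability(prevalence, "prevalence", open_low = TRUE, open_high = TRUE)
  check_probability(penetrance, "penetrance", open_low = TRUE)
  check_probability(detectance, "detectance", open_low = TRUE)

  D <- prevalence * detectance / penetrance
  if (D >= 1) {
    stop("infeasible disease model: per-locus case fraction ",
         "prevalence * detectance / penetrance = ", format(D),
         " is >= 1", call. = FALSE)
  }

  structure(
    list(prevalence = prevalence,
         inheritance = inheritance,
         penetrance = penetrance,
         detectance = detectance,
         situation = situation),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Mendelian disease model\n")
  cat(sprintf("  prevalence (Pd):  %s\n", format(x$prevalence)))
  cat(sprintf("  inheritance:      %s\n",
              if (x$inheritance == "AR") "autosomal recessive"
              else "autosomal dominant"))
  cat(sprintf("  penetrance (Ppt): %s\n", format(x$penetrance)))
  cat(sprintf("  detectance (Pdt): %s\n", format(x$detectance)))
  cat(sprintf("  sampling:         situation %s (%s)\n", x$situation,
              if (x$situation == "a") "whole population"
              else "non-diseased individuals only"))
  invisible(x)
}

#' @export
summary.disease_model <- function(object, ...) {
  q <- q_from_prevalence(object)
  out <- list(model = object,
              q_population = q,
              q_effective = effective_sampling_freq(q, object),
              genotypes = genotype_freqs(q))
  class(out) <- "summary.disease_model"
  out
}

#' @export
print.summary.disease_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  q (population):   %s\n", format(signif(x$q_population, 6))))
  cat(sprintf("  q (effective):    %s\n", format(signif(x$q_effective, 6))))
  g <- x$genotypes
  cat(sprintf("  HWE genotypes:    P = %s, H = %s, Q = %s\n",
              format(signif(g[["hom_wild"]], 6)),
              format(signif(g[["het"]], 6)),
              format(signif(g[["hom_mut"]], 6))))
  invisible(x)
}

#' Population mutant-allele frequency implied by a disease model
#'
#' Inverts the Hardy-Weinberg prevalence model. With the per-locus genetically
#' affected fraction \eqn{D = P_d P_{dt} / P_{pt}}:
#' \deqn{\mathrm{AR:}\quad q = \sqrt{D} \qquad
#'       \mathrm{AD:}\quad q = 1 - \sqrt{1 - D}}
#' Under full penetrance and no heterogeneity these reduce to the classical
#' forms \eqn{q = \sqrt{P_d}} (recessive: cases are the \eqn{q^2} homozygotes)
#' and \eqn{q = 1 - \sqrt{1 - P_d}} (dominant: cases are carriers,
#' \eqn{2pq + q^2 = 1 - p^2}).
#'
#' The AD inversion is computed directly as \eqn{1 - \sqrt{1 - D}}; values of
#' \eqn{D} at or above 1 are rejected at model construction rather than
#' silently mapped to \eqn{q} near 1.
#'
#' @param model A [disease_model()].
#' @return The mutant-allele frequency \eqn{q} in the population.
#' @examples
#' q_from_prevalence(disease_model(1e-4, "AR"))                    # 0.01
#' q_from_prevalence(disease_model(0.0199, "AD"))                  # 0.01
#' q_from_prevalence(disease_model(1e-4, "AR", penetrance = 0.25)) # 0.02
#' @export
q_from_prevalence <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  D <- model$prevalence * model$detectance / model$penetrance
  if (D >= 1) {
    stop("infeasible disease model: per-locus case fraction >= 1",
         call. = FALSE)
  }
  if (model$inheritance == "AR") sqrt(D) else 1 - sqrt(1 - D)
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param q Mutant-allele frequency in \[0, 1\].
#' @return Named numeric vector `c(hom_wild, het, hom_mut)` equal to
#'   \eqn{(p^2, 2pq, q^2)} with \eqn{p = 1 - q}.
#' @examples
#' genotype_freqs(0.01)  # 0.9801 0.0198 0.0001
#' @export
genotype_freqs <- function(q) {
  check_probability(q, "q")
  p <- 1 - q
  c(hom_wild = p^2, het = 2 * p * q, hom_mut = q^2)
}

#' Mutant-allele frequency among the sampled part of the population
#'
#' Under situation "a" (random sampling from the whole population) the
#' frequency among sampled individuals equals the population frequency
#' \eqn{q}. Under situation "b" only non-diseased individuals enter the
#' database, which removes mutant alleles carried by cases. Renormalizing
#' the HWE genotype classes over the non-diseased fraction gives
#' \deqn{\mathrm{AR:}\quad q' = \frac{pq + q^2 (1 - P_{pt})}{1 - P_{pt} q^2}
#' \qquad
#' \mathrm{AD:}\quad q' = \frac{q (1 - P_{pt})}{1 - P_{pt}(2pq + q^2)}}
#' In the full-penetrance limit these become \eqn{q' = q / (1 + q)} (AR: only
#' heterozygotes carry the allele unaffected) and \eqn{q' = 0} (AD: every
#' carrier is diseased and excluded).
#'
#' The renormalization uses only the locus-specific diseased fraction
#' (e.g. \eqn{P_{pt} q^2} for AR); under genetic heterogeneity, cases caused
#' by other loci are treated as a negligible share of excluded individuals,
#' consistent with the mutually-exclusive-loci approximation.
#'
#' @param q Population mutant-allele frequency, typically from
#'   [q_from_prevalence()].
#' @param model A [disease_model()]; its `situation` and `penetrance` are used.
#' @return The binomial success probability used downstream: `q` itself for
#'   situation "a", \eqn{q'} for situation "b".
#' @examples
#' m <- disease_model(1e-6, "AR", situation = "b")
#' effective_sampling_freq(0.001, m)  # 0.001/(1 + 0.001)
#' @export
effective_sampling_freq <- function(q, model) {
  stopifnot(inherits(model, "disease_model"))
  check_probability(q, "q")
  if (model$situation == "a") {
    return(q)
  }
  p <- 1 - q
  ppt <- model$penetrance
  if (model$inheritance == "AR") {
    denom <- 1 - ppt * q^2
    if (denom <= 0) {
      stop("infeasible model: the whole population is diseased under ",
           "situation b", call. = FALSE)
    }
    (p * q + q^2 * (1 - ppt)) / denom
  } else {
    denom <- 1 - ppt * (2 * p * q + q^2)
    if (denom <= 0) {
      stop("infeasible model: the whole population is diseased under ",
           "situation b", call. = FALSE)
    }
    q * (1 - ppt) / denom
  }
}

#' Disease prevalence implied by a mutant-allele frequency
#'
#' Forward Hardy-Weinberg model, the exact inverse of [q_from_prevalence()]:
#' \eqn{P_d = P_{pt} q^2 / P_{dt}} (AR) or
#' \eqn{P_d = P_{pt} (2pq + q^2) / P_{dt}} (AD).
#' Useful for round-trip validation and for forward-computing the prevalence a
#' proposed allele frequency would imply.
#'
#' @inheritParams effective_sampling_freq
#' @return The disease prevalence \eqn{P_d}.
#' @examples
#' prevalence_from_q(0.01, disease_model(0.5, "AR"))  # 1e-4
#' @export
prevalence_from_q <- function(q, model) {
  stopifnot(inherits(model, "disease_model"))
  check_probability(q, "q")
  p <- 1 - q
  geno <- if (model$inheritance == "AR") q^2 else 2 * p * q + q^2
  model$penetrance * geno / model$detectance
}

#' Resolve a prevalence reported as a range
#'
#' Epidemiological sources often give prevalence as a range; threshold
#' calculations use the upper bound (the most conservative choice against
#' false negatives: a higher prevalence gives a higher threshold).
#'
#' @param low,high Bounds of the reported range, each in (0, 1).
#' @return The upper bound, `high`.
#' @examples
#' prevalence_from_range(1 / 50000, 1 / 10000)  # 1e-4
#' @export
prevalence_from_range <- function(low, high) {
  check_probability(low, "low", open_low = TRUE, open_high = TRUE)
  check_probability(high, "high", open_low = TRUE, open_high = TRUE)
  if (low > high) stop("low must not exceed high", call. = FALSE)
  high
}

#' Expected allele-frequency threshold for a disease model
#'
#' Computes the quantile-based threshold Tv for the model in a database of
#' `individuals` diploid individuals: the population allele frequency from
#' [q_from_prevalence()], adjusted for the sampling situation by
#' [effective_sampling_freq()], then passed to [tv_threshold()].
#'
#' @param object A [disease_model()].
#' @param individuals Database size in diploid individuals (or a
#'   [database_spec()]).
#' @param level Quantile level; default 0.95.
#' @param ... Unused.
#' @return A `"tv_threshold"` object; see [tv_threshold()].
#' @examples
#' predict(disease_model(1e-4, "AR"), individuals = 50)  # Tv = 3/100 = 0.03
#' @export
predict.disease_model <- function(object, individuals, level = 0.95, ...) {
  q <- q_from_prevalence(object)
  q_eff <- effective_sampling_freq(q, object)
  tv <- tv_threshold(q_eff, individuals, level = level)
  tv$q_population <- q
  tv$model <- object
  tv
}

#' Simulate database allele counts of the causal variant
#'
#' Draws the number of mutant-allele copies among the `2 * individuals`
#' database chromosomes, \eqn{\Phi \sim \mathrm{Binomial}(2c, q_{\mathrm{eff}})},
#' with all alleles sampled i.i.d. (under HWE, sampling 2c alleles and
#' sampling c genotypes give the same allele-count distribution).
#'
#' @param object A [disease_model()].
#' @param nsim Number of replicate databases.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is restored afterwards.
#' @param individuals Database size in diploid individuals.
#' @param ... Unused.
#' @return Integer vector of length `nsim` of allele counts.
#' @examples
#' simulate(disease_model(1e-4, "AR"), nsim = 5, seed = 1, individuals = 50)
#' @export
simulate.disease_model <- function(object, nsim = 1, seed = NULL,
                                   individuals, ...) {
  db <- as_database_spec(individuals)
  q_eff <- effective_sampling_freq(q_from_prevalence(object), object)
  with_seed_restore(seed,
    stats::rbinom(nsim, size = db$chromosomes, prob = q_eff))
}

# shared argument validation; open_* exclude the endpoint
check_probability <- function(x, name, open_low = FALSE, open_high = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single non-missing number", call. = FALSE)
  }
  lo_ok <- if (open_low) x > 0 else x >= 0
  hi_ok <- if (open_high) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop(name, " must be in ",
         if (open_low) "(" else "[", "0, 1",
         if (open_high) ")" else "]",
         " (got ", format(x), ")", call. = FALSE)
  }
  invisible(x)
}
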