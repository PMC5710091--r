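#' Variant-database size specification
#'
#' A database of `individuals` diploid individuals carries
#' `2 * individuals` chromosomes; the allele count of a variant is modelled
#' as a binomial draw over those chromosomes.
#'
#' @param individuals Positive integer, number of diploid individuals `c`.
#' @return An object of class `"database_spec"` with fields `individuals`
#'   and `chromosomes` (= 2c).
#' @examples
#' database_spec(2504)  # 1000 Genomes phase 3 scale
#' @export
database_spec <- function(individuals) {
  if (!is.numeric(individuals) || length(individuals) != 1L ||
      is.na(individuals) || individuals < 1 ||
      individuals != round(individuals)) {
    stop("individuals must be a single positive integer", call. = FALSE)
  }
  individuals <- as.integer(individuals)
  structure(list(individuals = individuals,
                 chromosomes = 2L * individuals),
            class = "database_spec")
}

#' @export
print.database_spec <- function(x, ...) {
  cat(sprintf("Variant database: %d diploid individuals (%d chromosomes)\n",
              x$individuals, x$chromosomes))
  invisible(x)
}

# accept a database_spec or a bare individual count
as_database_spec <- function(x) {
  if (inherits(x, "database_spec")) x else database_spec(x)
}

#' Quantile-based allele-frequency threshold Tv
#'
#' The number of mutant-allele copies \eqn{\Phi} among the \eqn{2c}
#' chromosomes of a variant database is modelled as
#' \eqn{\Phi \sim \mathrm{Binomial}(2c, q_{\mathrm{eff}})}. The threshold Tv
#' is the smallest count \eqn{k} with
#' \eqn{P(\Phi \le k) \ge \mathrm{level}} (the standard lower quantile), so
#' that \eqn{P(\Phi > \mathrm{Tv}) \le 1 - \mathrm{level}}: a truly causal
#' variant exceeds Tv in at most a fraction \eqn{1 - \mathrm{level}} of
#' databases. Only database variants with frequency *strictly above*
#' `tv_frequency` should be used to remove candidates.
#'
#' The binomial CDF/quantile are evaluated exactly (regularized incomplete
#' beta); no normal or Poisson approximation is used — in the
#' small-\eqn{q}, large-\eqn{2c} regime of interest an approximation can
#' shift Tv by whole counts.
#'
#' @param q_effective Binomial success probability: the mutant-allele
#'   frequency among sampled individuals (\eqn{q} for situation "a",
#'   \eqn{q'} for situation "b").
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()].
#' @param level Quantile level in (0, 1); default 0.95.
#' @return An object of class `"tv_threshold"`: a list with `q_effective`,
#'   `individuals`, `chromosomes`, `level`, `tv_count` (integer threshold)
#'   and `tv_frequency` (`tv_count / chromosomes`).
#' @examples
#' # 1-in-10,000 recessive disease, database of 50 individuals
#' tv_threshold(0.01, 50)                 # Tv = 3 (frequency 0.03)
#' tv_threshold(0.000999001, 2504)        # Miller syndrome: Tv/5008 ~ 0.0018
#' @seealso [predict.disease_model()] to compute `q_effective` from a disease
#'   model, [flag_probability()] for the dual tail probability.
#' @export
tv_threshold <- function(q_effective, individuals, level = 0.95) {
  check_probability(q_effective, "q_effective")
  check_probability(level, "level", open_low = TRUE, open_high = TRUE)
  db <- as_database_spec(individuals)
  tv_count <- as.integer(stats::qbinom(level, size = db$chromosomes,
                                       prob = q_effective))
  structure(
    list(q_effective = q_effective,
         individuals = db$individuals,
         chromosomes = db$chromosomes,
         level = level,
         tv_count = tv_count,
         tv_frequency = tv_count / db$chromosomes),
    class = "tv_threshold"
  )
}

#' @export
print.tv_threshold <- function(x, ...) {
  cat("Quantile-based allele-frequency threshold\n")
  if (!is.null(x$q_population) && x$q_population != x$q_effective) {
    cat(sprintf("  q (population):   %s\n", format(signif(x$q_population, 4))))
  }
  cat(sprintf("  q (effective):    %s\n", format(signif(x$q_effective, 4))))
  cat(sprintf("  database:         %d individuals (%d chromosomes)\n",
              x$individuals, x$chromosomes))
  cat(sprintf("  quantile level:   %s\n", format(x$level)))
  cat(sprintf("  Tv count:         %d\n", x$tv_count))
  cat(sprintf("  Tv frequency:     %s (%d/%d)\n",
              format(signif(x$tv_frequency, 4)), x$tv_count, x$chromosomes))
  invisible(x)
}

#' Plot the allele-count distribution behind a threshold
#'
#' Draws the binomial pmf of the database allele count with the Tv cut-off
#' marked; counts above Tv (the upper \eqn{1 - \mathrm{level}} tail) are
#' shaded.
#'
#' @param x A `"tv_threshold"` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted pmf.
#' @export
plot.tv_threshold <- function(x, ...) {
  upper <- max(x$tv_count + 3L,
               as.integer(stats::qbinom(0.9999, x$chromosomes,
                                        x$q_effective)))
  k <- 0:upper
  pmf <- stats::dbinom(k, size = x$chromosomes, prob = x$q_effective)
  cols <- ifelse(k > x$tv_count, "firebrick", "grey70")
  mids <- graphics::barplot(pmf, names.arg = k, col = cols, border = NA,
                            xlab = "mutant-allele count in database",
                            ylab = "probability",
                            main = sprintf("Tv = %d/%d (level %.2f)",
                                           x$tv_count, x$chromosomes,
                                           x$level), ...)
  graphics::abline(v = mean(mids[k == x$tv_count] +
                              diff(mids[1:2]) / 2), lty = 2)
  invisible(pmf)
}

#' Tail probability of an observed database allele count
#'
#' For a variant reported as disease-causing under some model, computes the
#' probability of seeing its database frequency or a higher one,
#' \eqn{P(\Phi \ge k) = 1 - P(\Phi \le k - 1)} with
#' \eqn{\Phi \sim \mathrm{Binomial}(2c, q_{\mathrm{eff}})}. A small value
#' (conventionally \eqn{\le 0.05}) flags the genotype-phenotype association
#' for re-examination: the variant is too common in the database for the
#' proposed disease model.
#'
#' The tail is evaluated on the count scale. Database allele frequencies are
#' discretizations of counts, so a frequency `f` is first converted with
#' [frequency_to_count()].
#'
#' @param observed_count Observed mutant-allele count in the database
#'   (0 to `2c`). Exactly one of `observed_count` / `frequency` must be given.
#' @param q_effective Binomial success probability under the disease model.
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()].
#' @param frequency Alternative to `observed_count`: the database allele
#'   frequency `f`, converted to a count internally.
#' @return An object of class `"tail_probability"`: a list with
#'   `observed_count`, `chromosomes`, `q_effective` and `probability`
#'   (\eqn{P(\Phi \ge \mathrm{observed\_count})}).
#' @examples
#' # Fig-style check: is seeing the allele twice in 100 chromosomes
#' # surprising for a 1-in-10,000 recessive disease (q = 0.01)?
#' flag_probability(2, 0.01, 50)$probability  # 0.264: not surprising
#' @export
flag_probability <- function(observed_count = NULL, q_effective, individuals,
                             frequency = NULL) {
  check_probability(q_effective, "q_effective")
  db <- as_database_spec(individuals)
  if (is.null(observed_count) == is.null(frequency)) {
    stop("supply exactly one of observed_count or frequency", call. = FALSE)
  }
  if (is.null(observed_count)) {
    observed_count <- frequency_to_count(frequency, db)
  }
  if (!is.numeric(observed_count) || length(observed_count) != 1L ||
      is.na(observed_count) || observed_count != round(observed_count) ||
      observed_count < 0) {
    stop("observed_count must be a single non-negative integer",
         call. = FALSE)
  }
  if (observed_count > db$chromosomes) {
    stop("observed_count (", observed_count, ") exceeds the number of ",
         "database chromosomes (", db$chromosomes, ")", call. = FALSE)
  }
  prob <- stats::pbinom(observed_count - 1, size = db$chromosomes,
                        prob = q_effective, lower.tail = FALSE)
  structure(
    list(observed_count = as.integer(observed_count),
         chromosomes = db$chromosomes,
         q_effective = q_effective,
         probability = prob),
    class = "tail_probability"
  )
}

#' @export
print.tail_probability <- function(x, ...) {
  cat(sprintf(
    "P(count >= %d | q = %s, 2c = %d) = %s\n",
    x$observed_count, format(signif(x$q_effective, 4)), x$chromosomes,
    format(signif(x$probability, 4))))
  invisible(x)
}

#' Convert a database allele frequency to an allele count
#'
#' Public databases publish rounded allele frequencies, but the underlying
#' datum is an integer count over `2c` chromosomes. Converts with
#' round-half-away-from-zero so that e.g. f = 0.0004 over 5008 chromosomes
#' (0.0004 * 5008 = 2.0032) recovers count 2.
#'
#' @param f Allele frequency in \[0, 1\].
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()].
#' @return Integer allele count.
#' @examples
#' frequency_to_count(0.0004, 2504)  # 2
#' @export
frequency_to_count <- function(f, individuals) {
  check_probability(f, "f")
  db <- as_database_spec(individuals)
  as.integer(floor(f * db$chromosomes + 0.5))
}

#' Joint probability that several independent loci all stay below Tv
#'
#' An approximation for complex disorders: with `k_loci` independent
#' contributing loci, each with allele frequency `q`, the probability that
#' every locus occurs at or below `tv_count` copies in the database is the
#' product of the per-locus binomial CDFs,
#' \eqn{P(\Phi \le \mathrm{Tv})^{k}}. This presumes the general architecture
#' of complex disorders (several common co-occurring variants) and an assumed
#' number of loci; it is not applicable to Mendelian models, where causal
#' loci are treated as mutually exclusive.
#'
#' @param q Per-locus allele frequency.
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()].
#' @param tv_count Allele-count threshold.
#' @param k_loci Number of independent loci, >= 1.
#' @return The joint probability.
#' @examples
#' complex_joint_leq_prob(0.05, 50, tv_count = 10, k_loci = 3)
#' @export
complex_joint_leq_prob <- function(q, individuals, tv_count, k_loci) {
  check_probability(q, "q")
  db <- as_database_spec(individuals)
  if (!is.numeric(k_loci) || length(k_loci) != 1L || k_loci < 1 ||
      k_loci != round(k_loci)) {
    stop("k_loci must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(tv_count) || length(tv_count) != 1L || tv_count < 0 ||
      tv_count != round(tv_count)) {
    stop("tv_count must be a single non-negative integer", call. = FALSE)
  }
  stats::pbinom(tv_count, size = db$chromosomes, prob = q)^k_loci
}
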