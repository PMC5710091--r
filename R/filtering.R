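#' Filter candidate variants against a variant database
#'
#' Applies one of three database-filtering approaches to a candidate-variant
#' list (method 1, "variant filtering"):
#' \describe{
#'   \item{absence}{any candidate present in the database, at any frequency,
#'     is removed — this assumes disease-causing variants never enter variant
#'     databases and produces false negatives when they do ("variant database
#'     contamination").}
#'   \item{static}{candidates are removed when their database frequency is
#'     strictly above a fixed cutoff: 1\% for autosomal recessive disease,
#'     0.1\% for autosomal dominant (the conventional rule of thumb),
#'     overridable via `static_cutoff`.}
#'   \item{quantile}{candidates are removed when their database frequency is
#'     strictly above the model-derived threshold Tv from
#'     [predict.disease_model()]; the cutoff adapts to disease prevalence,
#'     inheritance, penetrance, detectance, sampling situation and database
#'     size.}
#' }
#' Removal always requires the database frequency to be *strictly* above the
#' threshold; a candidate sitting exactly at Tv is retained. Matching is
#' exact on `(chrom, pos, ref, alt)` — indels are not normalized or
#' left-aligned, so both files must use the same representation.
#'
#' When a database record carries an allele count consistent with
#' `individuals`, the comparison is done on the count scale
#' (`count > tv_count`), which avoids floating-point ties on rounded
#' published frequencies; otherwise the frequency scale is used.
#'
#' @param candidates Data frame of candidate variants
#'   (from [load_candidates()] or equivalent, with columns `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param database Data frame of database variants with `frequency` (and
#'   optionally `count`), from [load_database()] or equivalent.
#' @param approach `"quantile"`, `"static"` or `"absence"`.
#' @param model A [disease_model()]; required for the quantile approach and
#'   for the inheritance-specific default static cutoff.
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()]; required for the quantile approach.
#' @param static_cutoff Cutoff frequency for the static approach; defaults to
#'   0.01 (AR) or 0.001 (AD) based on `model`, or 0.01 when no model is
#'   given.
#' @param level Quantile level for the quantile approach; default 0.95.
#' @return A data frame of class `"filter_report"`, one row per candidate,
#'   with columns `chrom`, `pos`, `id`, `ref`, `alt`, `in_database`,
#'   `db_frequency`, `approach`, `threshold`, `retained`, `rationale`.
#'   The threshold object (for the quantile approach) is attached as
#'   attribute `"tv"`.
#' @examples
#' db <- data.frame(chrom = "1", pos = c(100, 200), ref = "A", alt = "T",
#'                  count = c(2, 35), frequency = c(0.02, 0.35))
#' cand <- data.frame(chrom = "1", pos = c(100, 200, 300), ref = "A",
#'                    alt = "T")
#' m <- disease_model(1e-4, "AR")
#' filter_candidates(cand, db, "quantile", model = m, individuals = 50)
#' @export
filter_candidates <- function(candidates, database,
                              approach = c("quantile", "static", "absence"),
                              model = NULL, individuals = NULL,
                              static_cutoff = NULL, level = 0.95) {
  approach <- match.arg(approach)
  check_variant_frame(candidates, "candidates")
  check_variant_frame(database, "database")

  tv <- NULL
  threshold <- switch(approach,
    absence = 0,
    static = {
      if (is.null(static_cutoff)) {
        static_cutoff <- if (!is.null(model) && model$inheritance == "AD")
          0.001 else 0.01
      }
      check_probability(static_cutoff, "static_cutoff")
      static_cutoff
    },
    quantile = {
      if (is.null(model) || is.null(individuals)) {
        stop("the quantile approach needs a disease model and the database ",
             "size (individuals)", call. = FALSE)
      }
      tv <- predict(model, individuals = individuals, level = level)
      tv$tv_frequency
    }
  )

  key_db <- variant_key(database)
  key_cand <- variant_key(candidates)
  idx <- match(key_cand, key_db)
  in_db <- !is.na(idx)
  f <- rep(NA_real_, length(key_cand))
  f[in_db] <- database$frequency[idx[in_db]]

  if (approach == "absence") {
    removed <- in_db
  } else if (!is.null(tv) && "count" %in% names(database) &&
             !anyNA(database$count)) {
    # exact integer comparison when the database carries counts
    cnt <- rep(NA_integer_, length(key_cand))
    cnt[in_db] <- database$count[idx[in_db]]
    removed <- in_db & cnt > tv$tv_count
  } else {
    removed <- in_db & !is.na(f) & f > threshold
  }

  rationale <- character(length(key_cand))
  rationale[!in_db] <- "not in database"
  rationale[in_db & !removed] <- sprintf(
    "in database at f = %s <= threshold %s",
    format(signif(f[in_db & !removed], 4)), format(signif(threshold, 4)))
  rationale[removed] <- if (approach == "absence") {
    "present in database"
  } else {
    sprintf("in database at f = %s > threshold %s",
            format(signif(f[removed], 4)), format(signif(threshold, 4)))
  }

  out <- data.frame(
    chrom = candidates$chrom,
    pos = candidates$pos,
    id = if ("id" %in% names(candidates)) candidates$id else NA_character_,
    ref = candidates$ref,
    alt = candidates$alt,
    in_database = in_db,
    db_frequency = f,
    approach = approach,
    threshold = threshold,
    retained = !removed,
    rationale = rationale,
    stringsAsFactors = FALSE
  )
  attr(out, "tv") <- tv
  attr(out, "model") <- model
  class(out) <- c("filter_report", "data.frame")
  out
}

#' @export
print.filter_report <- function(x, ...) {
  approach <- if ("approach" %in% names(x) && nrow(x) > 0) x$approach[1]
              else NA_character_
  cat(sprintf("Variant filtering report%s\n",
              if (is.na(approach)) ""
              else sprintf(" (%s approach)", approach)))
  tv <- attr(x, "tv")
  if (!is.null(tv)) {
    cat(sprintf("  Tv = %d/%d = %s (level %s)\n", tv$tv_count,
                tv$chromosomes, format(signif(tv$tv_frequency, 4)),
                format(tv$level)))
  } else if (identical(approach, "static") && "threshold" %in% names(x)) {
    cat(sprintf("  cutoff = %s\n", format(signif(x$threshold[1], 4))))
  }
  if ("retained" %in% names(x)) {
    cat(sprintf("  %d candidate(s): %d retained, %d filtered out\n",
                nrow(x), sum(x$retained), sum(!x$retained)))
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Flag database variants that are too common for their disease model
#'
#' For every record of a frequency-annotated database, computes the tail
#' probability \eqn{P(\Phi \ge \mathrm{count})} under the proposed disease
#' model ([flag_probability()]) and flags records with probability at most
#' `alpha` (method 2, "variant flagging"). A flagged variant occurs in the
#' database more often than its claimed disease model predicts: the
#' genotype-phenotype association, the prevalence estimate, the penetrance
#' or the mode of inheritance warrants re-examination.
#'
#' Tail probabilities are reported raw; no multiple-testing adjustment is
#' applied. The number of tests performed is attached to the report so
#' callers can adjust if desired.
#'
#' @param database Data frame of database variants with `count` or
#'   `frequency` columns ([load_database()]).
#' @param model A [disease_model()].
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()].
#' @param alpha Flagging significance level; default 0.05.
#' @return A data frame of class `"flag_report"`, one row per record, with
#'   `observed_count`, `tail_probability` and `flagged` columns; the number
#'   of tests is attached as attribute `"n_tests"`.
#' @examples
#' db <- data.frame(chrom = "1", pos = 100, ref = "A", alt = "T",
#'                  count = 2L, frequency = 0.02)
#' flag_database_variants(db, disease_model(1e-4, "AR"), individuals = 50)
#' @export
flag_database_variants <- function(database, model, individuals,
                                   alpha = 0.05) {
  stopifnot(inherits(model, "disease_model"))
  check_variant_frame(database, "database")
  check_probability(alpha, "alpha", open_low = TRUE, open_high = TRUE)
  db <- as_database_spec(individuals)

  q <- q_from_prevalence(model)
  q_eff <- effective_sampling_freq(q, model)

  counts <- if ("count" %in% names(database) && !anyNA(database$count)) {
    as.integer(database$count)
  } else if ("frequency" %in% names(database)) {
    vapply(database$frequency, frequency_to_count, integer(1), db)
  } else {
    stop("database records carry neither counts nor frequencies",
         call. = FALSE)
  }
  if (any(counts > db$chromosomes)) {
    stop("database allele count exceeds 2c = ", db$chromosomes,
         call. = FALSE)
  }
  probs <- stats::pbinom(counts - 1, size = db$chromosomes, prob = q_eff,
                         lower.tail = FALSE)

  out <- data.frame(
    chrom = database$chrom,
    pos = database$pos,
    id = if ("id" %in% names(database)) database$id else NA_character_,
    ref = database$ref,
    alt = database$alt,
    observed_count = counts,
    db_frequency = counts / db$chromosomes,
    tail_probability = probs,
    flagged = probs <= alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "model") <- model
  attr(out, "q_effective") <- q_eff
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("flag_report", "data.frame")
  out
}

#' @export
print.flag_report <- function(x, ...) {
  cat("Variant flagging report\n")
  if (!is.null(attr(x, "q_effective"))) {
    cat(sprintf("  q (effective) = %s, alpha = %s, %d test(s), %d flagged\n",
                format(signif(attr(x, "q_effective"), 4)),
                format(attr(x, "alpha")), attr(x, "n_tests"),
                sum(x$flagged)))
  }
  print.data.frame(x, ...)
  invisible(x)
}

#' Fraction of the database usable for filtering at a threshold
#'
#' The share of database records whose frequency is strictly above the
#' threshold — the variants "available" to remove candidates. At threshold 0
#' (absence approach) every segregating record is available; raising the
#' threshold trades false negatives for false positives.
#'
#' @param database Data frame of database variants with a `frequency` column.
#' @param threshold Frequency threshold in \[0, 1\] (e.g. 0.01 for the static
#'   approach, or `tv_frequency` from [tv_threshold()]).
#' @return The proportion of records with `frequency > threshold`.
#' @examples
#' db <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "T",
#'                  frequency = c(0.005, 0.02, 0.2, 0.6))
#' database_availability(db, 0.01)  # 0.75
#' @export
database_availability <- function(database, threshold) {
  check_variant_frame(database, "database")
  check_probability(threshold, "threshold")
  if (nrow(database) == 0L) {
    stop("database is empty: availability is undefined", call. = FALSE)
  }
  if (!"frequency" %in% names(database) || anyNA(database$frequency)) {
    stop("database records need frequencies", call. = FALSE)
  }
  mean(database$frequency > threshold)
}

#' Write a filtering or flagging report as annotated TSV
#'
#' Writes one row per variant, preceded by commented header lines (`# key:
#' value`) recording the model parameters, the threshold and the number of
#' tests, so a report is self-describing and byte-identical for identical
#' inputs.
#'
#' @param report A `"filter_report"` or `"flag_report"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  hdr <- c(sprintf("# afquantile report (%s)",
                   if (inherits(report, "filter_report")) "variant filtering"
                   else "variant flagging"))
  model <- attr(report, "model")
  if (!is.null(model)) {
    hdr <- c(hdr, sprintf(
      "# model: prevalence=%s inheritance=%s penetrance=%s detectance=%s situation=%s",
      format(model$prevalence), model$inheritance,
      format(model$penetrance), format(model$detectance), model$situation))
  }
  tv <- attr(report, "tv")
  if (!is.null(tv)) {
    hdr <- c(hdr, sprintf("# threshold: Tv=%d/%d (frequency %s, level %s)",
                          tv$tv_count, tv$chromosomes,
                          format(signif(tv$tv_frequency, 4)),
                          format(tv$level)))
  }
  if (inherits(report, "flag_report")) {
    hdr <- c(hdr, sprintf("# alpha: %s", format(attr(report, "alpha"))),
             sprintf("# tests: %d", attr(report, "n_tests")))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(report), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_variant_frame <- function(x, name) {
  if (!is.data.frame(x)) {
    stop(name, " must be a data frame of variant records", call. = FALSE)
  }
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop(name, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
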