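#' Threshold lookup table over prevalence and database-size grids
#'
#' Computes the quantile-based threshold Tv for every combination of disease
#' prevalence and database size, as a ready-made reference for users who do
#' not want to run per-disease calculations. Default grids cover prevalences
#' 1/n for n = 1000 to 100,000 in steps of 1000 and database sizes typical
#' of public catalogs (50 to 10,000 individuals, including the 2504 of
#' 1000 Genomes phase 3). The default sampling situation is "b"
#' (non-diseased individuals only), appropriate for consent-restricted human
#' databases.
#'
#' Grid cells whose disease model is infeasible (per-locus case fraction
#' >= 1) are reported as `NA` rather than aborting the table.
#'
#' @param inheritance `"AR"` or `"AD"`.
#' @param prevalences Ordered vector of prevalences (strictly monotone).
#' @param database_sizes Ordered vector of diploid individual counts
#'   (strictly monotone).
#' @param level Quantile level; default 0.95.
#' @param situation `"a"` or `"b"`; default `"b"`.
#' @param penetrance,detectance Model parameters, defaults 1.
#' @param what `"frequency"` (Tv as `tv_count / 2c`) or `"count"` (the
#'   integer Tv).
#' @return A numeric matrix of class `"tv_table"` with one row per
#'   prevalence and one column per database size; the generating parameters
#'   are attached as attributes.
#' @examples
#' tv_table("AR", prevalences = c(1e-4, 1e-5),
#'          database_sizes = c(50, 2504), situation = "a")
#' @export
tv_table <- function(inheritance = c("AR", "AD"),
                     prevalences = 1 / seq(1000, 100000, by = 1000),
                     database_sizes = c(50, 100, 500, 1000, 2504, 5000,
                                        10000),
                     level = 0.95,
                     situation = "b",
                     penetrance = 1,
                     detectance = 1,
                     what = c("frequency", "count")) {
  inheritance <- match.arg(toupper(inheritance[1]), c("AR", "AD"))
  what <- match.arg(what)
  if (length(prevalences) == 0L || length(database_sizes) == 0L) {
    stop("prevalence and database-size grids must be non-empty",
         call. = FALSE)
  }
  if (any(diff(prevalences) == 0) ||
      !(all(diff(prevalences) > 0) || all(diff(prevalences) < 0))) {
    stop("prevalences must be strictly monotone", call. = FALSE)
  }
  if (any(diff(database_sizes) <= 0)) {
    stop("database_sizes must be strictly increasing", call. = FALSE)
  }

  m <- matrix(NA_real_, nrow = length(prevalences),
              ncol = length(database_sizes),
              dimnames = list(format_prevalence(prevalences),
                              as.character(database_sizes)))
  counts <- m
  for (i in seq_along(prevalences)) {
    model <- tryCatch(
      disease_model(prevalences[i], inheritance, penetrance = penetrance,
                    detectance = detectance, situation = situation),
      error = function(e) NULL)
    if (is.null(model)) next  # infeasible cell stays NA
    for (j in seq_along(database_sizes)) {
      tv <- predict(model, individuals = database_sizes[j], level = level)
      m[i, j] <- tv$tv_frequency
      counts[i, j] <- tv$tv_count
    }
  }
  out <- if (what == "frequency") m else counts
  attr(out, "counts") <- counts
  attr(out, "prevalences") <- prevalences
  attr(out, "database_sizes") <- database_sizes
  attr(out, "inheritance") <- inheritance
  attr(out, "level") <- level
  attr(out, "situation") <- situation
  attr(out, "penetrance") <- penetrance
  attr(out, "detectance") <- detectance
  attr(out, "what") <- what
  class(out) <- c("tv_table", "matrix")
  out
}

#' @export
print.tv_table <- function(x, ...) {
  cat(sprintf(
    "Tv lookup table (%s): %s, level %s, situation %s, Ppt %s, Pdt %s\n",
    attr(x, "what"), attr(x, "inheritance"), format(attr(x, "level")),
    attr(x, "situation"), format(attr(x, "penetrance")),
    format(attr(x, "detectance"))))
  cat("rows: prevalence; columns: database size (diploid individuals)\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(signif(y, 4), ...)
  invisible(x)
}

#' Write a threshold lookup table to TSV or CSV
#'
#' Writes the table with a commented header recording the generating
#' parameters, a label column giving each prevalence both as 1/n and as a
#' decimal, and one column per database size. Frequencies are printed to 4
#' significant digits with the exact integer count in parentheses, so rounded
#' frequencies are never ambiguous. Infeasible cells are written as `NA` and
#' noted in a footer line.
#'
#' @param x A `"tv_table"`.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_tv_table <- function(x, path, format = c("tsv", "csv")) {
  stopifnot(inherits(x, "tv_table"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  counts <- attr(x, "counts")
  prev <- attr(x, "prevalences")

  hdr <- c(
    "# Tv lookup table",
    sprintf("# inheritance: %s", attr(x, "inheritance")),
    sprintf("# level: %s", format(attr(x, "level"))),
    sprintf("# situation: %s", attr(x, "situation")),
    sprintf("# penetrance: %s", format(attr(x, "penetrance"))),
    sprintf("# detectance: %s", format(attr(x, "detectance"))),
    "# cell format: Tv frequency (Tv allele count); NA = infeasible model")

  body <- matrix("NA", nrow = nrow(x), ncol = ncol(x))
  ok <- !is.na(unclass(x))
  body[ok] <- sprintf("%s (%d)", format(signif(unclass(x)[ok], 4)),
                      as.integer(counts[ok]))
  lines <- c(
    paste(c("prevalence", "prevalence_decimal", colnames(x)),
          collapse = sep),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], format(prev[i]), body[i, ]), collapse = sep)
    }, character(1))
  )
  if (any(!ok)) {
    lines <- c(lines,
               sprintf("# %d infeasible cell(s) reported as NA", sum(!ok)))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# prevalence as "1/n" when n is a round number, else as a decimal
format_prevalence <- function(p) {
  n <- 1 / p
  ifelse(abs(n - round(n)) < 1e-9,
         sprintf("1/%d", as.integer(round(n))),
         format(p))
}
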