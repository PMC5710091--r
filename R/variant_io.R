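#' Load a frequency-annotated variant database
#'
#' Reads a variant database from VCF (allele frequencies taken from the INFO
#' `AF` field, or computed as `AC/AN`) or from a TSV frequency table with
#' header columns `chrom`, `pos`, `ref`, `alt` and a `count` (or
#' `allele_count`/`ac`) or `frequency` (or `freq`/`af`) column. Multi-allelic
#' VCF sites are decomposed into one record per alternate allele, each with
#' its own frequency. Records with frequency 0 are dropped: an allele that
#' does not segregate in the database cannot filter anything.
#'
#' When a VCF carries `AN` and it disagrees with `2 * individuals`, the
#' file's `AN` takes precedence for the count/frequency conversion, with a
#' warning.
#'
#' @param path Path to the database file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @param individuals Database size in diploid individuals, or a
#'   [database_spec()]; used to interconvert counts and frequencies.
#' @return A data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `count`, `frequency`, one row per bi-allelic record.
#' @seealso [load_candidates()], [filter_candidates()]
#' @export
load_database <- function(path, format = c("auto", "vcf", "tsv"),
                          individuals = NULL) {
  format <- match.arg(format)
  db <- if (is.null(individuals)) NULL else as_database_spec(individuals)
  rec <- read_variant_file(path, format, db, require_freq = TRUE)
  rec[!is.na(rec$frequency) & rec$frequency > 0, , drop = FALSE]
}

#' Load a candidate-variant list
#'
#' Reads the variants discovered in a sequencing study, from VCF or from a
#' TSV with header columns `chrom`, `pos`, `ref`, `alt` (and optionally
#' `id`). Frequency annotations are not required — candidates are matched
#' against the database by `(chrom, pos, ref, alt)`.
#'
#' @inheritParams load_database
#' @return A data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (plus `count`/`frequency` if present in the file).
#' @export
load_candidates <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  read_variant_file(path, format, db = NULL, require_freq = FALSE)
}

read_variant_file <- function(path, format, db, require_freq) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") {
    read_variant_vcf(path, db, require_freq)
  } else {
    read_variant_tsv(path, db, require_freq)
  }
}

read_variant_vcf <- function(path, db, require_freq) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(empty_variant_frame())
  }
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  af <- suppressWarnings(vcfR::extract.info(vcf, element = "AF"))
  ac <- suppressWarnings(vcfR::extract.info(vcf, element = "AC"))
  an <- suppressWarnings(vcfR::extract.info(vcf, element = "AN",
                                            as.numeric = TRUE))
  n <- nrow(fix)
  if (is.null(af)) af <- rep(NA_character_, n)
  if (is.null(ac)) ac <- rep(NA_character_, n)
  if (is.null(an)) an <- rep(NA_real_, n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    k <- length(alts)
    afs <- split_numeric(af[i], k)
    acs <- split_numeric(ac[i], k)
    an_i <- an[i]
    freq <- afs
    count <- acs
    if (all(is.na(freq)) && !all(is.na(count)) && !is.na(an_i)) {
      freq <- count / an_i
    }
    if (require_freq && all(is.na(freq))) {
      stop("no AF (or AC+AN) annotation for database record ",
           fix[i, "CHROM"], ":", fix[i, "POS"], " ",
           fix[i, "REF"], ">", fix[i, "ALT"], call. = FALSE)
    }
    chroms_i <- NA_real_
    if (!is.na(an_i)) {
      if (!is.null(db) && an_i != db$chromosomes) {
        warning("AN = ", an_i, " at ", fix[i, "CHROM"], ":", fix[i, "POS"],
                " differs from 2c = ", db$chromosomes,
                "; AN takes precedence", call. = FALSE)
      }
      chroms_i <- an_i
    } else if (!is.null(db)) {
      chroms_i <- db$chromosomes
    }
    if (all(is.na(count)) && !all(is.na(freq)) && !is.na(chroms_i)) {
      count <- as.integer(floor(freq * chroms_i + 0.5))
    }
    out[[i]] <- data.frame(
      chrom = rep(fix[i, "CHROM"], k),
      pos = rep(as.integer(fix[i, "POS"]), k),
      id = rep(na_if_dot(fix[i, "ID"]), k),
      ref = rep(fix[i, "REF"], k),
      alt = alts,
      count = as.integer(count),
      frequency = as.numeric(freq),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

read_variant_tsv <- function(path, db, require_freq) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  if (nrow(tab) == 0L) {
    return(empty_variant_frame())
  }
  names(tab) <- tolower(names(tab))
  need <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("TSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  count_col <- intersect(c("count", "allele_count", "ac"), names(tab))[1]
  freq_col <- intersect(c("frequency", "freq", "af"), names(tab))[1]
  count <- if (!is.na(count_col)) as.integer(tab[[count_col]])
           else rep(NA_integer_, nrow(tab))
  freq <- if (!is.na(freq_col)) as.numeric(tab[[freq_col]])
          else rep(NA_real_, nrow(tab))
  if (require_freq && all(is.na(count)) && all(is.na(freq))) {
    stop("TSV database needs a count or frequency column", call. = FALSE)
  }
  if (!is.null(db)) {
    fill <- is.na(freq) & !is.na(count)
    freq[fill] <- count[fill] / db$chromosomes
    fill <- is.na(count) & !is.na(freq)
    count[fill] <- as.integer(floor(freq[fill] * db$chromosomes + 0.5))
    both <- !is.na(count) & !is.na(freq)
    off <- both & abs(freq - count / db$chromosomes) >= 1 / (2 * db$chromosomes)
    if (any(off)) {
      warning(sum(off), " record(s) have a frequency inconsistent with ",
              "their count at 2c = ", db$chromosomes, call. = FALSE)
    }
  }
  data.frame(
    chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos),
    id = if ("id" %in% names(tab)) na_if_dot(as.character(tab$id))
         else rep(NA_character_, nrow(tab)),
    ref = as.character(tab$ref),
    alt = as.character(tab$alt),
    count = count,
    frequency = freq,
    stringsAsFactors = FALSE
  )
}

empty_variant_frame <- function() {
  data.frame(chrom = character(), pos = integer(), id = character(),
             ref = character(), alt = character(), count = integer(),
             frequency = numeric(), stringsAsFactors = FALSE)
}

split_numeric <- function(x, k) {
  if (is.na(x)) return(rep(NA_real_, k))
  vals <- suppressWarnings(as.numeric(strsplit(as.character(x), ",",
                                               fixed = TRUE)[[1]]))
  if (length(vals) != k) rep(NA_real_, k) else vals
}

na_if_dot <- function(x) {
  x[!is.na(x) & x == "."] <- NA_character_
  x
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}
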