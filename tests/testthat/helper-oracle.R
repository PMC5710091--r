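# Independent brute-force binomial oracle: exhaustive log-space pmf
# summation, deliberately not using pbinom/qbinom so it can cross-check them.
oracle_pmf <- function(k, n, p) {
  if (p == 0) return(as.numeric(k == 0))
  if (p == 1) return(as.numeric(k == n))
  exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
}

oracle_cdf <- function(k, n, p) {
  if (k < 0) return(0)
  sum(oracle_pmf(0:min(k, n), n, p))
}

oracle_quantile <- function(level, n, p) {
  cdf <- cumsum(oracle_pmf(0:n, n, p))
  min(which(cdf >= level)) - 1L
}

oracle_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(oracle_pmf(k:n, n, p))
}

# minimal frequency-annotated VCF for I/O tests
write_test_vcf <- function(path, body_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele Count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele Number\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    body_lines), path)
  path
}

vcf_line <- function(chrom, pos, id, ref, alt, info) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info), collapse = "\t")
}

# small in-memory variant frames for filtering tests
variant_frame <- function(pos, ref = "A", alt = "T", chrom = "1",
                          count = NULL, frequency = NULL, id = NULL) {
  n <- length(pos)
  out <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    stringsAsFactors = FALSE)
  if (!is.null(id)) out$id <- id
  if (!is.null(count)) out$count <- as.integer(count)
  if (!is.null(frequency)) out$frequency <- frequency
  out
}
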