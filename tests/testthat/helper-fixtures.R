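# Shared fixture builders for the test suite. All data are constructed in
# code or read from the package's plain-text extdata files.

extdata <- function(name) {
  system.file("extdata", name, package = "mosaicSNV", mustWork = TRUE)
}

read_table1_somatic <- function() {
  df <- utils::read.delim(extdata("table1_somatic_damaging.tsv"),
                          stringsAsFactors = FALSE)
  df$damaging <- flag_damaging(df$consequence, df$cadd)
  df
}

read_germline_fixture <- function() {
  utils::read.delim(extdata("germline_damaging_synthetic.tsv"),
                    stringsAsFactors = FALSE)
}

read_sfari_fixture <- function() {
  utils::read.delim(extdata("sfari_classes_synthetic.tsv"),
                    colClasses = "character")
}

# A minimal passing candidate call; override fields as needed.
make_call <- function(...) {
  base <- data.frame(
    subject = "S1", tissue = "BA9", chrom = "1", pos = 1000L,
    ref = "C", alt = "T", vaf = 0.05, depth = 500L, alt_count = 25L,
    eb_score = 30, caller = "single", end_read_only = FALSE,
    clean_support = TRUE, blat_second_avg = NA_real_,
    consequence = "missense_variant", cadd = 25, population_af = NA_real_,
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# Independent oracle: exact binomial upper tail by direct summation of the
# mass function (never uses pbinom).
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(x) stats::dbinom(x, n, p), numeric(1L)))
}

# Independent oracle: exact overlap-tail probability by full enumeration
# of all k-subsets of the pool.
overlap_tail_oracle <- function(pool, k, reference, observed) {
  subsets <- utils::combn(length(pool), k)
  in_ref <- pool %in% reference
  overlaps <- colSums(matrix(in_ref[subsets], nrow = k))
  mean(overlaps >= observed)
}
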