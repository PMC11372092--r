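# Readers and writers for the plain-text exchange formats used by the
# pipeline: GMT gene lists, error-model TSVs, long-format tables and VCF.

#' Read and write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1L), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a substitution error-model TSV
#'
#' Two columns, `class` and `rate`, one line per substitution class.
#'
#' @param path File path.
#' @return `read_error_model`: an [error_model()].
#' @export
read_error_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_columns(df, c("class", "rate"), "error model file")
  error_model(stats::setNames(df$rate, df$class))
}

#' @rdname read_error_model
#' @param model An [error_model()].
#' @export
write_error_model <- function(model, path) {
  stopifnot(inherits(model, "error_model"))
  utils::write.table(
    data.frame(class = names(model), rate = as.numeric(model)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidate somatic calls as a VCF file
#'
#' One file per (subject, tissue) call set is the pipeline convention;
#' this writer emits the rows it is given. INFO keys: `VAF`, `DP`, `ALTC`,
#' `EB`, `CADD`, `CSQ` and `CLR` (caller provenance).
#'
#' @param calls Call data frame (columns `chrom, pos, ref, alt, vaf,
#'   depth, alt_count, eb_score, cadd, consequence, caller`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  stop_if_not_columns(calls, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                               "alt_count", "eb_score", "cadd",
                               "consequence", "caller"), "calls")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaicSNV",
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=ALTC,Number=1,Type=Integer,Description="Alternate read count">',
    '##INFO=<ID=EB,Number=1,Type=Float,Description="Empirical Bayes score">',
    '##INFO=<ID=CADD,Number=1,Type=Float,Description="Phred-scaled CADD score">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence annotation">',
    '##INFO=<ID=CLR,Number=1,Type=String,Description="Caller provenance">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  info <- sprintf("VAF=%s;DP=%s;ALTC=%s;EB=%s;CADD=%s;CSQ=%s;CLR=%s",
                  fmt_num(round(calls$vaf, 6)), fmt_num(calls$depth),
                  fmt_num(calls$alt_count), fmt_num(round(calls$eb_score, 4)),
                  fmt_num(round(calls$cadd, 3)), calls$consequence,
                  calls$caller)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                  info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF of candidate calls written by [write_variant_vcf()]
#'
#' Uses the vcfR package for parsing.
#'
#' @param path VCF path.
#' @return A data frame `chrom, pos, ref, alt, vaf, depth, alt_count,
#'   eb_score, cadd, consequence, caller`.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variant_vcf requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key, as = as.numeric) {
    as(vcfR::extract.info(v, element = key))
  }
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    vaf = info_field("VAF"), depth = info_field("DP", as.integer),
    alt_count = info_field("ALTC", as.integer),
    eb_score = info_field("EB"), cadd = info_field("CADD"),
    consequence = info_field("CSQ", as.character),
    caller = info_field("CLR", as.character),
    stringsAsFactors = FALSE)
}
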