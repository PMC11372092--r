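# Amplicon validation against substitution-specific background error
# rates: exact binomial upper-tail tests, precision with Clopper-Pearson
# intervals, and cross-platform VAF concordance.

#' Collapse a substitution to its pyrimidine-context class
#'
#' Substitutions reported on a purine reference base are mapped to the
#' equivalent pyrimidine-context class (e.g. `G>A` to `C>T`), matching the
#' six classes of the background error model.
#'
#' @param substitution Character vector like `"C>T"` or `"G>A"`.
#' @return Character vector over the six canonical classes; `NA` for
#'   strings that are not single-base substitutions.
#' @examples
#' normalize_substitution(c("G>A", "A>C", "C>T"))
#' @export
normalize_substitution <- function(substitution) {
  x <- toupper(gsub("\\s", "", substitution))
  ref <- substr(x, 1L, 1L)
  alt <- substr(x, 3L, 3L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  ref2 <- ifelse(purine, comp[ref], ref)
  alt2 <- ifelse(purine, comp[alt], alt)
  out <- paste0(ref2, ">", alt2)
  out[!grepl("^[ACGT]>[ACGT]$", x) | ref == alt] <- NA_character_
  out
}

#' Validate amplicon observations against background error rates
#'
#' For each candidate, tests whether the observed alternate read count
#' exceeds what the substitution-specific background error rate would
#' produce: a one-sided exact binomial upper tail,
#' `p = P(X >= alt_count | depth, background rate)`. A candidate is
#' validated iff `p < alpha`. Replicate observations of one candidate
#' (same variant key) are combined by summing depths and alternate counts
#' before testing.
#'
#' @param obs Data frame with columns `class` (one of the six canonical
#'   substitution classes, or a raw substitution that will be
#'   strand-collapsed), `depth`, `alt_count`, and optionally the variant
#'   identity columns `subject, chrom, pos, ref, alt` used to combine
#'   replicates.
#' @param error A background [error_model()].
#' @param alpha Significance level (default 0.05).
#' @param combine_replicates Sum depths/alt counts over rows sharing one
#'   variant key before testing (default `TRUE` when identity columns are
#'   present).
#' @return A data frame with one row per tested candidate: identity
#'   columns (if present), `class`, `depth`, `alt_count`, `observed_vaf`,
#'   `background_rate`, `p_value`, `validated`.
#' @export
validate_calls <- function(obs, error = default_error_model(), alpha = 0.05,
                           combine_replicates = TRUE) {
  stop_if_not_columns(obs, c("class", "depth", "alt_count"), "obs")
  stopifnot(alpha > 0, alpha < 1)
  id_cols <- intersect(c("subject", "chrom", "pos", "ref", "alt"), names(obs))
  cls <- normalize_substitution(obs$class)
  unknown <- unique(obs$class[is.na(cls)])
  if (length(unknown) > 0L) {
    stop("unknown substitution class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obs$class <- cls
  if (combine_replicates && length(id_cols) == 5L && anyDuplicated(variant_key(obs))) {
    key <- variant_key(obs)
    depth <- tapply(obs$depth, key, sum)
    altc <- tapply(obs$alt_count, key, sum)
    keys <- unique(key)
    combined <- obs[match(keys, key), c(id_cols, "class"), drop = FALSE]
    combined$depth <- as.integer(depth[keys])
    combined$alt_count <- as.integer(altc[keys])
    obs <- combined
  }
  if (any(obs$alt_count > obs$depth)) {
    stop("alt_count exceeds depth", call. = FALSE)
  }
  rate <- unclass(error)[obs$class]
  p <- binomial_upper_tail(obs$alt_count, obs$depth, rate)
  zero_depth <- obs$depth == 0
  if (any(zero_depth)) {
    warning(sum(zero_depth), " observation(s) with zero depth: not validated")
    p[zero_depth] <- 1
  }
  out <- obs[, c(id_cols, "class", "depth", "alt_count"), drop = FALSE]
  out$observed_vaf <- ifelse(obs$depth > 0, obs$alt_count / obs$depth, NA_real_)
  out$background_rate <- unname(rate)
  out$p_value <- p
  out$validated <- p < alpha
  rownames(out) <- NULL
  out
}

# Exact one-sided upper-tail binomial probability P(X >= k | n, p).
binomial_upper_tail <- function(k, n, p) {
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Precision of a validation run with exact binomial confidence interval
#'
#' @param results A data frame from [validate_calls()] (needs a logical
#'   `validated` column), or a logical vector.
#' @param conf_level Confidence level of the Clopper-Pearson interval.
#' @return A list: `precision`, `ci_low`, `ci_high`, `n_validated`,
#'   `n_total`.
#' @export
compute_precision <- function(results, conf_level = 0.95) {
  validated <- if (is.data.frame(results)) {
    stop_if_not_columns(results, "validated", "results")
    results$validated
  } else {
    results
  }
  stopifnot(is.logical(validated))
  if (length(validated) == 0L) stop("no validation results", call. = FALSE)
  k <- sum(validated)
  n <- length(validated)
  bt <- stats::binom.test(k, n, conf.level = conf_level)
  list(precision = k / n, ci_low = bt$conf.int[1], ci_high = bt$conf.int[2],
       n_validated = k, n_total = n)
}

#' Cross-platform VAF concordance
#'
#' Pearson correlation between per-variant VAFs measured on two platforms,
#' plus a per-pair fold-change and absolute-difference table.
#'
#' @param vaf1,vaf2 Numeric VAF vectors of equal length (one entry per
#'   shared variant).
#' @return A list: `correlation` (`NA` with a warning if either vector has
#'   zero variance or fewer than 3 pairs are given) and `pairs` (data frame
#'   `vaf1, vaf2, fold_change, abs_diff`; fold change is `NA` when exactly
#'   one VAF is zero and 1 when both are zero).
#' @export
vaf_concordance <- function(vaf1, vaf2) {
  stopifnot(is.numeric(vaf1), is.numeric(vaf2), length(vaf1) == length(vaf2))
  lo <- pmin(vaf1, vaf2)
  hi <- pmax(vaf1, vaf2)
  fold <- ifelse(hi == 0, 1, ifelse(lo == 0, NA_real_, hi / lo))
  pairs <- data.frame(vaf1 = vaf1, vaf2 = vaf2, fold_change = fold,
                      abs_diff = abs(vaf1 - vaf2))
  correlation <- if (length(vaf1) < 3L) {
    warning("fewer than 3 pairs: correlation not computed")
    NA_real_
  } else if (stats::sd(vaf1) == 0 || stats::sd(vaf2) == 0) {
    warning("zero-variance input: correlation undefined")
    NA_real_
  } else {
    stats::cor(vaf1, vaf2)
  }
  list(correlation = correlation, pairs = pairs)
}
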