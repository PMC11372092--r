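# Damaging gene-set construction (somatic + germline), carrier tables and
# exact-test risk assessment.

#' Select per-subject damaging germline gene sets
#'
#' A (subject, gene) pair is selected iff: total depth >= 100, allele
#' fraction >= 30% (the within-sample alternate-read fraction, a
#' heterozygous-call heuristic), ExAC population allele frequency < 0.02%
#' (missing treated as 0 — a novel variant cannot be common), CADD > 20,
#' the gene is SFARI class 1-3, and the consequence is in the `LOF_MIS`
#' category.
#'
#' @param calls Germline call data frame: `subject, gene, depth,
#'   allele_fraction, cadd, exac_af, consequence`.
#' @param sfari Data frame `gene, class` with class labels in
#'   `{"1","2","3","other"}` (numeric classes allowed). Genes absent from
#'   the table are treated as class `"other"` and excluded.
#' @param depth_min,af_min,exac_max,cadd_min Selection thresholds.
#' @return A data frame `subject, gene` of selected pairs (deduplicated).
#' @export
select_damaging_germline <- function(calls, sfari, depth_min = 100,
                                     af_min = 0.30, exac_max = 0.0002,
                                     cadd_min = 20) {
  stop_if_not_columns(calls, c("subject", "gene", "depth", "allele_fraction",
                               "cadd", "exac_af", "consequence"), "calls")
  stop_if_not_columns(sfari, c("gene", "class"), "sfari")
  sfari_class <- as.character(sfari$class)[match(calls$gene, sfari$gene)]
  sfari_class[is.na(sfari_class)] <- "other"
  exac <- ifelse(is.na(calls$exac_af), 0, calls$exac_af)
  keep <- calls$depth >= depth_min &
    calls$allele_fraction >= af_min &
    exac < exac_max &
    !is.na(calls$cadd) & calls$cadd > cadd_min &
    sfari_class %in% c("1", "2", "3") &
    classify_consequence(calls$consequence) == "LOF_MIS"
  unique(calls[keep, c("subject", "gene"), drop = FALSE])
}

#' Select per-subject damaging somatic gene sets
#'
#' A (subject, gene) pair is selected iff the call is flagged damaging
#' (`LOF_MIS` consequence with CADD > 20) and was validated by ultradeep
#' targeted amplicon sequencing.
#'
#' @param calls Somatic call data frame with columns `subject`, `gene`,
#'   `damaging` (logical) and `validated` (logical). Use [flag_damaging()]
#'   and [validate_calls()] to derive the flags.
#' @return A data frame `subject, gene` of selected pairs (deduplicated).
#' @export
select_damaging_somatic <- function(calls) {
  stop_if_not_columns(calls, c("subject", "gene", "damaging", "validated"),
                      "calls")
  keep <- calls$damaging & calls$validated
  out <- unique(calls[keep, c("subject", "gene"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Merge somatic and germline damaging gene sets for one group
#'
#' Union of distinct gene symbols across subjects and across both mutation
#' sources, annotating each gene with its source(s).
#'
#' @param somatic,germline Data frames `subject, gene` from
#'   [select_damaging_somatic()] / [select_damaging_germline()], already
#'   restricted to one diagnosis group.
#' @return A data frame `gene, source` with source in
#'   `{"somatic", "germline", "somatic+germline"}`.
#' @export
merge_genesets <- function(somatic, germline) {
  s <- unique(somatic$gene %||% character())
  g <- unique(germline$gene %||% character())
  genes <- sort(union(s, g))
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  source <- ifelse(genes %in% s & genes %in% g, "somatic+germline",
                   ifelse(genes %in% s, "somatic", "germline"))
  data.frame(gene = genes, source = source, stringsAsFactors = FALSE)
}

#' Build the 2x2 carrier table for a case-control cohort
#'
#' A subject is a carrier iff it holds at least one selected gene under
#' the chosen mode: somatic only, germline only, or either (merged).
#'
#' @param somatic,germline Data frames `subject, gene` of selected pairs
#'   (whole cohort).
#' @param cohort Cohort table with columns `subject` and `diagnosis`.
#' @param mode `"somatic_only"`, `"germline_only"` or `"merged"`.
#' @return A 2x2 integer matrix, rows = case/control, columns =
#'   carrier/non-carrier; cells sum to the cohort size.
#' @export
carrier_table <- function(somatic, germline, cohort,
                          mode = c("merged", "somatic_only", "germline_only")) {
  mode <- match.arg(mode)
  stop_if_not_columns(cohort, c("subject", "diagnosis"), "cohort")
  if (anyNA(cohort$diagnosis)) {
    stop("subject(s) missing diagnosis: ",
         paste(cohort$subject[is.na(cohort$diagnosis)], collapse = ", "),
         call. = FALSE)
  }
  carriers <- switch(mode,
    somatic_only = unique(somatic$subject),
    germline_only = unique(germline$subject),
    merged = union(unique(somatic$subject), unique(germline$subject)))
  is_case <- cohort$diagnosis == "ASD"
  is_carrier <- cohort$subject %in% carriers
  m <- matrix(c(sum(is_case & is_carrier), sum(is_case & !is_carrier),
                sum(!is_case & is_carrier), sum(!is_case & !is_carrier)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non_carrier")))
  storage.mode(m) <- "integer"
  m
}

#' Exact-test risk assessment of a 2x2 carrier table
#'
#' Two-sided Fisher exact p-value (summation of all tables with point
#' probability at most that of the observed table), the conditional
#' maximum-likelihood odds ratio with its exact 95% confidence interval,
#' and, for transparency, the sample (cross-product) odds ratio.
#'
#' @param table A 2x2 matrix of non-negative integer counts
#'   (rows = groups, columns = carrier status).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `contingency_result`: a list with `table`,
#'   `odds_ratio` (conditional MLE; `NA` when a margin is zero),
#'   `sample_odds_ratio`, `ci_low`, `ci_high`, `p_two_sided`.
#' @examples
#' fisher_risk(matrix(c(14, 10, 8, 23), 2, byrow = TRUE))
#' @export
fisher_risk <- function(table, conf_level = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(structure(list(table = table, odds_ratio = NA_real_,
                          sample_odds_ratio = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_two_sided = 1),
                     class = "contingency_result"))
  }
  ft <- stats::fisher.test(table, conf.level = conf_level)
  sample_or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(table = table, odds_ratio = unname(ft$estimate),
                 sample_odds_ratio = sample_or,
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 p_two_sided = ft$p.value),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 carrier table:\n")
  print(x$table)
  cat(sprintf("odds ratio (conditional MLE) = %.3f [%.3f, %.3f]\n",
              x$odds_ratio, x$ci_low, x$ci_high))
  cat(sprintf("sample odds ratio = %.3f\n", x$sample_odds_ratio))
  cat(sprintf("two-sided Fisher exact p = %.4g\n", x$p_two_sided))
  invisible(x)
}
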