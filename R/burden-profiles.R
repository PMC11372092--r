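# Mutational burden summaries: per-subject-region counts, group
# comparisons, transcript-length normalisation and genome-scale
# extrapolation.

#' Summarise somatic burden per subject and brain region
#'
#' Builds one row per subject-region pair — including explicit zero rows
#' for regions with no surviving calls — and group means with standard
#' errors over subject-region rows (so "per single brain region" averages
#' weight subject-region pairs, not subjects).
#'
#' @param calls Filtered somatic call data frame with columns `subject`,
#'   `tissue`, `vaf` and `consequence`; peripheral rows should be removed
#'   beforehand.
#' @param cohort Cohort table from [generate_cohort()] (columns `subject`,
#'   `diagnosis`, `regions`).
#' @return A list with `table` (columns `subject, diagnosis, region,
#'   snv_count, mean_vaf, n_lof_mis, n_syn`) and `group_summary` (columns
#'   `diagnosis, mean_snv_count, se_snv_count, n_subject_regions`).
#' @export
summarize_burden <- function(calls, cohort) {
  stop_if_not_columns(cohort, c("subject", "diagnosis", "regions"), "cohort")
  region_lists <- cohort_regions(cohort)
  grid <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    data.frame(subject = cohort$subject[i], diagnosis = cohort$diagnosis[i],
               region = region_lists[[i]], stringsAsFactors = FALSE)
  }))
  if (nrow(calls) > 0L) {
    stop_if_not_columns(calls, c("subject", "tissue", "vaf", "consequence"),
                        "calls")
    known <- paste(grid$subject, grid$region)
    seen <- paste(calls$subject, calls$tissue)
    bad <- unique(calls$tissue[!seen %in% known])
    if (length(bad) > 0L) {
      stop("call region(s) absent from cohort: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    category <- classify_consequence(calls$consequence)
    idx <- match(seen, known)
    grid$snv_count <- tabulate(idx, nbins = nrow(grid))
    sum_by <- function(x) {
      v <- rep(0, nrow(grid))
      s <- tapply(x, idx, sum)
      v[as.integer(names(s))] <- s
      v
    }
    grid$mean_vaf <- ifelse(grid$snv_count > 0,
                            sum_by(calls$vaf) / grid$snv_count, NA_real_)
    grid$n_lof_mis <- as.integer(sum_by(category == "LOF_MIS"))
    grid$n_syn <- as.integer(sum_by(category == "SYN"))
  } else {
    grid$snv_count <- 0L
    grid$mean_vaf <- NA_real_
    grid$n_lof_mis <- 0L
    grid$n_syn <- 0L
  }
  groups <- unique(grid$diagnosis)
  group_summary <- do.call(rbind, lapply(groups, function(g) {
    v <- grid$snv_count[grid$diagnosis == g]
    data.frame(diagnosis = g, mean_snv_count = mean(v),
               se_snv_count = stats::sd(v) / sqrt(length(v)),
               n_subject_regions = length(v), stringsAsFactors = FALSE)
  }))
  list(table = grid, group_summary = group_summary)
}

#' Compare burden (or any numeric measure) between two groups
#'
#' @param values_a,values_b Numeric vectors.
#' @param test `"students_t"` (two-sample Student's t, equal variances) or
#'   `"wilcoxon"` (two-sided rank-sum).
#' @return A list: `statistic`, `p_value` (two-sided), `mean_a`, `mean_b`.
#'   Zero variance in both groups with equal means yields `p_value = 1`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("students_t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "students_t") {
    stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
    degenerate <- stats::sd(values_a) == 0 && stats::sd(values_b) == 0
    if (degenerate && mean(values_a) == mean(values_b)) {
      return(list(statistic = 0, p_value = 1,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
    }
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  } else {
    stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Extrapolate a per-exome-region SNV count to genome scale
#'
#' Linear scaling from the exome footprint (~75 Mb) to the genome
#' (~3 Gb): `count * genome_bp / exome_bp`.
#'
#' @param count_per_exome_region Observed SNVs per exome per region.
#' @param exome_bp Exome footprint in base pairs.
#' @param genome_bp Genome size in base pairs.
#' @return Extrapolated genome-scale count.
#' @examples
#' extrapolate_genome(2.4) # 96
#' @export
extrapolate_genome <- function(count_per_exome_region, exome_bp = 75e6,
                               genome_bp = 3e9) {
  stopifnot(is.numeric(count_per_exome_region), count_per_exome_region >= 0)
  if (exome_bp <= 0 || genome_bp <= 0) {
    stop("exome_bp and genome_bp must be positive", call. = FALSE)
  }
  count_per_exome_region * genome_bp / exome_bp
}

#' Transcript-length-normalised mutation burden by consequence category
#'
#' Per mutated gene: mutations per kilobase of transcript, separately for
#' the `LOF_MIS` and `SYN` categories, with a two-sided Wilcoxon rank-sum
#' comparison of the per-gene rates between the two category gene sets.
#'
#' @param calls Call data frame with columns `gene` and `consequence`.
#' @param transcript_lengths Named numeric vector, gene symbol to
#'   canonical-transcript length in bp.
#' @return A list: `per_gene` (data frame `gene, category, n_mutations,
#'   transcript_bp, rate_per_kb`) and `wilcoxon_p` (`NA` with a warning
#'   when either category has no mutated genes).
#' @export
length_normalized_burden <- function(calls, transcript_lengths) {
  stop_if_not_columns(calls, c("gene", "consequence"), "calls")
  stopifnot(is.numeric(transcript_lengths), !is.null(names(transcript_lengths)))
  category <- classify_consequence(calls$consequence)
  keep <- category %in% c("LOF_MIS", "SYN")
  calls <- calls[keep, , drop = FALSE]
  category <- category[keep]
  missing <- setdiff(unique(calls$gene), names(transcript_lengths))
  if (length(missing) > 0L) {
    stop("no transcript length for gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(calls) == 0L) {
    warning("no LOF_MIS or SYN calls: comparison skipped")
    return(list(per_gene = data.frame(gene = character(),
                                      category = character(),
                                      n_mutations = integer(),
                                      transcript_bp = numeric(),
                                      rate_per_kb = numeric(),
                                      stringsAsFactors = FALSE),
                wilcoxon_p = NA_real_))
  }
  key <- paste(calls$gene, category, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  per_gene <- data.frame(
    gene = vapply(parts, `[`, character(1L), 1L),
    category = vapply(parts, `[`, character(1L), 2L),
    n_mutations = as.integer(counts), stringsAsFactors = FALSE)
  per_gene$transcript_bp <- unname(transcript_lengths[per_gene$gene])
  per_gene$rate_per_kb <- per_gene$n_mutations * 1000 / per_gene$transcript_bp
  a <- per_gene$rate_per_kb[per_gene$category == "LOF_MIS"]
  b <- per_gene$rate_per_kb[per_gene$category == "SYN"]
  wilcoxon_p <- if (length(a) == 0L || length(b) == 0L) {
    warning("a consequence category has no mutated genes: comparison skipped")
    NA_real_
  } else {
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  list(per_gene = per_gene, wilcoxon_p = wilcoxon_p)
}
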