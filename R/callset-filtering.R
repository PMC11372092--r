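# Post-call filter cascade for candidate somatic SNVs: paired/unpaired
# thresholds, multi-region pseudoreplicate rescue, barcode-sequencing
# concordance, and consequence/damaging classification.

#' Filter thresholds for the somatic post-call cascade
#'
#' All thresholds follow the calling protocol: paired calls are excluded at
#' VAF >= 20% and EBscore <= 5; unpaired (brain-only) calls additionally
#' require depth >= 300 and VAF < 10%; barcode-sequencing concordance
#' requires > 4 supporting barcodes, a WES/BCDseq VAF fold change <= 10 and
#' an absolute VAF difference <= 5% in every contributing region; damaging
#' calls need CADD > 20.
#'
#' @param vaf_max_paired Calls with VAF at or above this are excluded
#'   (paired analysis).
#' @param eb_min Calls with EBscore at or below this are excluded.
#' @param depth_min_unpaired Minimum depth for unpaired calls.
#' @param vaf_max_unpaired Calls with VAF at or above this are excluded
#'   (unpaired analysis).
#' @param blat_max Calls whose supporting reads average a second-highest
#'   BLAT score at or above this are excluded (missing scores pass).
#' @param bcd_min_barcodes Minimum supporting barcodes, exclusive.
#' @param bcd_fold_max Maximum WES/BCDseq VAF fold change.
#' @param bcd_absdiff_max Maximum absolute WES/BCDseq VAF difference.
#' @param cadd_damaging CADD cutoff (exclusive) for damaging calls.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(vaf_max_paired = 0.20, eb_min = 5,
                          depth_min_unpaired = 300, vaf_max_unpaired = 0.10,
                          blat_max = 900, bcd_min_barcodes = 4,
                          bcd_fold_max = 10, bcd_absdiff_max = 0.05,
                          cadd_damaging = 20) {
  stopifnot(vaf_max_paired > 0, eb_min > 0, depth_min_unpaired > 0,
            vaf_max_unpaired > 0, blat_max > 0, bcd_min_barcodes > 0,
            bcd_fold_max > 1, bcd_absdiff_max > 0, cadd_damaging > 0)
  structure(as.list(environment()), class = "filter_config")
}

# Shared criteria for paired and unpaired calls. Returns, per call, the
# first criterion failed (NA_character_ if none), in the documented order.
paired_criteria <- function(calls, cfg) {
  stop_if_not_columns(calls, c("vaf", "eb_score", "end_read_only",
                               "clean_support", "blat_second_avg"), "calls")
  if (anyNA(calls$vaf) || anyNA(calls$eb_score)) {
    bad <- which(is.na(calls$vaf) | is.na(calls$eb_score))
    stop("calls with missing vaf or eb_score at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(calls))
  fail <- function(reason, cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- fail(reason, calls$vaf >= cfg$vaf_max_paired, "vaf_high")
  reason <- fail(reason, calls$eb_score <= cfg$eb_min, "eb_low")
  reason <- fail(reason, calls$end_read_only, "end_read_only")
  reason <- fail(reason, !calls$clean_support, "dirty_support")
  reason <- fail(reason, !is.na(calls$blat_second_avg) &
                   calls$blat_second_avg >= cfg$blat_max, "blat_high")
  reason
}

finish_filter <- function(calls, reason, labels) {
  kept <- calls[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  rejections <- vapply(labels, function(l) sum(reason == l, na.rm = TRUE),
                       integer(1L))
  list(calls = kept, rejections = rejections)
}

#' Filter paired-analysis somatic candidate calls
#'
#' A call survives iff VAF < 20%, EBscore > 5, its supporting reads are not
#' all located at read ends, its supporting reads carry no other base
#' changes, and (when available) the average second-highest BLAT score of
#' supporting reads is below 900. Rejections are attributed to the first
#' criterion failed, in that order, so the counts sum to input - output.
#'
#' @param calls Candidate call data frame (columns `vaf`, `eb_score`,
#'   `end_read_only`, `clean_support`, `blat_second_avg`).
#' @param cfg A [filter_config()].
#' @return A list with `calls` (surviving subset, same columns) and
#'   `rejections` (named integer vector of per-criterion counts).
#' @export
filter_paired_calls <- function(calls, cfg = filter_config()) {
  labels <- c("vaf_high", "eb_low", "end_read_only", "dirty_support",
              "blat_high")
  if (nrow(calls) == 0L) {
    return(list(calls = calls,
                rejections = stats::setNames(integer(length(labels)), labels)))
  }
  finish_filter(calls, paired_criteria(calls, cfg), labels)
}

#' Filter unpaired (brain-only) somatic candidate calls
#'
#' Applies every paired-analysis criterion plus the stricter brain-only
#' thresholds: depth >= 300 and VAF < 10%.
#'
#' @inheritParams filter_paired_calls
#' @return A list with `calls` and per-criterion `rejections`.
#' @export
filter_unpaired_calls <- function(calls, cfg = filter_config()) {
  labels <- c("depth_low", "vaf_high_unpaired", "vaf_high", "eb_low",
              "end_read_only", "dirty_support", "blat_high")
  if (nrow(calls) == 0L) {
    return(list(calls = calls,
                rejections = stats::setNames(integer(length(labels)), labels)))
  }
  stop_if_not_columns(calls, "depth", "calls")
  reason <- rep(NA_character_, nrow(calls))
  reason[calls$depth < cfg$depth_min_unpaired] <- "depth_low"
  reason[is.na(reason) & calls$vaf >= cfg$vaf_max_unpaired] <- "vaf_high_unpaired"
  shared <- paired_criteria(calls, cfg)
  reason[is.na(reason)] <- shared[is.na(reason)]
  finish_filter(calls, reason, labels)
}

#' Rescue low-VAF variants recurring across brain regions
#'
#' Treats multiple brain regions of one subject as pseudoreplicates: a
#' variant (subject, chrom, pos, ref, alt) is rescued iff it is called in
#' at least two distinct unordered region pairs — equivalently, present in
#' at least three distinct brain regions — and absent from that subject's
#' peripheral call set.
#'
#' @param calls Candidate call data frame with columns `subject`, `tissue`,
#'   `chrom`, `pos`, `ref`, `alt`. Rows with `tissue` equal to
#'   `peripheral_label` form the peripheral call set.
#' @param peripheral_label Tissue label marking peripheral samples.
#' @return A data frame of rescued variants: `subject, chrom, pos, ref,
#'   alt, n_regions, regions` (comma-separated supporting brain regions).
#' @export
find_replicate_calls <- function(calls, peripheral_label = "peripheral") {
  stop_if_not_columns(calls, c("subject", "tissue", "chrom", "pos",
                               "ref", "alt"), "calls")
  empty <- data.frame(subject = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      n_regions = integer(), regions = character(),
                      stringsAsFactors = FALSE)
  if (nrow(calls) == 0L) return(empty)
  key <- variant_key(calls)
  is_periph <- calls$tissue %in% peripheral_label
  periph_keys <- unique(key[is_periph])
  brain <- calls[!is_periph, , drop = FALSE]
  bkey <- key[!is_periph]
  if (nrow(brain) == 0L) return(empty)
  regions_by_variant <- tapply(brain$tissue, bkey,
                               function(x) sort(unique(x)), simplify = FALSE)
  n_regions <- vapply(regions_by_variant, length, integer(1L))
  rescued_keys <- names(regions_by_variant)[n_regions >= 3L]
  rescued_keys <- setdiff(rescued_keys, periph_keys)
  if (length(rescued_keys) == 0L) return(empty)
  first <- brain[match(rescued_keys, bkey), c("subject", "chrom", "pos",
                                              "ref", "alt"), drop = FALSE]
  first$n_regions <- n_regions[rescued_keys]
  first$regions <- vapply(regions_by_variant[rescued_keys],
                          paste, character(1L), collapse = ",")
  rownames(first) <- NULL
  first
}

#' Filter variants by barcode-sequencing (BCDseq) concordance
#'
#' A variant passes iff in every contributing region: more than
#' `bcd_min_barcodes` supporting barcodes, WES and BCDseq VAFs within a
#' `bcd_fold_max`-fold change, and within an absolute difference of
#' `bcd_absdiff_max` — and the variant was observed in at least two
#' regions. A zero VAF on one platform with a nonzero VAF on the other
#' leaves the fold change undefined and fails concordance.
#'
#' @param bcd Data frame with one row per (variant, region): columns
#'   `subject, chrom, pos, ref, alt, region, barcode_count, wes_vaf,
#'   bcd_vaf`.
#' @param cfg A [filter_config()].
#' @return A data frame with one row per variant: identity columns,
#'   `n_regions`, the per-rule flags `barcodes_ok`, `fold_ok`, `absdiff_ok`,
#'   `multi_region`, and `pass`.
#' @export
filter_bcd_calls <- function(bcd, cfg = filter_config()) {
  stop_if_not_columns(bcd, c("subject", "chrom", "pos", "ref", "alt",
                             "region", "barcode_count", "wes_vaf",
                             "bcd_vaf"), "bcd")
  key <- variant_key(bcd)
  lo <- pmin(bcd$wes_vaf, bcd$bcd_vaf)
  hi <- pmax(bcd$wes_vaf, bcd$bcd_vaf)
  fold_ok_row <- ifelse(hi == 0, TRUE,            # both zero: no discordance
                        ifelse(lo == 0, FALSE,    # one-sided zero: undefined
                               hi / lo <= cfg$bcd_fold_max))
  row_flags <- data.frame(
    key = key,
    barcodes = bcd$barcode_count > cfg$bcd_min_barcodes,
    fold = fold_ok_row,
    absdiff = abs(bcd$wes_vaf - bcd$bcd_vaf) <= cfg$bcd_absdiff_max,
    stringsAsFactors = FALSE)
  agg <- function(col) {
    tapply(row_flags[[col]], row_flags$key, all)
  }
  keys <- unique(key)
  barcodes_ok <- agg("barcodes")[keys]
  fold_ok <- agg("fold")[keys]
  absdiff_ok <- agg("absdiff")[keys]
  n_regions <- tapply(bcd$region, key, function(x) length(unique(x)))[keys]
  out <- bcd[match(keys, key), c("subject", "chrom", "pos", "ref", "alt"),
             drop = FALSE]
  out$n_regions <- as.integer(n_regions)
  out$barcodes_ok <- as.logical(barcodes_ok)
  out$fold_ok <- as.logical(fold_ok)
  out$absdiff_ok <- as.logical(absdiff_ok)
  out$multi_region <- out$n_regions >= 2L
  out$pass <- out$barcodes_ok & out$fold_ok & out$absdiff_ok & out$multi_region
  rownames(out) <- NULL
  out
}

LOF_MIS_TERMS <- c("missense", "stop_gained", "start_lost", "stop_lost",
                   "splice_donor", "splice_acceptor")

#' Classify a consequence annotation string
#'
#' Maps (possibly multi-term) consequence strings to the simplified
#' categories used throughout the analysis: `LOF_MIS` (missense, stop
#' gained, start lost, stop lost, splice donor or splice acceptor), `SYN`
#' (synonymous) or `OTHER`. Matching is case-insensitive; terms may be
#' separated by commas or ampersands.
#'
#' @param consequence Character vector of consequence strings.
#' @return Character vector over `{"LOF_MIS", "SYN", "OTHER"}`.
#' @examples
#' classify_consequence(c("missense_variant", "synonymous_variant",
#'                        "intron_variant"))
#' @export
classify_consequence <- function(consequence) {
  stopifnot(is.character(consequence))
  if (any(!nzchar(consequence) | is.na(consequence))) {
    stop("consequence strings must be nonempty", call. = FALSE)
  }
  x <- tolower(consequence)
  terms <- strsplit(x, "[,&]")
  vapply(terms, function(tt) {
    tt <- trimws(tt)
    if (any(vapply(LOF_MIS_TERMS,
                   function(p) any(grepl(p, tt, fixed = TRUE)), logical(1L)))) {
      "LOF_MIS"
    } else if (any(grepl("synonymous", tt, fixed = TRUE))) {
      "SYN"
    } else {
      "OTHER"
    }
  }, character(1L))
}

#' Flag putatively damaging calls
#'
#' A call is damaging iff its consequence category is `LOF_MIS` and its
#' Phred-scaled CADD score is strictly greater than the cutoff (default
#' 20). A missing CADD score on a `LOF_MIS` call yields `FALSE` with a
#' warning.
#'
#' @param consequence Character vector of consequence strings (or already
#'   classified categories).
#' @param cadd Numeric vector of Phred-scaled CADD scores (`NA` allowed).
#' @param cfg A [filter_config()]; `cfg$cadd_damaging` is the cutoff.
#' @return Logical vector.
#' @export
flag_damaging <- function(consequence, cadd, cfg = filter_config()) {
  category <- ifelse(consequence %in% c("LOF_MIS", "SYN", "OTHER"),
                     consequence, classify_consequence(consequence))
  missing_cadd <- category == "LOF_MIS" & is.na(cadd)
  if (any(missing_cadd)) {
    warning(sum(missing_cadd),
            " LOF_MIS call(s) with missing CADD treated as not damaging")
  }
  category == "LOF_MIS" & !is.na(cadd) & cadd > cfg$cadd_damaging
}
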