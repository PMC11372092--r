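# Spatiotemporal expression signatures: robust z-scores per gene within
# stage (across regions) and within region (across stages), combined into
# a meta-z, thresholded into per-window signatures, and tested for gene-set
# enrichment with Fisher's exact test + Benjamini-Hochberg correction.

#' Robust z-score with MAD scale
#'
#' `z = (e - center) / (1.4826 * mad)`; `1.4826 * MAD` is the robust
#' standard-deviation estimate under normality. When `mad` is zero the
#' robust scale is uninformative and the z-score is undefined (`NA`).
#'
#' @param e Expression value(s).
#' @param center Median of the comparison distribution.
#' @param mad Raw (unscaled) median absolute deviation; non-negative.
#' @param mad_scale Consistency constant (default 1.4826).
#' @return Numeric vector of z-scores; `NA` where `mad == 0`.
#' @export
robust_z <- function(e, center, mad, mad_scale = 1.4826) {
  stopifnot(all(mad >= 0, na.rm = TRUE))
  ifelse(mad > 0, (e - center) / (mad_scale * mad), NA_real_)
}

# Accept a long-format data frame (gene, region, stage, rpkm) or a 3D
# array [gene, region, stage]; return the array, erroring on missing cells.
as_expression_tensor <- function(expr) {
  if (is.array(expr) && length(dim(expr)) == 3L) {
    if (anyNA(expr)) stop("expression tensor contains NA cells", call. = FALSE)
    return(expr)
  }
  stop_if_not_columns(expr, c("gene", "region", "stage", "rpkm"), "expr")
  genes <- unique(expr$gene); regions <- unique(expr$region)
  stages <- unique(expr$stage)
  tensor <- array(NA_real_, dim = c(length(genes), length(regions),
                                    length(stages)),
                  dimnames = list(genes, regions, stages))
  tensor[cbind(match(expr$gene, genes), match(expr$region, regions),
               match(expr$stage, stages))] <- expr$rpkm
  if (anyNA(tensor)) {
    miss <- which(is.na(tensor), arr.ind = TRUE)
    stop(sprintf("incomplete expression grid: %d missing cell(s), e.g. (%s, %s, %s)",
                 nrow(miss), genes[miss[1, 1]], regions[miss[1, 2]],
                 stages[miss[1, 3]]), call. = FALSE)
  }
  tensor
}

#' Build stage x region expression signatures from a tensor
#'
#' For each gene `i` and window `(s, r)`, the expression `e_i^sr` is
#' standardised twice with robust z-scores: against the distribution
#' across all regions at stage `s` (giving `z_i^s`) and against all stages
#' at region `r` (giving `z_i^r`), each using the median and
#' `1.4826 * MAD` of the comparison distribution. The two components are
#' combined into a meta-z, `z_i^sr = (z_i^s + z_i^r) / sqrt(2)`, and the
#' window's signature is the set of genes with meta-z at or above the
#' threshold (default 1.5) and both components defined (a zero MAD makes a
#' component undefined and excludes the gene from that window).
#'
#' @param expr Long-format data frame (`gene, region, stage, rpkm`) on a
#'   complete grid, or a 3D array `[gene, region, stage]`.
#' @param threshold Meta-z membership threshold (default 1.5).
#' @param mad_scale MAD consistency constant (default 1.4826).
#' @return An object of class `signature_model`: list with `signatures`
#'   (named list of gene vectors, one per window, names `"region|stage"`),
#'   `meta_z`, `z_stage`, `z_region` (3D arrays), `genes`, `regions`,
#'   `stages`, `threshold`.
#' @export
build_signatures <- function(expr, threshold = 1.5, mad_scale = 1.4826) {
  tensor <- as_expression_tensor(expr)
  if (any(tensor < 0)) stop("expression values must be >= 0", call. = FALSE)
  dn <- dimnames(tensor)
  nG <- dim(tensor)[1]; nR <- dim(tensor)[2]; nS <- dim(tensor)[3]
  z_stage <- array(NA_real_, dim(tensor), dimnames = dn)
  z_region <- array(NA_real_, dim(tensor), dimnames = dn)
  # Row-wise robust standardisation of a gene x column matrix; rows with
  # zero MAD are undefined (NA).
  row_robust_z <- function(m) {
    ctr <- apply(m, 1L, stats::median)
    md <- apply(m, 1L, stats::mad, constant = 1)
    z <- (m - ctr) / (mad_scale * md)
    z[md == 0, ] <- NA_real_
    z
  }
  for (s in seq_len(nS)) {
    m <- tensor[, , s, drop = FALSE][, , 1]       # gene x region at stage s
    if (nG == 1L) m <- matrix(m, nrow = 1L)
    z_stage[, , s] <- row_robust_z(m)
  }
  for (r in seq_len(nR)) {
    m <- tensor[, r, , drop = FALSE][, 1, ]       # gene x stage at region r
    if (nG == 1L) m <- matrix(m, nrow = 1L)
    z_region[, r, ] <- row_robust_z(m)
  }
  meta_z <- (z_stage + z_region) / sqrt(2)
  signatures <- vector("list", nR * nS)
  labels <- character(nR * nS)
  k <- 0L
  for (s in seq_len(nS)) {
    for (r in seq_len(nR)) {
      k <- k + 1L
      member <- !is.na(meta_z[, r, s]) & meta_z[, r, s] >= threshold
      signatures[[k]] <- dn[[1]][member]
      labels[k] <- paste(dn[[2]][r], dn[[3]][s], sep = "|")
    }
  }
  names(signatures) <- labels
  structure(list(signatures = signatures, meta_z = meta_z,
                 z_stage = z_stage, z_region = z_region,
                 genes = dn[[1]], regions = dn[[2]], stages = dn[[3]],
                 threshold = threshold),
            class = "signature_model")
}

#' Test a gene set for enrichment in every expression signature window
#'
#' One-sided (over-representation) Fisher exact test of the overlap
#' between the gene set and each window's signature over the expression
#' universe, with Benjamini-Hochberg correction across all windows of the
#' model (one correction family per gene set).
#'
#' @param gene_set Character vector of gene symbols. Members absent from
#'   the universe are dropped (their count is reported in the
#'   `n_dropped` attribute).
#' @param signatures A `signature_model` from [build_signatures()], or a
#'   named list of signature gene vectors.
#' @param universe Gene universe; defaults to the model's genes.
#' @param alpha Significance level on the adjusted q-values.
#' @return A data frame with one row per window: `window, region, stage,
#'   set_size, signature_size, overlap, p_value, q_value, significant`.
#' @export
enrich_windows <- function(gene_set, signatures, universe = NULL,
                           alpha = 0.05) {
  if (inherits(signatures, "signature_model")) {
    universe <- universe %||% signatures$genes
    sigs <- signatures$signatures
  } else {
    stopifnot(is.list(signatures), !is.null(names(signatures)))
    if (is.null(universe)) {
      stop("universe is required when signatures are a plain list",
           call. = FALSE)
    }
    sigs <- signatures
  }
  if (!all(unlist(sigs) %in% universe)) {
    stop("signatures must be subsets of the universe", call. = FALSE)
  }
  n_dropped <- sum(!gene_set %in% universe)
  if (n_dropped > 0L) {
    message(n_dropped, " gene-set member(s) absent from the universe dropped")
  }
  gene_set <- unique(gene_set[gene_set %in% universe])
  N <- length(universe)
  n_set <- length(gene_set)
  parts <- strsplit(names(sigs), "|", fixed = TRUE)
  out <- data.frame(
    window = names(sigs),
    region = vapply(parts, `[`, character(1L), 1L),
    stage = vapply(parts, `[`, character(1L), 2L),
    set_size = n_set,
    signature_size = vapply(sigs, length, integer(1L)),
    overlap = vapply(sigs, function(s) sum(gene_set %in% s), integer(1L)),
    stringsAsFactors = FALSE)
  # One-sided Fisher exact p on the 2x2 over the universe equals the
  # hypergeometric upper tail P(X >= overlap).
  out$p_value <- if (n_set == 0L) {
    rep(1, nrow(out))
  } else {
    stats::phyper(out$overlap - 1L, out$signature_size,
                  N - out$signature_size, n_set, lower.tail = FALSE)
  }
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
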