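# Synthetic cohorts, call sets, amplicon counts, expression tensors, PPI
# graphs and reference gene lists with known ground truth, so the whole
# post-calling pipeline can be exercised without any external download.

SUBSTITUTION_CLASSES <- c("T>A", "T>C", "T>G", "C>T", "C>G", "C>A")

DEFAULT_BRAIN_REGIONS <- c("BA9", "BA21", "BA22", "BA17", "CB")

#' Cohort specification
#'
#' Describes the shape of a simulated case-control postmortem cohort:
#' how many ASD-labelled subjects and neurotypical controls, which brain
#' regions were sampled per subject, and what fraction of each group has a
#' matched peripheral tissue (enabling paired somatic calling). Defaults
#' mirror a 24-case / 31-control cohort in which 13 cases and all controls
#' are paired.
#'
#' @param n_cases Number of case (ASD-labelled) subjects; non-negative.
#' @param n_controls Number of control subjects; non-negative.
#' @param regions Character vector of brain region labels sampled for every
#'   subject.
#' @param paired_fraction Fraction of subjects with a matched peripheral
#'   sample, in `[0, 1]`. Either a single value for both groups or a
#'   length-2 vector `c(cases, controls)`.
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 24, n_controls = 31,
                        regions = DEFAULT_BRAIN_REGIONS,
                        paired_fraction = c(13 / 24, 1),
                        seed = NULL) {
  if (length(n_cases) != 1L || length(n_controls) != 1L ||
      !is.numeric(n_cases) || !is.numeric(n_controls) ||
      is.na(n_cases) || is.na(n_controls) ||
      n_cases < 0 || n_controls < 0 ||
      n_cases != round(n_cases) || n_controls != round(n_controls)) {
    stop("n_cases and n_controls must be single non-negative integers",
         call. = FALSE)
  }
  if (!is.character(regions) || length(regions) < 1L || anyDuplicated(regions)) {
    stop("regions must be a character vector of distinct labels", call. = FALSE)
  }
  if (!is_fraction(paired_fraction) ||
      !length(paired_fraction) %in% c(1L, 2L)) {
    stop("paired_fraction must be 1 or 2 fractions in [0, 1]", call. = FALSE)
  }
  if (length(paired_fraction) == 1L) {
    paired_fraction <- rep(paired_fraction, 2L)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         regions = regions, paired_fraction = paired_fraction, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a subject table from a cohort specification
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per subject: `subject`, `diagnosis`
#'   (`"ASD"` or `"control"`), `regions` (comma-separated region labels),
#'   `paired` (logical, matched peripheral tissue available) and `sex`.
#' @examples
#' generate_cohort(cohort_spec(n_cases = 2, n_controls = 2, seed = 1))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  if (n == 0L) {
    return(data.frame(subject = character(), diagnosis = character(),
                      regions = character(), paired = logical(),
                      sex = character(), stringsAsFactors = FALSE))
  }
  with_seed(spec$seed, {
    diagnosis <- rep(c("ASD", "control"), c(spec$n_cases, spec$n_controls))
    subject <- sprintf("%s%03d", ifelse(diagnosis == "ASD", "A", "C"),
                       c(seq_len(spec$n_cases), seq_len(spec$n_controls)))
    # The number of paired subjects per group is fixed by the fraction
    # (rounded); which subjects are paired is randomised.
    paired <- logical(n)
    for (g in c(1L, 2L)) {
      idx <- which(diagnosis == c("ASD", "control")[g])
      n_paired <- round(spec$paired_fraction[g] * length(idx))
      if (n_paired > 0L) paired[sample(idx, n_paired)] <- TRUE
    }
    sex <- sample(c("M", "F"), n, replace = TRUE)
    data.frame(subject = subject, diagnosis = diagnosis,
               regions = rep(paste(spec$regions, collapse = ","), n),
               paired = paired, sex = sex, stringsAsFactors = FALSE)
  })
}

#' Split the comma-separated region field of a cohort row
#' @param cohort A cohort data frame from [generate_cohort()].
#' @return A named list (by subject) of character vectors of region labels.
#' @export
cohort_regions <- function(cohort) {
  stats::setNames(strsplit(cohort$regions, ",", fixed = TRUE), cohort$subject)
}

#' Somatic mutation model for call-set simulation
#'
#' True variant allele fractions follow a Beta distribution rescaled to
#' `(vaf_min, vaf_max)`; defaults give VAFs as low as 0.3% with mean about
#' 5.3%. `mutations_per_region_mean` is the expected number of true somatic
#' SNVs per exome per single brain region. A `shared_region_fraction` of the
#' true mutations arose early enough in development to be present in at
#' least three brain regions of their subject; the remainder are private to
#' one region. Artifact candidates (sequencing/alignment errors) are emitted
#' at `artifact_rate` per region; a fraction `artifact_pass_eb_fraction` of
#' them carry an empirical-Bayes score above the filter cutoff and so can
#' survive filtering, which sets the residual false-positive rate of the
#' post-call candidate set.
#'
#' @param true_vaf_shape1,true_vaf_shape2 Beta shape parameters of the true
#'   VAF distribution before rescaling.
#' @param vaf_min,vaf_max Support of the rescaled true VAF distribution.
#' @param mutations_per_region_mean Expected true somatic SNVs per region.
#' @param shared_region_fraction Fraction of true mutations present in >= 3
#'   regions.
#' @param artifact_rate Expected artifact candidates per region.
#' @param artifact_pass_eb_fraction Fraction of artifacts with EBscore > 5.
#' @param coding_fraction Fraction of true mutations in protein-coding
#'   consequence classes.
#' @param damaging_fraction Fraction of coding LOF/missense mutations with
#'   CADD > 20.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(true_vaf_shape1 = 1.2, true_vaf_shape2 = 3.53,
                           vaf_min = 0.003, vaf_max = 0.2,
                           mutations_per_region_mean = 2.4,
                           shared_region_fraction = 0.2,
                           artifact_rate = 2,
                           artifact_pass_eb_fraction = 0.3,
                           coding_fraction = 0.364,
                           damaging_fraction = 0.38) {
  stopifnot(true_vaf_shape1 > 0, true_vaf_shape2 > 0,
            vaf_min >= 0, vaf_max <= 1, vaf_min < vaf_max,
            mutations_per_region_mean >= 0, artifact_rate >= 0,
            is_fraction(shared_region_fraction),
            is_fraction(artifact_pass_eb_fraction),
            is_fraction(coding_fraction), is_fraction(damaging_fraction))
  structure(as.list(environment()), class = "mutation_model")
}

#' Substitution-specific amplicon background error model
#'
#' Background alternate-allele fractions of the amplicon validation
#' platform for the six strand-collapsed substitution classes. The default
#' rates are the platform calibration values measured from replicate
#' sequencing of spike-in samples.
#'
#' @param rates Named numeric vector over the six classes
#'   `T>A, T>C, T>G, C>T, C>G, C>A`, each in `(0, 1)`.
#' @return A named numeric vector of class `error_model`.
#' @export
error_model <- function(rates = c("T>A" = 0.00312, "T>C" = 0.00797,
                                  "T>G" = 0.000758, "C>T" = 0.00407,
                                  "C>G" = 0.000765, "C>A" = 0.00185)) {
  if (!is.numeric(rates) || is.null(names(rates)) ||
      !setequal(names(rates), SUBSTITUTION_CLASSES)) {
    stop("rates must be a numeric vector named with all six classes: ",
         paste(SUBSTITUTION_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (any(rates <= 0) || any(rates >= 1)) {
    stop("every background error rate must lie in (0, 1)", call. = FALSE)
  }
  structure(rates[SUBSTITUTION_CLASSES], class = "error_model")
}

#' @rdname error_model
#' @export
default_error_model <- function() error_model()

# Draw true VAFs from the rescaled Beta model.
draw_true_vaf <- function(n, model) {
  model$vaf_min +
    (model$vaf_max - model$vaf_min) *
      stats::rbeta(n, model$true_vaf_shape1, model$true_vaf_shape2)
}

#' Simulate per-subject, per-region somatic SNV call sets
#'
#' Emits one row per (variant, tissue) candidate call, with hidden truth
#' labels retained for recovery testing. True mutations carry a latent VAF
#' from the mutation model's Beta distribution and are re-observed in each
#' of their regions with binomially resampled read counts at the local
#' sequencing depth; early-arising ("shared") mutations span >= 3 regions.
#' Artifacts carry low VAFs and are split between low-EBscore (filterable)
#' and EBscore-passing (residual) populations. For paired subjects a small
#' rate of multi-region candidates that also appear in the peripheral
#' tissue is emitted, exercising the peripheral-exclusion rule of
#' pseudoreplicate rescue.
#'
#' A call only exists where at least one alternate read was sampled; the
#' number of latent true (variant, region) observations lost to zero
#' sampled reads is recorded in the `n_zero_alt_dropped` attribute, so no
#' record disappears silently.
#'
#' @param cohort Subject table from [generate_cohort()].
#' @param model A [mutation_model()].
#' @param error A background [error_model()] (used for class labels only).
#' @param depth_mean Mean sequencing depth per site (Poisson).
#' @param peripheral_shared_rate Expected number per paired subject of
#'   multi-region candidates also present in peripheral tissue.
#' @param gene_pool_size Number of distinct gene symbols to draw from.
#' @param seed Integer RNG seed.
#' @return A data frame of candidate calls (see Details) with columns
#'   `subject, diagnosis, tissue, chrom, pos, ref, alt, substitution, gene,
#'   vaf, depth, alt_count, eb_score, caller, end_read_only, clean_support,
#'   blat_second_avg, consequence, cadd, population_af, is_true, true_vaf`.
#' @export
simulate_callsets <- function(cohort, model = mutation_model(),
                              error = default_error_model(),
                              depth_mean = 559,
                              peripheral_shared_rate = 0.3,
                              gene_pool_size = 5000, seed = NULL) {
  if (nrow(cohort) == 0L) stop("cohort must be nonempty", call. = FALSE)
  stopifnot(inherits(model, "mutation_model"))
  region_lists <- cohort_regions(cohort)
  with_seed(seed, {
    out <- vector("list", nrow(cohort))
    n_zero_dropped <- 0L
    for (i in seq_len(nrow(cohort))) {
      regions <- region_lists[[i]]
      nR <- length(regions)
      # Expected regions spanned per mutation under the sharing mixture;
      # shared mutations span k ~ Uniform{3..nR} regions when nR >= 3.
      sf <- if (nR >= 3L) model$shared_region_fraction else 0
      mean_span <- (1 - sf) + sf * mean(seq(3L, max(3L, nR)))
      n_mut <- stats::rpois(1L, nR * model$mutations_per_region_mean / mean_span)
      rows <- list()
      if (n_mut > 0L) {
        sub_class <- sample(SUBSTITUTION_CLASSES, n_mut, replace = TRUE)
        ref <- substr(sub_class, 1L, 1L)
        alt <- substr(sub_class, 3L, 3L)
        tv <- draw_true_vaf(n_mut, model)
        gene <- sprintf("GENE%04d", sample.int(gene_pool_size, n_mut, replace = TRUE))
        coding <- stats::runif(n_mut) < model$coding_fraction
        lofmis <- coding & stats::runif(n_mut) < 0.65
        consequence <- ifelse(lofmis, "missense_variant",
                              ifelse(coding, "synonymous_variant",
                                     "intron_variant"))
        cadd <- ifelse(lofmis & stats::runif(n_mut) < model$damaging_fraction,
                       stats::runif(n_mut, 20.5, 45),
                       stats::runif(n_mut, 0, 18))
        shared <- if (nR >= 3L) stats::runif(n_mut) < sf else rep(FALSE, n_mut)
        chrom <- sample(1:22, n_mut, replace = TRUE)
        pos <- sample.int(5e7, n_mut)
        for (m in seq_len(n_mut)) {
          span <- if (shared[m]) sample(3:nR, 1L) else 1L
          in_regions <- sample(regions, span)
          depth <- stats::rpois(span, depth_mean)
          alt_count <- stats::rbinom(span, depth, tv[m])
          keep <- alt_count > 0L & depth > 0L
          n_zero_dropped <- n_zero_dropped + sum(!keep)
          if (!any(keep)) next
          rows[[length(rows) + 1L]] <- data.frame(
            subject = cohort$subject[i], diagnosis = cohort$diagnosis[i],
            tissue = in_regions[keep], chrom = as.character(chrom[m]),
            pos = pos[m], ref = ref[m], alt = alt[m],
            substitution = sub_class[m], gene = gene[m],
            vaf = alt_count[keep] / depth[keep], depth = depth[keep],
            alt_count = alt_count[keep],
            eb_score = stats::runif(sum(keep), 6, 60),
            caller = if (span >= 3L) "replicate" else "single",
            end_read_only = FALSE, clean_support = TRUE,
            blat_second_avg = NA_real_,
            consequence = consequence[m], cadd = cadd[m],
            population_af = NA_real_,
            is_true = TRUE, true_vaf = tv[m], stringsAsFactors = FALSE)
        }
      }
      # Artifact candidates, per brain region.
      for (r in regions) {
        n_art <- stats::rpois(1L, model$artifact_rate)
        if (n_art == 0L) next
        sub_class <- sample(SUBSTITUTION_CLASSES, n_art, replace = TRUE)
        depth <- stats::rpois(n_art, depth_mean)
        av <- stats::runif(n_art, 0.005, 0.08)
        alt_count <- pmax(1L, stats::rbinom(n_art, depth, av))
        passes_eb <- stats::runif(n_art) < model$artifact_pass_eb_fraction
        coding <- stats::runif(n_art) < model$coding_fraction
        lofmis <- coding & stats::runif(n_art) < 0.65
        rows[[length(rows) + 1L]] <- data.frame(
          subject = cohort$subject[i], diagnosis = cohort$diagnosis[i],
          tissue = r, chrom = as.character(sample(1:22, n_art, replace = TRUE)),
          pos = sample.int(5e7, n_art),
          ref = substr(sub_class, 1L, 1L), alt = substr(sub_class, 3L, 3L),
          substitution = sub_class,
          gene = sprintf("GENE%04d", sample.int(gene_pool_size, n_art, replace = TRUE)),
          vaf = alt_count / pmax(depth, 1L), depth = pmax(depth, 1L),
          alt_count = alt_count,
          eb_score = ifelse(passes_eb, stats::runif(n_art, 5.01, 15),
                            stats::runif(n_art, 0, 5)),
          caller = "single",
          end_read_only = stats::runif(n_art) < 0.2,
          clean_support = stats::runif(n_art) < 0.9,
          blat_second_avg = NA_real_,
          consequence = ifelse(lofmis, "missense_variant",
                               ifelse(coding, "synonymous_variant",
                                      "intron_variant")),
          cadd = stats::runif(n_art, 0, 30), population_af = NA_real_,
          is_true = FALSE, true_vaf = NA_real_, stringsAsFactors = FALSE)
      }
      # Peripheral-shared contaminants for paired subjects: present in >= 3
      # regions AND the peripheral tissue, so pseudoreplicate rescue must
      # reject them.
      if (cohort$paired[i] && nR >= 3L) {
        n_ps <- stats::rpois(1L, peripheral_shared_rate)
        for (m in seq_len(n_ps)) {
          sub_class <- sample(SUBSTITUTION_CLASSES, 1L)
          span <- sample(3:nR, 1L)
          tissues <- c(sample(regions, span), "peripheral")
          depth <- stats::rpois(length(tissues), depth_mean)
          av <- stats::runif(1L, 0.01, 0.08)
          alt_count <- pmax(1L, stats::rbinom(length(tissues), depth, av))
          rows[[length(rows) + 1L]] <- data.frame(
            subject = cohort$subject[i], diagnosis = cohort$diagnosis[i],
            tissue = tissues, chrom = as.character(sample(1:22, 1L)),
            pos = sample.int(5e7, 1L),
            ref = substr(sub_class, 1L, 1L), alt = substr(sub_class, 3L, 3L),
            substitution = sub_class,
            gene = sprintf("GENE%04d", sample.int(gene_pool_size, 1L)),
            vaf = alt_count / pmax(depth, 1L), depth = pmax(depth, 1L),
            alt_count = alt_count,
            eb_score = stats::runif(length(tissues), 6, 30),
            caller = "replicate", end_read_only = FALSE, clean_support = TRUE,
            blat_second_avg = NA_real_, consequence = "intron_variant",
            cadd = stats::runif(1L, 0, 10), population_af = NA_real_,
            is_true = FALSE, true_vaf = NA_real_, stringsAsFactors = FALSE)
        }
      }
      out[[i]] <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    if (is.null(res)) {
      res <- data.frame()
    }
    rownames(res) <- NULL
    attr(res, "n_zero_alt_dropped") <- n_zero_dropped
    res
  })
}

#' Simulate targeted-amplicon validation read counts
#'
#' True variants yield alternate read counts distributed
#' `Binomial(depth, true VAF + class error rate)`; false candidates yield
#' `Binomial(depth, class error rate)`.
#'
#' @param variants Data frame with columns `substitution` (or `ref`/`alt`),
#'   `is_true` and `true_vaf`; typically a subset of [simulate_callsets()]
#'   output, one row per candidate.
#' @param error A background [error_model()].
#' @param depth Total amplicon read depth per site (non-negative integer).
#' @param seed Integer RNG seed.
#' @return A data frame: variant identity columns present in `variants`,
#'   plus `class`, `depth`, `alt_count`, `platform`.
#' @export
simulate_amplicon <- function(variants, error = default_error_model(),
                              depth = 10000, seed = NULL) {
  stopifnot(depth >= 0, depth == round(depth))
  if (!"substitution" %in% names(variants)) {
    stop_if_not_columns(variants, c("ref", "alt"), "variants")
    variants$substitution <- normalize_substitution(
      paste0(variants$ref, ">", variants$alt))
  }
  stop_if_not_columns(variants, c("substitution", "is_true"), "variants")
  cls <- normalize_substitution(variants$substitution)
  unknown <- unique(variants$substitution[is.na(cls) |
                                            !cls %in% SUBSTITUTION_CLASSES])
  if (length(unknown) > 0L) {
    stop("unknown substitution class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rate <- unclass(error)[cls]
  p <- ifelse(variants$is_true,
              pmin(1, variants$true_vaf + rate), rate)
  with_seed(seed, {
    alt <- if (depth == 0L) {
      rep(0L, nrow(variants))
    } else {
      stats::rbinom(nrow(variants), depth, p)
    }
    out <- variants
    out$class <- cls
    out$depth <- as.integer(depth)
    out$alt_count <- alt
    out$platform <- "TASeq"
    out
  })
}

#' Simulate a gene x region x stage expression tensor with planted windows
#'
#' Background expression is log-normal per cell around a per-gene baseline.
#' Each planted window elevates its gene subset at one (region, stage) cell
#' so that both the within-stage and within-region robust z-scores reach
#' `effect_z` in expectation, i.e. the planted genes exceed the meta-z
#' membership threshold used by [build_signatures()].
#'
#' @param genes Character vector of gene symbols.
#' @param regions,stages Label vectors (defaults: 15 regions, 10 stages).
#' @param planted_windows A list of lists, each with elements `region`,
#'   `stage`, `genes` (subset of `genes`) and `effect_z`.
#' @param baseline_meanlog_sd SD of per-gene baseline log-expression.
#' @param noise_sdlog Log-normal noise SD per cell.
#' @param seed Integer RNG seed.
#' @return A long-format data frame `gene, region, stage, rpkm` covering
#'   the complete grid.
#' @export
simulate_expression <- function(genes, regions = sprintf("R%02d", 1:15),
                                stages = sprintf("S%02d", 1:10),
                                planted_windows = list(),
                                baseline_meanlog_sd = 1,
                                noise_sdlog = 0.5, seed = NULL) {
  stopifnot(is.character(genes), length(genes) > 0L, !anyDuplicated(genes))
  for (w in planted_windows) {
    if (!all(c("region", "stage", "genes", "effect_z") %in% names(w))) {
      stop("each planted window needs region, stage, genes, effect_z",
           call. = FALSE)
    }
    if (!w$region %in% regions || !w$stage %in% stages) {
      stop(sprintf("planted window (%s, %s) outside the %d x %d grid",
                   w$region, w$stage, length(regions), length(stages)),
           call. = FALSE)
    }
    if (!all(w$genes %in% genes)) {
      stop("planted gene subset must be contained in `genes`", call. = FALSE)
    }
  }
  nG <- length(genes); nR <- length(regions); nS <- length(stages)
  with_seed(seed, {
    baseline <- stats::rnorm(nG, mean = 2, sd = baseline_meanlog_sd)
    tensor <- array(
      exp(rep(baseline, nR * nS) + stats::rnorm(nG * nR * nS, 0, noise_sdlog)),
      dim = c(nG, nR, nS), dimnames = list(genes, regions, stages))
    for (w in planted_windows) {
      r <- match(w$region, regions); s <- match(w$stage, stages)
      for (g in match(w$genes, genes)) {
        m_s <- stats::median(tensor[g, , s])
        mad_s <- stats::mad(tensor[g, , s], constant = 1)
        m_r <- stats::median(tensor[g, r, ])
        mad_r <- stats::mad(tensor[g, r, ], constant = 1)
        tensor[g, r, s] <- max(m_s + w$effect_z * 1.4826 * mad_s,
                               m_r + w$effect_z * 1.4826 * mad_r)
      }
    }
    data.frame(
      gene = rep(genes, times = nR * nS),
      region = rep(rep(regions, each = nG), times = nS),
      stage = rep(stages, each = nG * nR),
      rpkm = as.vector(tensor), stringsAsFactors = FALSE)
  })
}

#' Simulate an undirected PPI edge table with reliability scores
#'
#' Background edges follow an Erdos-Renyi model with expected degree
#' `mean_degree`; each planted hub receives extra random partners until its
#' degree reaches `hub_degree_multiplier * mean_degree`. Each unordered gene
#' pair appears at most once.
#'
#' @param genes Character vector of gene symbols (nodes).
#' @param mean_degree Expected background degree per gene.
#' @param planted_hub_genes Genes given elevated degree.
#' @param hub_degree_multiplier Target hub degree as a multiple of
#'   `mean_degree`.
#' @param reliability_shape1,reliability_shape2 Beta parameters of edge
#'   reliability scores in `(0, 1]`.
#' @param seed Integer RNG seed.
#' @return A data frame `geneA, geneB, reliability`.
#' @export
simulate_ppi <- function(genes, mean_degree = 4,
                         planted_hub_genes = character(),
                         hub_degree_multiplier = 10,
                         reliability_shape1 = 2, reliability_shape2 = 2,
                         seed = NULL) {
  stopifnot(is.character(genes), length(genes) >= 2L, mean_degree >= 0,
            all(planted_hub_genes %in% genes))
  n <- length(genes)
  with_seed(seed, {
    p_edge <- min(1, mean_degree / (n - 1))
    pairs <- if (p_edge > 0) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      idx[stats::runif(nrow(idx)) < p_edge, , drop = FALSE]
    } else {
      matrix(integer(), ncol = 2L)
    }
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_len(nrow(pairs))) {
      assign(edge_key(pairs[k, 1L], pairs[k, 2L]), TRUE, envir = seen)
    }
    extra <- list()
    deg <- tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = n)
    for (h in match(planted_hub_genes, genes)) {
      target <- round(hub_degree_multiplier * mean_degree)
      candidates <- sample(setdiff(seq_len(n), h))
      for (cand in candidates) {
        if (deg[h] >= target) break
        key <- edge_key(h, cand)
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          extra[[length(extra) + 1L]] <- c(h, cand)
          deg[h] <- deg[h] + 1L
          deg[cand] <- deg[cand] + 1L
        }
      }
    }
    all_pairs <- rbind(pairs, do.call(rbind, extra))
    if (is.null(all_pairs) || nrow(all_pairs) == 0L) {
      return(data.frame(geneA = character(), geneB = character(),
                        reliability = numeric(), stringsAsFactors = FALSE))
    }
    data.frame(
      geneA = genes[all_pairs[, 1L]], geneB = genes[all_pairs[, 2L]],
      reliability = pmax(stats::rbeta(nrow(all_pairs), reliability_shape1,
                                      reliability_shape2), 1e-6),
      stringsAsFactors = FALSE)
  })
}

#' Simulate reference gene lists with a planted overlap
#'
#' Generates `n_lists` random gene lists from a universe. One list (at
#' `planted_overlap$index`) is constructed to share exactly
#' `planted_overlap$k` genes with `planted_overlap$target`.
#'
#' @param universe Character vector of gene symbols to draw from.
#' @param n_lists Number of lists.
#' @param list_size_range Length-2 integer range of list sizes.
#' @param planted_overlap Optional list with elements `target` (gene set),
#'   `index` (which list) and `k` (exact overlap size).
#' @param seed Integer RNG seed.
#' @return A named list of character vectors (GMT-style gene lists).
#' @export
simulate_reference_genesets <- function(universe, n_lists = 8,
                                        list_size_range = c(50, 300),
                                        planted_overlap = NULL,
                                        seed = NULL) {
  stopifnot(is.character(universe), n_lists >= 1,
            length(list_size_range) == 2L,
            list_size_range[1] >= 1,
            list_size_range[2] <= length(universe))
  if (!is.null(planted_overlap)) {
    stopifnot(all(c("target", "index", "k") %in% names(planted_overlap)),
              planted_overlap$index >= 1, planted_overlap$index <= n_lists,
              all(planted_overlap$target %in% universe))
  }
  with_seed(seed, {
    sizes <- sample(seq(list_size_range[1], list_size_range[2]),
                    n_lists, replace = TRUE)
    lists <- vector("list", n_lists)
    for (i in seq_len(n_lists)) {
      if (!is.null(planted_overlap) && i == planted_overlap$index) {
        target <- planted_overlap$target
        k <- planted_overlap$k
        size <- sizes[i]
        non_target <- setdiff(universe, target)
        if (k > min(size, length(target)) || size - k > length(non_target)) {
          stop(sprintf("planted overlap k = %d infeasible for list size %d",
                       k, size), call. = FALSE)
        }
        lists[[i]] <- c(if (k > 0) sample(target, k) else character(),
                        if (size - k > 0) sample(non_target, size - k)
                        else character())
      } else {
        lists[[i]] <- sample(universe, sizes[i])
      }
    }
    names(lists) <- sprintf("REFSET_%02d", seq_len(n_lists))
    lists
  })
}
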