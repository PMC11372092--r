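test_that("cohort generation honours the spec and is deterministic", {
  empty <- generate_cohort(cohort_spec(n_cases = 0, n_controls = 0))
  expect_equal(nrow(empty), 0L)

  spec <- cohort_spec(n_cases = 24, n_controls = 31,
                      paired_fraction = c(13 / 24, 1), seed = 11)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 55L)
  expect_equal(sum(co$diagnosis == "ASD"), 24L)
  expect_equal(sum(co$paired), 44L)
  expect_equal(sum(co$paired & co$diagnosis == "ASD"), 13L)
  expect_identical(co, generate_cohort(spec))

  expect_error(cohort_spec(n_cases = -1), "non-negative")
  expect_error(cohort_spec(paired_fraction = 1.2), "paired_fraction")
})

test_that("call-set simulation recovers its own mutation model", {
  co <- generate_cohort(cohort_spec(n_cases = 100, n_controls = 100,
                                    seed = 3))
  calls <- simulate_callsets(co, mutation_model(), seed = 7)
  expect_identical(calls, simulate_callsets(co, mutation_model(), seed = 7))

  # Latent true mutation-region observations (emitted plus the ones whose
  # binomial resampling produced zero alternate reads) recover the
  # per-region rate of 2.4 over 1,000 subject-regions.
  n_regions <- sum(lengths(cohort_regions(co)))
  expect_equal(n_regions, 1000L)
  latent <- sum(calls$is_true) + attr(calls, "n_zero_alt_dropped")
  expect_gte(latent / n_regions, 2.25)
  expect_lte(latent / n_regions, 2.55)

  # True VAFs follow the scaled Beta model: Monte-Carlo mean within 3
  # standard errors of the analytic mean.
  model <- mutation_model()
  n <- 20000L
  vafs <- mosaicSNV:::with_seed(13, mosaicSNV:::draw_true_vaf(n, model))
  mean_expected <- model$vaf_min + (model$vaf_max - model$vaf_min) *
    model$true_vaf_shape1 / (model$true_vaf_shape1 + model$true_vaf_shape2)
  expect_lt(abs(mean(vafs) - mean_expected), 3 * sd(vafs) / sqrt(n))
})

test_that("forcing full sharing puts every true variant in >= 3 regions", {
  co <- generate_cohort(cohort_spec(n_cases = 10, n_controls = 0, seed = 5))
  calls <- simulate_callsets(
    co, mutation_model(shared_region_fraction = 1, artifact_rate = 0,
                       vaf_min = 0.05),   # high VAFs: no zero-alt dropouts
    peripheral_shared_rate = 0, seed = 9)
  expect_true(all(calls$is_true))
  regions_per_variant <- tapply(calls$tissue, mosaicSNV:::variant_key(calls),
                                function(x) length(unique(x)))
  expect_true(all(regions_per_variant >= 3L))
})

test_that("amplicon simulation matches its binomial model", {
  fake <- data.frame(substitution = rep("T>G", 2000), is_true = FALSE,
                     true_vaf = NA_real_, stringsAsFactors = FALSE)
  zero <- simulate_amplicon(fake, depth = 0, seed = 1)
  expect_true(all(zero$alt_count == 0L))

  amp <- simulate_amplicon(fake, depth = 10000, seed = 2)
  mean_frac <- mean(amp$alt_count / amp$depth)
  expect_gte(mean_frac, 0.0005)
  expect_lte(mean_frac, 0.0011)

  truev <- data.frame(substitution = "C>T", is_true = TRUE, true_vaf = 0.05,
                      stringsAsFactors = FALSE)
  amp2 <- simulate_amplicon(truev, depth = 10000, seed = 3)
  p <- 0.05 + 0.00407
  expect_gte(amp2$alt_count, qbinom(0.0005, 10000, p))
  expect_lte(amp2$alt_count, qbinom(0.9995, 10000, p))

  bad <- data.frame(substitution = "C>X", is_true = FALSE,
                    true_vaf = NA_real_)
  expect_error(simulate_amplicon(bad, depth = 10, seed = 1), "C>X")
})

test_that("expression tensor has the full grid and plants recoverable signal", {
  genes <- sprintf("G%03d", 1:40)
  expr <- simulate_expression(genes, seed = 4)
  expect_equal(nrow(expr), 40L * 15L * 10L)
  expect_equal(length(unique(expr$region)) * length(unique(expr$stage)), 150L)

  # Zero noise: constant per gene, all robust scales zero, no signatures.
  flat <- simulate_expression(genes, noise_sdlog = 0, seed = 4)
  sigs <- build_signatures(flat)$signatures
  expect_true(all(lengths(sigs) == 0L))

  expect_error(
    simulate_expression(genes, planted_windows = list(
      list(region = "nope", stage = "S01", genes = genes[1], effect_z = 5))),
    "outside")
})

test_that("PPI simulation emits unique undirected edges and real hubs", {
  genes <- sprintf("P%03d", 1:300)
  expect_equal(nrow(simulate_ppi(genes, mean_degree = 0, seed = 1)), 0L)

  hubs <- genes[1:50]
  edges <- simulate_ppi(genes, mean_degree = 4, planted_hub_genes = hubs,
                        seed = 2)
  keys <- paste(pmin(edges$geneA, edges$geneB),
                pmax(edges$geneA, edges$geneB))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(edges$reliability > 0 & edges$reliability <= 1))

  deg <- ppi_weighted_degree(edges, genes = genes)
  background <- sample(setdiff(genes, hubs), 50)
  cmp <- compare_ppi(deg[hubs], deg[background])
  expect_gt(cmp$median_a, cmp$median_b)
  expect_lt(cmp$p_value, 0.01)
})

test_that("reference gene lists carry exactly the planted overlap", {
  universe <- sprintf("U%03d", 1:200)
  target <- universe[1:18]
  for (k in c(0L, 5L, 18L)) {
    lists <- simulate_reference_genesets(
      universe, n_lists = 4, list_size_range = c(30, 60),
      planted_overlap = list(target = target, index = 2, k = k), seed = k + 1)
    expect_equal(sum(lists[[2]] %in% target), k)
  }
  expect_error(
    simulate_reference_genesets(
      universe, n_lists = 2, list_size_range = c(5, 5),
      planted_overlap = list(target = target, index = 1, k = 6), seed = 1),
    "infeasible")
})
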