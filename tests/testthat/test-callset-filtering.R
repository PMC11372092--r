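test_that("paired filter applies each exclusion criterion", {
  calls <- make_calls(
    make_call(pos = 1L, vaf = 0.25),                 # VAF >= 20%
    make_call(pos = 2L, eb_score = 5),               # EBscore <= 5 (boundary)
    make_call(pos = 3L, end_read_only = TRUE),
    make_call(pos = 4L, clean_support = FALSE),
    make_call(pos = 5L, blat_second_avg = 950),
    make_call(pos = 6L),                             # survivor
    make_call(pos = 7L, vaf = 0.199999, eb_score = 5.0001))  # boundary pass
  res <- filter_paired_calls(calls)
  expect_equal(sort(res$calls$pos), c(6L, 7L))
  expect_equal(res$rejections[["vaf_high"]], 1L)
  expect_equal(res$rejections[["eb_low"]], 1L)
  expect_equal(sum(res$rejections), nrow(calls) - nrow(res$calls))

  empty <- filter_paired_calls(calls[0, ])
  expect_equal(nrow(empty$calls), 0L)
  expect_true(all(empty$rejections == 0L))

  expect_error(filter_paired_calls(make_call(vaf = NA_real_)), "missing")
})

test_that("unpaired filter adds the stricter depth and VAF thresholds", {
  calls <- make_calls(
    make_call(pos = 1L, depth = 299L, vaf = 0.05),   # depth < 300
    make_call(pos = 2L, depth = 500L, vaf = 0.10),   # VAF >= 10% (boundary)
    make_call(pos = 3L, depth = 500L, vaf = 0.05),   # survivor
    make_call(pos = 4L, depth = 500L, vaf = 0.05, eb_score = 2))
  res <- filter_unpaired_calls(calls)
  expect_equal(res$calls$pos, 3L)
  expect_equal(res$rejections[["depth_low"]], 1L)
  expect_equal(res$rejections[["vaf_high_unpaired"]], 1L)
  expect_equal(res$rejections[["eb_low"]], 1L)
})

test_that("filters are subsets, idempotent and criterion-order independent", {
  set.seed(42)
  n <- 300
  calls <- make_call()[rep(1, n), ]
  calls$pos <- seq_len(n)
  calls$vaf <- runif(n, 0, 0.4)
  calls$depth <- sample(100:800, n, replace = TRUE)
  calls$eb_score <- runif(n, 0, 40)
  calls$end_read_only <- runif(n) < 0.2
  calls$clean_support <- runif(n) < 0.8
  calls$blat_second_avg <- ifelse(runif(n) < 0.5, NA_real_,
                                  runif(n, 500, 1100))
  for (f in list(filter_paired_calls, filter_unpaired_calls)) {
    once <- f(calls)
    expect_true(all(once$calls$pos %in% calls$pos))
    twice <- f(once$calls)
    expect_equal(twice$calls, once$calls)
    expect_true(all(twice$rejections == 0L))
  }
  # The surviving set equals the plain conjunction of the criteria, so any
  # criterion ordering yields the same survivors.
  survivors <- filter_paired_calls(calls)$calls$pos
  manual <- calls$pos[calls$vaf < 0.20 & calls$eb_score > 5 &
                        !calls$end_read_only & calls$clean_support &
                        (is.na(calls$blat_second_avg) |
                           calls$blat_second_avg < 900)]
  expect_setequal(survivors, manual)
})

test_that("pseudoreplicate rescue requires >= 3 regions and no peripheral call", {
  v <- function(tissue, pos = 100L) make_call(tissue = tissue, pos = pos)
  three <- make_calls(v("BA9"), v("BA21"), v("BA17"))
  expect_equal(nrow(find_replicate_calls(three)), 1L)
  expect_equal(find_replicate_calls(three)$regions, "BA17,BA21,BA9")

  two <- make_calls(v("BA9"), v("BA21"))
  expect_equal(nrow(find_replicate_calls(two)), 0L)

  with_periph <- make_calls(v("BA9"), v("BA21"), v("BA17"), v("peripheral"))
  expect_equal(nrow(find_replicate_calls(with_periph)), 0L)
})

test_that("rescue agrees with brute-force region-pair enumeration", {
  # Oracle: count distinct unordered region pairs in which the variant was
  # called; rescue iff >= 2 pairs and no peripheral call.
  oracle <- function(calls) {
    key <- paste(calls$subject, calls$chrom, calls$pos, calls$ref, calls$alt)
    rescued <- character()
    for (k in unique(key)) {
      tissues <- unique(calls$tissue[key == k])
      regions <- setdiff(tissues, "peripheral")
      n_pairs <- if (length(regions) >= 2) choose(length(regions), 2) else 0
      if (n_pairs >= 2 && !"peripheral" %in% tissues) rescued <- c(rescued, k)
    }
    rescued
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- 40
    calls <- make_call()[rep(1, n), ]
    calls$subject <- sample(c("S1", "S2"), n, replace = TRUE)
    calls$pos <- sample(1:6, n, replace = TRUE)
    calls$tissue <- sample(c("BA9", "BA21", "BA22", "BA17", "CB",
                             "peripheral"), n, replace = TRUE)
    got <- find_replicate_calls(calls)
    got_keys <- paste(got$subject, got$chrom, got$pos, got$ref, got$alt)
    expect_setequal(got_keys, oracle(calls))
  }
})

test_that("BCDseq concordance filter enforces all three rules in all regions", {
  bcd_row <- function(region, barcode_count = 10, wes_vaf = 0.02,
                      bcd_vaf = 0.03, pos = 1L) {
    data.frame(subject = "S1", chrom = "1", pos = pos, ref = "C", alt = "T",
               region = region, barcode_count = barcode_count,
               wes_vaf = wes_vaf, bcd_vaf = bcd_vaf, stringsAsFactors = FALSE)
  }
  pass <- rbind(bcd_row("BA9"), bcd_row("BA21"))
  expect_true(filter_bcd_calls(pass)$pass)

  low_bc <- rbind(bcd_row("BA9", barcode_count = 4), bcd_row("BA21"))
  expect_false(filter_bcd_calls(low_bc)$pass)

  fold <- rbind(bcd_row("BA9", wes_vaf = 0.010, bcd_vaf = 0.0009),
                bcd_row("BA21"))
  res <- filter_bcd_calls(fold)
  expect_false(res$fold_ok)
  expect_false(res$pass)

  zero <- rbind(bcd_row("BA9", wes_vaf = 0.01, bcd_vaf = 0),
                bcd_row("BA21"))
  expect_false(filter_bcd_calls(zero)$pass)

  single_region <- bcd_row("BA9")
  expect_false(filter_bcd_calls(single_region)$pass)

  diff <- rbind(bcd_row("BA9", wes_vaf = 0.10, bcd_vaf = 0.16),
                bcd_row("BA21"))
  expect_false(filter_bcd_calls(diff)$absdiff_ok)
})

test_that("consequence classification and damaging flag follow the categories", {
  expect_equal(
    classify_consequence(c("missense_variant", "stop_gained&intron_variant",
                           "start_lost", "stop_lost", "splice_donor_variant",
                           "splice_acceptor_variant", "synonymous_variant",
                           "intron_variant", "MISSENSE_VARIANT",
                           "synonymous_variant,missense_variant")),
    c(rep("LOF_MIS", 6), "SYN", "OTHER", "LOF_MIS", "LOF_MIS"))
  expect_error(classify_consequence(""), "nonempty")

  expect_false(flag_damaging("missense_variant", 20.0))   # strict >
  expect_true(flag_damaging("missense_variant", 25.1))
  expect_false(flag_damaging("synonymous_variant", 35))
  expect_warning(got <- flag_damaging("missense_variant", NA_real_),
                 "missing CADD")
  expect_false(got)
})

test_that("the cascade recovers all shared true variants when artifacts fail EB", {
  co <- generate_cohort(cohort_spec(n_cases = 15, n_controls = 15, seed = 21))
  calls <- simulate_callsets(
    co, mutation_model(artifact_pass_eb_fraction = 0),
    peripheral_shared_rate = 0, seed = 22)

  # Artifacts all have EBscore <= 5, so every filtered call is true.
  kept <- filter_paired_calls(calls)$calls
  expect_true(all(kept$is_true))

  # Every true variant emitted in >= 3 brain regions (and absent from
  # peripheral tissue by construction) is rescued.
  true_calls <- calls[calls$is_true, ]
  per_variant <- tapply(true_calls$tissue, mosaicSNV:::variant_key(true_calls),
                        function(x) length(unique(x)))
  shared_keys <- names(per_variant)[per_variant >= 3]
  rescued <- find_replicate_calls(calls)
  rescued_keys <- mosaicSNV:::variant_key(rescued)
  expect_true(all(shared_keys %in% rescued_keys))
})
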