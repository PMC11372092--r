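germline_row <- function(...) {
  base <- data.frame(subject = "A1", gene = "CHD8", depth = 150L,
                     allele_fraction = 0.45, cadd = 28, exac_af = NA_real_,
                     consequence = "missense_variant", stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

test_that("damaging germline selection applies every threshold", {
  sfari <- read_sfari_fixture()
  pass <- germline_row()
  expect_equal(nrow(select_damaging_germline(pass, sfari)), 1L)

  expect_equal(nrow(select_damaging_germline(
    germline_row(depth = 99L), sfari)), 0L)
  expect_equal(nrow(select_damaging_germline(
    germline_row(allele_fraction = 0.29), sfari)), 0L)
  expect_equal(nrow(select_damaging_germline(
    germline_row(cadd = 20.0), sfari)), 0L)               # strict >
  expect_equal(nrow(select_damaging_germline(
    germline_row(exac_af = 0.0002), sfari)), 0L)          # >= 0.02% common
  expect_equal(nrow(select_damaging_germline(
    germline_row(gene = "TTN"), sfari)), 0L)              # SFARI "other"
  expect_equal(nrow(select_damaging_germline(
    germline_row(gene = "NOT_IN_TABLE"), sfari)), 0L)     # absent -> other
  expect_equal(nrow(select_damaging_germline(
    germline_row(consequence = "synonymous_variant"), sfari)), 0L)
})

test_that("the validated damaging somatic table yields 7 genes in 6 subjects", {
  tab1 <- read_table1_somatic()
  sel <- select_damaging_somatic(tab1)
  expect_equal(length(unique(sel$gene)), 7L)
  expect_equal(length(unique(sel$subject)), 6L)
  expect_setequal(sel$gene, c("DVL1", "ADCY5", "ERBB3", "PEAK1", "RGS6",
                              "SLC25A22", "CENPJ"))

  # The gates: damaging-but-unvalidated and validated-but-synonymous calls
  # are excluded.
  unval <- tab1[1, ]; unval$validated <- FALSE
  expect_equal(nrow(select_damaging_somatic(unval)), 0L)
  syn <- tab1[1, ]
  syn$damaging <- flag_damaging("synonymous_variant", syn$cadd)
  expect_equal(nrow(select_damaging_somatic(syn)), 0L)
})

test_that("merging somatic and germline sets uses union semantics", {
  som <- data.frame(subject = c("A1", "A2"), gene = c("A", "B"))
  ger <- data.frame(subject = c("A3", "A4"), gene = c("B", "C"))
  merged <- merge_genesets(som, ger)
  expect_equal(merged$gene, c("A", "B", "C"))
  expect_equal(merged$source[merged$gene == "B"], "somatic+germline")

  expect_equal(nrow(merge_genesets(som[0, ], ger[0, ])), 0L)

  # 7 validated somatic genes + 11 disjoint germline genes = 18 merged.
  tab1 <- read_table1_somatic()
  germ <- select_damaging_germline(read_germline_fixture(),
                                   read_sfari_fixture())
  expect_equal(length(unique(germ$gene)), 11L)
  merged_asd <- merge_genesets(select_damaging_somatic(tab1), germ)
  expect_equal(nrow(merged_asd), 18L)
})

test_that("carrier tables reproduce the case-control layout", {
  cohort <- data.frame(
    subject = c(sprintf("A%02d", 1:24), sprintf("C%02d", 1:31)),
    diagnosis = rep(c("ASD", "control"), c(24, 31)),
    stringsAsFactors = FALSE)
  # Carriers mirroring the published counts: 6 ASD somatic carriers, 12 ASD
  # germline carriers (4 shared, union 14); controls: 2 somatic carriers
  # within the 8 germline carriers (union 8).
  som <- data.frame(subject = c(sprintf("A%02d", 1:6), sprintf("C%02d", 1:2)),
                    gene = "X", stringsAsFactors = FALSE)
  ger <- data.frame(subject = c(sprintf("A%02d", 3:14), sprintf("C%02d", 1:8)),
                    gene = "Y", stringsAsFactors = FALSE)
  merged <- carrier_table(som, ger, cohort, mode = "merged")
  expect_equal(unname(merged), matrix(c(14L, 10L, 8L, 23L), 2, byrow = TRUE))
  expect_equal(sum(merged), 55L)
  expect_equal(unname(carrier_table(som, ger, cohort, "somatic_only")[, 1]),
               c(6L, 2L))
  expect_equal(unname(carrier_table(som, ger, cohort, "germline_only")[, 1]),
               c(12L, 8L))

  none <- carrier_table(som[0, ], ger[0, ], cohort, "merged")
  expect_equal(unname(none[, "carrier"]), c(0L, 0L))
  expect_equal(unname(none[, "non_carrier"]), c(24L, 31L))

  cohort$diagnosis[1] <- NA
  expect_error(carrier_table(som, ger, cohort, "merged"), "missing diagnosis")
})

test_that("Fisher risk assessment matches exact-test conventions", {
  sym <- fisher_risk(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p_two_sided, 1)

  # Enumeration oracle on [[3,1],[1,3]]: sum point probabilities of all
  # tables with the same margins that are no more probable than observed.
  m <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  support <- 0:4                      # top-left cell ranges over 0..4
  probs <- dhyper(support, 4, 4, 4)
  p_oracle <- sum(probs[probs <= dhyper(3, 4, 4, 4) * (1 + 1e-7)])
  expect_equal(fisher_risk(m)$p_two_sided, p_oracle, tolerance = 1e-10)

  # Transposition invariance of the p-value.
  set.seed(71)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_risk(tab)$p_two_sided,
                 fisher_risk(t(tab))$p_two_sided, tolerance = 1e-12)
  }

  # Removing a control carrier (holding cases fixed) never lowers the OR.
  t1 <- fisher_risk(matrix(c(10, 10, 8, 12), 2, byrow = TRUE))
  t2 <- fisher_risk(matrix(c(10, 10, 7, 13), 2, byrow = TRUE))
  expect_gte(t2$odds_ratio, t1$odds_ratio)

  zero_margin <- fisher_risk(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))
  expect_true(is.na(zero_margin$odds_ratio))
  expect_equal(zero_margin$p_two_sided, 1)
})

test_that("conditional-MLE and sample odds ratios bracket the printed values", {
  res <- fisher_risk(matrix(c(14, 10, 8, 23), 2, byrow = TRUE))
  expect_equal(res$sample_odds_ratio, 14 * 23 / (10 * 8))
  expect_equal(round(res$sample_odds_ratio, 3), 4.025)
  expect_equal(round(res$odds_ratio, 2), 3.92)
  expect_lt(res$odds_ratio, res$sample_odds_ratio)
})
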