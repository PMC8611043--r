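test_that("contingency table validation", {
  expect_error(contingency_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "all-zero")
  expect_error(contingency_2x2(1.5, 2, 3, 4), "integer")
})

test_that("two-tailed Fisher matches enumeration on random small tables", {
  expect_equal(fisher_exact_two_tailed(contingency_2x2(1, 1, 1, 1)), 1.0)
  set.seed(17)
  for (i in 1:1000) {
    total <- sample(4:40, 1)
    cuts <- sort(sample(0:total, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    c <- cuts[3] - cuts[2]; d <- total - cuts[3]
    if ((a + b + c + d) == 0 || (a + c) == 0 && (b + d) == 0) next
    if (a + b == 0 || c + d == 0) next
    tab <- contingency_2x2(a, b, c, d)
    expect_equal(fisher_exact_two_tailed(tab), fisher_oracle(a, b, c, d),
                 tolerance = 1e-12)
  }
})

test_that("Fisher agrees with the standard library on large tables", {
  tabs <- list(c(14, 234, 3079, 130401), c(13, 49, 532, 4290),
               c(8, 54, 206, 4616), c(3, 500, 1200, 99000))
  for (t in tabs) {
    m <- matrix(t, nrow = 2, byrow = TRUE)
    expect_equal(fisher_exact_two_tailed(do.call(contingency_2x2,
                                                 as.list(t))),
                 stats::fisher.test(m)$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher P is invariant to simultaneous row and column swaps", {
  set.seed(23)
  for (i in 1:50) {
    x <- sample(0:15, 4, replace = TRUE)
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0) next
    p1 <- fisher_exact_two_tailed(contingency_2x2(x[1], x[2], x[3], x[4]))
    p2 <- fisher_exact_two_tailed(contingency_2x2(x[4], x[3], x[2], x[1]))
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("odds ratio and chi-square follow the stated conventions", {
  r <- odds_ratio_chisq(contingency_2x2(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1.0)
  expect_equal(r$chi_square, 0)
  r <- odds_ratio_chisq(contingency_2x2(14, 234, 3079, 130401))
  expect_equal(r$odds_ratio, (14 * 130401) / (234 * 3079))
  m <- matrix(c(14, 234, 3079, 130401), nrow = 2, byrow = TRUE)
  expect_equal(r$chi_square,
               unname(suppressWarnings(
                 stats::chisq.test(m, correct = FALSE)$statistic)))
  # zero cell: Haldane-Anscombe keeps the estimate finite
  r0 <- odds_ratio_chisq(contingency_2x2(0, 10, 5, 5))
  expect_true(is.finite(r0$odds_ratio))
  expect_equal(r0$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio_chisq(contingency_2x2(0, 0, 5, 5)),
               "zero margin")
  # OR > 1 iff case minor fraction exceeds control fraction; chi2 = 0 iff
  # OR = 1 (no zero cells)
  set.seed(3)
  for (i in 1:50) {
    x <- sample(1:30, 4, replace = TRUE)
    r <- odds_ratio_chisq(contingency_2x2(x[1], x[2], x[3], x[4]))
    expect_equal(r$odds_ratio > 1,
                 x[1] / (x[1] + x[2]) > x[3] / (x[3] + x[4]))
    expect_equal(isTRUE(all.equal(r$chi_square, 0)),
                 isTRUE(all.equal(r$odds_ratio, 1)))
  }
})

test_that("allele counting caps at two per subject-gene and matches a tally", {
  # 12 single-gene heterozygotes + 1 dual-gene heterozygote over 62
  # subjects and two genes
  ig <- study_index_genotypes()
  cc <- count_alleles(ig$genotypes, ig$subjects, c("DSP", "PPL"))
  expect_equal(cc$minor, 14)
  expect_equal(cc$major, 234)
  expect_equal(cc$total, 2 * 62 * 2)
  # no carriers
  cc0 <- count_alleles(ig$genotypes[0, ], sprintf("s%d", 1:10),
                       c("A", "B"))
  expect_equal(cc0$minor, 0)
  expect_equal(cc0$major, 40)
  # random genotype matrix vs brute-force per-allele tally
  set.seed(41)
  subjects <- sprintf("s%02d", 1:30)
  genes <- c("G1", "G2", "G3")
  geno <- expand.grid(sample_id = subjects, gene = genes,
                      stringsAsFactors = FALSE)
  geno$genotype <- sample(c("hom_ref", "het", "hom_alt", "missing"),
                          nrow(geno), TRUE)
  cc <- suppressWarnings(count_alleles(geno, subjects, genes))
  dose_of <- c(hom_ref = 0, het = 1, hom_alt = 2, missing = 0)
  expect_equal(cc$minor, sum(dose_of[geno$genotype]))
  # QC-missing-only subject-gene pairs warn (or error when configured)
  geno2 <- data.frame(sample_id = "s01", gene = "G1",
                      genotype = "missing", stringsAsFactors = FALSE)
  expect_warning(count_alleles(geno2, "s01", "G1"), "major")
  expect_error(count_alleles(geno2, "s01", "G1",
                             missing_as_major = FALSE), "informative")
})

test_that("carrier burden builds the subject-level table", {
  b <- carrier_burden(13, 62, 532, 4822)
  expect_equal(b$table$b, 49)
  expect_equal(b$table$d, 4290)
  # identical carrier rates at n = 4 each give P = 1
  expect_equal(carrier_burden(2, 4, 2, 4)$p_fisher_two_tailed, 1.0)
  expect_error(carrier_burden(5, 4, 1, 10), "exceed")
})

test_that("second-hit enrichment counts dual-hit subjects correctly", {
  subjects <- sprintf("s%02d", 1:20)
  gs <- desmosome_gene_set()
  expect_length(gs, 25)
  expect_true(all(c("DSP", "PPL", "DSG1") %in% gs))
  # plant dual hits: s01-s03 carry DSP + another desmosome gene; s04
  # carries DSP only; s05 carries DSG1 only
  geno <- data.frame(
    sample_id = c("s01", "s01", "s02", "s02", "s03", "s03", "s04", "s05"),
    gene = c("DSP", "DSG1", "PPL", "PKP1", "DSP", "DSC2", "DSP", "DSG1"),
    genotype = "het", stringsAsFactors = FALSE
  )
  b <- second_hit_enrichment(geno, subjects, c("DSP", "PPL"), gs,
                             control_carriers = 10, control_total = 1000)
  expect_equal(b$table$a, 3)
  expect_equal(b$table$b, 17)
  # a DSP+PPL pair is not a second hit when primaries are excluded
  geno2 <- rbind(geno,
                 data.frame(sample_id = c("s06", "s06"),
                            gene = c("DSP", "PPL"), genotype = "het"))
  b2 <- second_hit_enrichment(geno2, subjects, c("DSP", "PPL"), gs,
                              control_carriers = 10, control_total = 1000)
  expect_equal(b2$table$a, 3)
  b3 <- second_hit_enrichment(geno2, subjects, c("DSP", "PPL"), gs,
                              control_carriers = 10, control_total = 1000,
                              exclude_primary = FALSE)
  expect_equal(b3$table$a, 4)
  # zero dual hits anywhere -> P = 1
  b0 <- second_hit_enrichment(geno[0, ], subjects, c("DSP", "PPL"), gs,
                              control_carriers = 0, control_total = 1000)
  expect_equal(b0$p_fisher_two_tailed, 1.0)
  expect_error(second_hit_enrichment(geno, subjects, "DSP", character(0),
                                     1, 10), "empty gene set")
})

test_that("family carrier summary counts distinct families", {
  cand <- study_candidate_variants()
  s <- family_carrier_summary(cand, 62)
  expect_equal(s$n_carrier_families, 13)
  expect_equal(s$percent, 21.0)
  s0 <- family_carrier_summary(cand[0, ], 62)
  expect_equal(s0$n_carrier_families, 0)
  expect_equal(s0$percent, 0.0)
  # planted carriers in a simulated cohort equal the truth count
  cfg <- sim_config(n_families = 10, seed = 19)
  coh <- simulate_cohort(cfg)
  fc <- filter_cohort(coh$calls, coh$annotations, coh$pedigrees)
  carrier_fams <- coh$variants[coh$variants$variant_id %in%
                                 fc$candidates$variant_id, ]
  s2 <- family_carrier_summary(carrier_fams, 10)
  expect_equal(s2$n_carrier_families,
               length(unique(carrier_fams$family_id)))
})
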