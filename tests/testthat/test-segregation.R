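test_that("Mendelian check flags impossible trios only", {
  ped <- make_trio()
  ids <- ped$individual_id
  # het child of two hom-ref parents is impossible
  v <- check_mendelian(ped, genotypes_df(ids, c("hom_ref", "hom_ref", "het")))
  expect_equal(nrow(v), 1)
  expect_equal(v$individual_id, "T1_C")
  # het child with one het parent is fine
  v <- check_mendelian(ped, genotypes_df(ids, c("het", "hom_ref", "het")))
  expect_equal(nrow(v), 0)
  # hom-alt child needs an alternate allele from each parent
  v <- check_mendelian(ped, genotypes_df(ids, c("hom_ref", "het", "hom_alt")))
  expect_equal(nrow(v), 1)
  # missing genotypes are uninformative
  v <- check_mendelian(ped, genotypes_df(ids, c("missing", "hom_ref", "het")))
  expect_equal(nrow(v), 0)
  # cyclic pedigrees are rejected
  cyc <- ped
  cyc$father_id[1] <- "T1_C"
  expect_error(check_mendelian(cyc, genotypes_df(ids, rep("het", 3))),
               "cyclic")
})

test_that("discovery co-segregation tolerates unaffected carriers", {
  # a five-affected family: all affected carry, two unaffected/unknown
  # members also carry -> still co-segregates, carriers reported
  ids <- sprintf("D%02d", 1:9)
  ped <- data.frame(
    family_id = "F430x", individual_id = ids,
    father_id = NA_character_, mother_id = NA_character_,
    sex = "male",
    affection = c(rep("affected", 5), "unaffected", "unknown",
                  "unaffected", "unaffected"),
    stringsAsFactors = FALSE
  )
  gt <- genotypes_df(ids, c(rep("het", 5), "het", "het",
                            "hom_ref", "hom_ref"))
  r <- cosegregates_discovery(ped, gt)
  expect_true(r$cosegregates)
  expect_equal(r$affected_carriers, 5)
  expect_equal(r$unaffected_carriers, 2)
  # one affected non-carrier breaks co-segregation
  gt2 <- genotypes_df(ids, c(rep("het", 4), "hom_ref", rep("hom_ref", 4)))
  r2 <- cosegregates_discovery(ped, gt2)
  expect_false(r2$cosegregates)
  expect_equal(r2$affected_noncarriers, 1)
  # all carriers all affected
  ped3 <- ped; ped3$affection <- "affected"
  r3 <- cosegregates_discovery(ped3, genotypes_df(ids, rep("het", 9)))
  expect_true(r3$cosegregates)
  expect_equal(r3$unaffected_carriers, 0)
  # no genotyped affected member is an input error
  ped4 <- ped; ped4$affection <- "unaffected"
  expect_error(cosegregates_discovery(ped4, gt), "affected")
})

test_that("binomial upper tail matches the exact summation oracle", {
  expect_equal(binomial_upper_tail(0, 10, 0.5), 1.0)
  expect_equal(binomial_upper_tail(5, 5, 0.5), 0.03125)
  expect_equal(binomial_upper_tail(18, 23, 0.5), 44552 / 8388608)
  for (n in c(1, 2, 7, 23, 50)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      for (p in c(0.1, 0.5, 0.9)) {
        expect_equal(binomial_upper_tail(k, n, p),
                     binom_tail_oracle(k, n, p), tolerance = 1e-12)
      }
    }
  }
  # monotone non-increasing in k
  tails <- vapply(0:30, binomial_upper_tail, numeric(1), n = 30, p = 0.5)
  expect_true(all(diff(tails) <= 0))
  expect_error(binomial_upper_tail(5, 4, 0.5), "k <= n")
  expect_error(binomial_upper_tail(1, 4, 1.5), "p <= 1")
})

test_that("sibling and dyad units are scored per the concordance rules", {
  # one family: affected carrier proband, one concordant affected carrier
  # sib, one discordant affected non-carrier sib, affected carrier father
  fid <- "S1"
  ids <- paste0(fid, c("_FA", "_MO", "_P", "_S1", "_S2", "_S3"))
  ped <- data.frame(
    family_id = fid, individual_id = ids,
    father_id = c(NA, NA, rep(ids[1], 4)),
    mother_id = c(NA, NA, rep(ids[2], 4)),
    sex = "female",
    affection = c("affected", "unaffected", "affected", "affected",
                  "affected", "unknown"),
    stringsAsFactors = FALSE
  )
  gt <- genotypes_df(ids, c("het", "hom_ref", "het", "het", "hom_ref",
                            "het"))
  r <- score_concordance(list(list(pedigree = ped, proband_id = ids[3],
                                   genotypes = gt)))
  # S3 has unknown affection: excluded; dyad + 2 sibling units
  expect_equal(r$n_units, 3)
  expect_equal(sum(r$units$kind == "parent_dyad"), 1)
  expect_equal(r$k_concordant, 2)
  expect_equal(r$proportion, 2 / 3)
  # non-carrier proband is an input error
  gt_bad <- genotypes_df(ids, c("het", "hom_ref", "hom_ref", "het",
                                "hom_ref", "het"))
  expect_error(score_concordance(list(list(pedigree = ped,
                                           proband_id = ids[3],
                                           genotypes = gt_bad))),
               "carrier")
})

test_that("single-genotyped-parent dyads use complement inference", {
  fid <- "S2"
  ids <- paste0(fid, c("_FA", "_MO", "_P"))
  ped <- data.frame(
    family_id = fid, individual_id = ids,
    father_id = c(NA, NA, ids[1]), mother_id = c(NA, NA, ids[2]),
    sex = c("male", "female", "male"),
    affection = c("affected", "unaffected", "affected"),
    stringsAsFactors = FALSE
  )
  # only the mother genotyped, non-carrier: father inferred carrier;
  # father affected -> concordant
  gt <- genotypes_df(ids, c("missing", "hom_ref", "het"))
  r <- score_concordance(list(list(pedigree = ped, proband_id = ids[3],
                                   genotypes = gt)))
  expect_equal(r$n_units, 1)
  expect_equal(r$k_concordant, 1)
  # mother genotyped carrier but unaffected, father affected inferred
  # non-carrier -> discordant on both grounds
  gt2 <- genotypes_df(ids, c("missing", "het", "het"))
  r2 <- score_concordance(list(list(pedigree = ped, proband_id = ids[3],
                                    genotypes = gt2)))
  expect_equal(r2$k_concordant, 0)
  # neither parent genotyped -> no dyad unit
  gt3 <- genotypes_df(ids, c("missing", "missing", "het"))
  r3 <- score_concordance(list(list(pedigree = ped, proband_id = ids[3],
                                    genotypes = gt3)))
  expect_equal(r3$n_units, 0)
})

test_that("concordance result is invariant to family order and closed forms hold", {
  fams <- synthetic_replication_cohort()
  r1 <- score_concordance(fams)
  r2 <- score_concordance(rev(fams))
  expect_identical(r1$units, r2$units)
  expect_identical(r1$p_binomial, r2$p_binomial)
  # all-concordant cohorts give p = 0.5^n
  conc <- fams[1:6]
  rc <- score_concordance(conc)
  expect_equal(rc$proportion, 1.0)
  expect_equal(rc$p_binomial, 0.5^rc$n_units)
  # half-concordant on even n gives p > 0.5 (binomial symmetry)
  expect_gt(binomial_upper_tail(5, 10, 0.5), 0.5)
  # two-sided option doubles the tail
  r_two <- score_concordance(fams, tail = "two")
  expect_equal(r_two$p_binomial, min(1, 2 * r1$p_binomial))
})

test_that("perfect-penetrance cohorts give concordance 1 and co-segregation", {
  cfg <- sim_config(n_families = 8, penetrance = 1, phenocopy_rate = 0,
                    seed = 31)
  coh <- simulate_cohort(cfg)
  cc <- cohort_concordance(coh)
  expect_gt(cc$n_units, 0)
  expect_equal(cc$proportion, 1.0)
  truth_geno <- data.frame(
    individual_id = coh$pedigrees$individual_id,
    genotype = ifelse(coh$pedigrees$carrier, "het", "hom_ref"),
    stringsAsFactors = FALSE
  )
  for (fid in unique(coh$pedigrees$family_id)[1:3]) {
    ped <- coh$pedigrees[coh$pedigrees$family_id == fid, ]
    gt <- truth_geno[truth_geno$individual_id %in% ped$individual_id, ]
    expect_true(cosegregates_discovery(ped, gt)$cosegregates)
  }
})
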