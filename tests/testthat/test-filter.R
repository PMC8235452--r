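test_that("consequence whitelist retains protein-altering classes only", {
  cfg <- filterConfig()
  v <- toyVariants(rbind(vrow(consequence = "stopgain"),
                         vrow(pos = 2L, consequence = "other"),
                         vrow(pos = 3L, consequence = "splice_site"),
                         vrow(pos = 4L, consequence = "nonframeshift_deletion",
                              ref = "ATTT", alt = "A")),
                   list(), samples = "S1")
  expect_equal(passesConsequence(v, cfg), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("frequency rule keeps novel and strictly-below-threshold variants", {
  cfg <- filterConfig()
  v <- toyVariants(rbind(vrow(pop_af = 0.04),
                         vrow(pos = 2L, pop_af = NA_real_),
                         vrow(pos = 3L, pop_af = 0.05),
                         vrow(pos = 4L, pop_af = 0.2)),
                   list(), samples = "S1")
  # the boundary is exclusive: a variant at exactly the threshold is dropped
  expect_equal(passesFrequency(v, cfg), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("damaging rule requires >=1 damaging call only for annotated variants", {
  cfg <- filterConfig()
  v <- toyVariants(rbind(
    vrow(),                                               # SIFT damaging
    vrow(pos = 2L, sift = "benign"),                      # all four benign
    vrow(pos = 3L, sift = "missing", polyphen2 = "missing", lrt = "missing",
         mutation_taster = "missing", annotated_in_db = FALSE),
    vrow(pos = 4L, sift = "benign", mutation_taster = "damaging")),
    list(), samples = "S1")
  expect_equal(passesDamaging(v, cfg), c(TRUE, FALSE, TRUE, TRUE))
  # unannotated variants can be dropped instead by configuration
  cfgStrict <- filterConfig(retain_if_unannotated = FALSE)
  expect_equal(passesDamaging(v, cfgStrict), c(TRUE, FALSE, FALSE, TRUE))
  # raising the required predictor count tightens the rule
  cfg2 <- filterConfig(damaging_min_predictors = 2)
  expect_equal(passesDamaging(v, cfg2), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("artifact strip honors flags and the key blacklist", {
  v <- toyVariants(rbind(vrow(), vrow(pos = 2L, artifact_flag = TRUE),
                         vrow(pos = 3L)),
                   list(), samples = "S1")
  cfg <- filterConfig(artifact_keys = "chr1:3:A:G")
  expect_equal(passesArtifact(v, cfg), c(TRUE, FALSE, FALSE))
  cfgOff <- filterConfig(drop_artifacts = FALSE, artifact_keys = "chr1:3:A:G")
  expect_equal(passesArtifact(v, cfgOff), rep(TRUE, 3))
})

test_that("sharing requires every sequenced member to carry the alt allele", {
  cohort <- toyCohort()   # sequenced members: II-1, III-1
  v <- toyVariants(rbind(vrow(), vrow(pos = 2L), vrow(pos = 3L)),
                   list(c(`II-1` = "het", `III-1` = "hom_alt"),
                        c(`II-1` = "het", `III-1` = "hom_ref"),
                        c(`II-1` = "het", `III-1` = "missing")))
  # missing genotype in a sequenced member fails the test (conservative)
  expect_equal(sharedByAllSequenced(v, cohort, "G"), c(TRUE, FALSE, FALSE))
})

test_that("a single sequenced member trivially shares its variants", {
  df <- data.frame(family_id = "S", individual_id = "P1",
                   father_id = NA_character_, mother_id = NA_character_,
                   sex = "female", affection = "affected", sequenced = TRUE)
  solo <- FamilyCohort(df)
  v <- toyVariants(vrow(), list(c(P1 = "het")))
  expect_true(sharedByAllSequenced(v, solo, "S"))
})

test_that("sharing errors when no sequenced member is genotyped", {
  cohort <- toyCohort()
  v <- toyVariants(vrow(), list(c(`II-1` = "missing", `III-1` = "missing")))
  expect_error(sharedByAllSequenced(v, cohort, "G"), "chr1:100:A:G")
})

test_that("the five-stage cascade reproduces the hand-derived funnel", {
  cohort <- toyCohort()
  carriers <- c(`II-1` = "het", `III-1` = "het")
  oneOut <- c(`II-1` = "het", `III-1` = "hom_ref")
  v <- toyVariants(rbind(
    vrow(pos = 10L, pop_af = 0.01),                       # (a) retained
    vrow(pos = 20L, consequence = "other", pop_af = 0.01),# (b) consequence
    vrow(pos = 30L, pop_af = 0.2),                        # (c) frequency
    vrow(pos = 40L, pop_af = 0.01, sift = "benign"),      # (d) all benign
    vrow(pos = 50L, pop_af = 0.01)),                      # (e) not shared
    list(carriers, carriers, carriers, carriers, oneOut))
  res <- runCascade(v, cohort, "G")
  expect_equal(res$funnel$n_in, c(5L, 4L, 4L, 3L, 2L))
  expect_equal(res$funnel$n_out, c(4L, 4L, 3L, 2L, 1L))
  expect_equal(variantKeys(res$retained), "chr1:10:A:G")
  # matches the brute-force predicate-intersection oracle
  expect_equal(variantKeys(res$retained), bruteForceRetained(v, cohort, "G"))
})

test_that("an identity configuration retains every shared variant", {
  cohort <- toyCohort()
  carriers <- c(`II-1` = "het", `III-1` = "het")
  v <- toyVariants(rbind(vrow(pos = 1L, pop_af = 0.9, sift = "benign",
                              consequence = "other"),
                         vrow(pos = 2L, pop_af = NA_real_)),
                   list(carriers, carriers))
  cfg <- filterConfig(maf_threshold = 1, consequence_whitelist = consequenceClasses(),
                      damaging_min_predictors = 1, retain_if_unannotated = TRUE)
  # all-benign still fails the damaging rule; relax it via unannotated route
  meta <- variantMeta(v)
  meta$annotated_in_db <- FALSE
  meta[, c("sift", "polyphen2", "lrt", "mutation_taster")] <- "missing"
  v2 <- toyVariants(meta, list(carriers, carriers))
  res <- runCascade(v2, cohort, "G", cfg)
  expect_equal(length(res$retained), length(v2))
  expect_equal(res$funnel$n_out, rep(2L, 5))
})

test_that("the cascade of an empty variant set is empty with a zero funnel", {
  cohort <- toyCohort()
  v <- toyVariants(vrow()[0, ], list(), samples = c("II-1", "III-1"))
  res <- runCascade(v, cohort, "G")
  expect_equal(length(res$retained), 0)
  expect_equal(res$funnel$n_in, rep(0L, 5))
  expect_equal(res$funnel$n_out, rep(0L, 5))
})

test_that("cascade equals the brute-force oracle on simulated cohorts", {
  for (seed in c(11, 23, 57)) {
    sim <- simulateCohort(simulationParams(n_families = 2, seed = seed,
                                           variants_median = 15,
                                           variants_range = c(8L, 20L)))
    for (fam in familyIds(sim$cohort)) {
      res <- runCascade(sim$variants, sim$cohort, fam)
      expect_equal(sort(variantKeys(res$retained)),
                   bruteForceRetained(sim$variants, sim$cohort, fam))
      # funnel monotonicity and stage chaining
      expect_true(all(res$funnel$n_out <= res$funnel$n_in))
      expect_equal(res$funnel$n_in[-1], res$funnel$n_out[-5])
      # every retained variant satisfies each predicate individually
      r <- res$retained
      expect_true(all(passesConsequence(r, filterConfig())))
      expect_true(all(passesArtifact(r, filterConfig())))
      expect_true(all(passesFrequency(r, filterConfig())))
      expect_true(all(passesDamaging(r, filterConfig())))
      expect_true(all(sharedByAllSequenced(r, sim$cohort, fam)))
    }
  }
})
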