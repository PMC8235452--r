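test_that("pedigree simulation honors its structural contract", {
  params <- simulationParams(seed = 1)
  ped <- simulatePedigree(params, "F01", seed = 77)
  df <- ped$members
  expect_true(all(df$family_id == "F01"))
  nseq <- sum(df$sequenced)
  expect_gte(nseq, 3); expect_lte(nseq, 5)
  # sequenced members are affected and span >= 2 generations
  expect_true(all(df$affection[df$sequenced] == "affected"))
  seqGen <- ped$generation[df$individual_id[df$sequenced]]
  expect_gte(length(unique(seqGen)), 2)
  # founders have no parents; everyone else has both in the family
  founders <- is.na(df$father_id) & is.na(df$mother_id)
  expect_true(all(df$father_id[!founders] %in% df$individual_id))
  # affected members' Cobb angles respect the diagnostic threshold
  expect_true(all(unlist(df$cobb) >= 10))
  # constructs a valid cohort (acyclicity etc. checked by the class)
  expect_s4_class(FamilyCohort(df), "FamilyCohort")
})

test_that("pedigree simulation is deterministic and rejects depth 1", {
  params <- simulationParams()
  p1 <- simulatePedigree(params, "FX", seed = 5)
  p2 <- simulatePedigree(params, "FX", seed = 5)
  expect_identical(p1, p2)
  expect_error(simulationParams(depth = 1), "depth")
})

test_that("homozygous-reference parents only produce homozygous-reference children", {
  expect_true(all(mendelianCross("hom_ref", "hom_ref", 500, seed = 1) ==
                    "hom_ref"))
  expect_true(all(mendelianCross("hom_alt", "hom_alt", 500, seed = 1) ==
                    "hom_alt"))
})

test_that("transmitted genotypes are Mendelian-consistent with planted carriage", {
  params <- simulationParams(seed = 2)
  ped <- simulatePedigree(params, "F01", seed = 11)
  af <- c(0.3, 0.05, NA, 0.5)
  planted <- c(FALSE, FALSE, TRUE, FALSE)
  gt <- transmitGenotypes(ped$members, af, planted, lineage = ped$lineage,
                          seed = 13)
  count <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  cnt <- matrix(count[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  for (i in seq_len(nrow(ped$members))) {
    fa <- ped$members$father_id[i]; mo <- ped$members$mother_id[i]
    if (is.na(fa)) next
    child <- cnt[, ped$members$individual_id[i]]
    maxFromParents <- (cnt[, fa] >= 1) + (cnt[, mo] >= 1)
    minFromParents <- (cnt[, fa] == 2) + (cnt[, mo] == 2)
    expect_true(all(child <= maxFromParents))
    expect_true(all(child >= minFromParents))
  }
  # planted variant: heterozygous in every lineage member, absent elsewhere
  expect_true(all(gt[3, ped$lineage] == "het"))
  expect_true(all(gt[3, setdiff(colnames(gt), ped$lineage)] == "hom_ref"))
  seqIds <- ped$members$individual_id[ped$members$sequenced]
  expect_true(all(gt[3, seqIds] == "het"))
  # planted transmission without a lineage is refused
  expect_error(transmitGenotypes(ped$members, af, planted), "lineage")
})

test_that("a het x hom_ref cross transmits the allele to half the offspring", {
  off <- mendelianCross("het", "hom_ref", 10000, seed = 99)
  carrier <- mean(off %in% c("het", "hom_alt"))
  expect_lt(abs(carrier - 0.5), 0.02)   # 4 binomial standard errors
  expect_true(all(off %in% c("hom_ref", "het")))
})

test_that("generated frequency bins match the configured masses", {
  set.seed(17)
  af <- FamVarPrio:::.sampleMaf(10000, c(0.12, 0.18, 0.22, 0.48))
  obs <- c(mean(is.na(af)), mean(!is.na(af) & af < 1e-3),
           mean(!is.na(af) & af >= 1e-3 & af < 1e-2),
           mean(!is.na(af) & af >= 1e-2))
  exp <- c(0.12, 0.18, 0.22, 0.48)
  se <- sqrt(exp * (1 - exp) / 10000)
  expect_true(all(abs(obs - exp) <= 3 * se))
})

test_that("the simulated cohort keeps its planted and decoy promises", {
  sim <- simulateCohort(simulationParams(n_families = 3, seed = 23,
                                         variants_median = 20,
                                         variants_range = c(10L, 30L)))
  truth <- sim$truth
  gt <- genotypes(sim$variants)
  keys <- variantKeys(sim$variants)
  for (fam in familyIds(sim$cohort)) {
    seqIds <- sequencedSamples(sim$cohort, fam)
    tf <- truth[truth$family_id == fam, ]
    carried <- matrix(gt[match(tf$key, keys), seqIds] != "hom_ref",
                      nrow = nrow(tf))
    allCarried <- rowSums(carried) == length(seqIds)
    expect_true(all(allCarried[tf$class != "decoy_unshared"]))
    expect_true(all(!allCarried[tf$class == "decoy_unshared"]))
  }
  # decoy classes carry their designed violations
  meta <- variantMeta(sim$variants)
  m <- meta[match(truth$key, keys), ]
  expect_true(all(m$pop_af[truth$class == "decoy_high_af"] >= 0.05))
  benign <- m[truth$class == "decoy_benign",
              c("sift", "polyphen2", "lrt", "mutation_taster")]
  expect_true(all(as.matrix(benign) == "benign"))
  expect_true(all(m$consequence[truth$class == "decoy_consequence"] == "other"))
  expect_true(all(m$consequence[truth$class == "planted"] != "other"))
})

test_that("identical simulation parameters give byte-identical output files", {
  params <- simulationParams(n_families = 2, seed = 3,
                             variants_median = 15,
                             variants_range = c(8L, 20L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateCohortFiles(params, d1)
  simulateCohortFiles(params, d2)
  for (f in c("cohort.vcf", "cohort.ped", "terms.gmt", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and the VCF/PED round-trip back into equivalent objects
  sim <- simulateCohort(params)
  cohort <- readPedigree(file.path(d1, "cohort.ped"))
  expect_equal(members(cohort)[, names(members(sim$cohort))],
               members(sim$cohort))
  vars <- readVariants(file.path(d1, "cohort.vcf"), cohort = cohort)
  # frequencies are written with 8 significant digits
  expect_equal(variantMeta(vars), variantMeta(sim$variants), tolerance = 1e-6)
  expect_equal(genotypes(vars), genotypes(sim$variants))
})

test_that("the full pipeline recovers exactly the planted variants", {
  sim <- simulateCohort(simulationParams(n_families = 3, seed = 71,
                                         variants_median = 20,
                                         variants_range = c(10L, 30L)))
  filt <- filterCohort(sim$variants, sim$cohort)
  got <- unlist(lapply(names(filt$retained), function(f) {
    paste(f, variantKeys(filt$retained[[f]]))
  }))
  want <- paste(sim$truth$family_id, sim$truth$key)[sim$truth$expected_retained]
  expect_setequal(got, want)
})
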