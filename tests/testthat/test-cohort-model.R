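test_that("a trio pedigree parses with PED conventions applied", {
  ped <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("A\tDAD\t0\t0\t1\t1",
               "A\tMOM\t0\t0\t2\t1",
               "A\tKID\tDAD\tMOM\t2\t2\t1\t24"), ped)
  cohort <- readPedigree(ped)
  df <- members(cohort)
  expect_equal(nrow(df), 3)
  expect_equal(familyIds(cohort), "A")
  expect_equal(sum(df$affection == "affected"), 1)
  # "0" parent ids become NA (founder convention)
  expect_true(is.na(df$father_id[df$individual_id == "DAD"]))
  expect_equal(df$father_id[df$individual_id == "KID"], "DAD")
  expect_equal(sequencedSamples(cohort, "A"), "KID")
  expect_equal(df$cobb[[3]], 24)
})

test_that("pedigree parsing rejects duplicates and unknown parents by name", {
  ped <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("G\tII-1\t0\t0\t1\t2\t1",
               "G\tII-1\t0\t0\t2\t1"), ped)
  expect_error(readPedigree(ped), "G/II-1")

  ped2 <- withr::local_tempfile(fileext = ".ped")
  writeLines("G\tII-1\tGHOST\t0\t1\t2\t1", ped2)
  expect_error(readPedigree(ped2), "GHOST")
})

test_that("pedigrees survive a write/read round trip and row permutation", {
  cohort <- toyCohort()
  ped <- withr::local_tempfile(fileext = ".ped")
  writePedigree(cohort, ped)
  back <- readPedigree(ped)
  expect_equal(members(back), members(cohort))

  # permuting rows yields the same families up to ordering
  lines <- readLines(ped)
  shuf <- withr::local_tempfile(fileext = ".ped")
  # keep a valid file: permutation of data rows only
  writeLines(rev(lines), shuf)
  back2 <- readPedigree(shuf)
  m1 <- members(back)[order(members(back)$individual_id), ]
  m2 <- members(back2)[order(members(back2)$individual_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})

test_that("cohort validity catches inconsistent pedigrees", {
  df <- members(toyCohort())
  bad <- df
  bad$affection[bad$individual_id == "III-1"] <- "unaffected"  # sequenced member
  expect_error(FamilyCohort(bad), "sequenced")
  bad2 <- df
  bad2$cobb[[1]] <- c(35, 8)   # affected below the diagnostic threshold
  expect_error(FamilyCohort(bad2), "Cobb")
  bad3 <- df
  bad3$father_id[bad3$individual_id == "I-1"] <- "III-1"  # parental cycle
  expect_error(FamilyCohort(bad3), "cyclic")
})

test_that("GMT term sets parse, normalize and round-trip", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:0005874\tmicrotubule\tINVS\tDNAH1",
               "GO:XXXX\tdup and case\tinvs\tINVS\tttn"), gmt)
  ts <- readTermSets(gmt)
  expect_equal(length(ts), 2)
  expect_equal(termGenes(ts)[["GO:0005874"]], c("INVS", "DNAH1"))
  # lowercase stored uppercase; duplicate within a line counted once
  expect_setequal(termGenes(ts)[["GO:XXXX"]], c("INVS", "TTN"))
  out <- withr::local_tempfile(fileext = ".gmt")
  writeTermSets(ts, out)
  back <- readTermSets(out)
  expect_equal(termGenes(back), termGenes(ts))
  expect_equal(termNames(back), termNames(ts))

  gmt2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:1\tok\tA", "GO:2\tno genes"), gmt2)
  expect_error(readTermSets(gmt2), "line 2")
})

test_that("a biallelic VCF record parses into one annotated entry", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  v <- toyVariants(vrow(pop_af = 0.03),
                   list(c(S1 = "het", S2 = "het", S3 = "het")))
  writeVariantsVcf(v, vcf)
  back <- readVariants(vcf)
  expect_equal(length(back), 1)
  df <- variantMeta(back)
  expect_equal(df$pop_af, 0.03)
  expect_equal(df$sift, "damaging")
  expect_equal(df$polyphen2, "benign")
  expect_true(all(genotypes(back) == "het"))
})

test_that("multiallelic records decompose and conserve genotype carriers", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=EXAC_AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=SIFT_PRED,Number=1,Type=String,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t200\t.\tC\tA,T\t.\tPASS\tGENE=TTN;CSQCLASS=nonsynonymous_SNV;EXAC_AF=0.002,0.001;SIFT_PRED=D\tGT\t1/2\t0/1"
  ), vcf)
  back <- readVariants(vcf)
  expect_equal(length(back), 2)
  df <- variantMeta(back)
  expect_equal(df$chrom, c("chr1", "chr1"))
  expect_equal(df$pos, c(200L, 200L))
  expect_equal(df$ref, c("C", "C"))
  expect_setequal(df$alt, c("A", "T"))
  expect_equal(df$pop_af[df$alt == "A"], 0.002)
  expect_equal(df$pop_af[df$alt == "T"], 0.001)
  gt <- genotypes(back)
  # S1 called 1/2: het carrier of both decomposed entries, each once
  expect_equal(unname(gt[, "S1"]), c("het", "het"))
  expect_equal(unname(gt[df$alt == "A", "S2"]), "het")
  expect_equal(unname(gt[df$alt == "T", "S2"]), "hom_ref")
})

test_that("a record without the frequency key is novel; bad genotypes go missing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  v <- toyVariants(vrow(pop_af = NA_real_),
                   list(c(S1 = "het", S2 = "hom_alt")))
  writeVariantsVcf(v, vcf)
  back <- readVariants(vcf)
  expect_true(is.na(popAF(back)))

  lines <- readLines(vcf)
  lines[length(lines)] <- sub("0/1", "0/x", lines[length(lines)])
  writeLines(lines, vcf)
  expect_message(back2 <- readVariants(vcf), "1 malformed")
  expect_equal(unname(genotypes(back2)[1, "S1"]), "missing")
})

test_that("annotated variants survive a VCF round trip", {
  meta <- rbind(
    vrow(pos = 101L, consequence = "stopgain", pop_af = 0.0004),
    vrow(pos = 202L, ref = "AT", alt = "A",
         consequence = "frameshift_deletion", pop_af = NA_real_,
         sift = "missing", polyphen2 = "missing", lrt = "missing",
         mutation_taster = "missing", annotated_in_db = FALSE),
    vrow(pos = 303L, consequence = "other", sift = "benign")
  )
  v <- toyVariants(meta, list(c(S1 = "het"), c(S1 = "hom_alt", S2 = "het"),
                              c(S2 = "missing")), samples = c("S1", "S2"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(v, vcf)
  back <- readVariants(vcf)
  expect_equal(variantMeta(back), variantMeta(v))
  expect_equal(genotypes(back), genotypes(v))
})

test_that("VCF samples absent from the pedigree trigger a warning only", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  v <- toyVariants(vrow(), list(c(`II-1` = "het", OUTSIDER = "het")))
  writeVariantsVcf(v, vcf)
  expect_warning(back <- readVariants(vcf, cohort = toyCohort()), "OUTSIDER")
  expect_true("OUTSIDER" %in% sampleIds(back))
})

test_that("multi-gene annotations fall back to the first symbol with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  v <- toyVariants(vrow(gene = "AAA|BBB"), list(c(S1 = "het")))
  writeVariantsVcf(v, vcf)
  expect_warning(back <- readVariants(vcf), "first symbol")
  expect_equal(genes(back), "AAA")
  # a declared primary-gene key silences the fallback
  v2 <- toyVariants(cbind(vrow(gene = "AAA|BBB")), list(c(S1 = "het")))
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeVariantsVcf(v2, vcf2)
  lines <- readLines(vcf2)
  lines <- append(lines, "##INFO=<ID=PRIMARY,Number=1,Type=String,Description=\"primary gene\">",
                  after = 2)
  lines[length(lines)] <- sub("GENE=", "PRIMARY=BBB;GENE=", lines[length(lines)])
  writeLines(lines, vcf2)
  back2 <- expect_no_warning(
    readVariants(vcf2, dialect = vcfDialect(primary_gene = "PRIMARY")))
  expect_equal(genes(back2), "BBB")
})
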