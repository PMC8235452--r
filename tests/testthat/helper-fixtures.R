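# Small in-code fixtures shared across the test files.

# a three-generation family: founder couple, two children (one married-in
# spouse), two grandchildren; sequenced affected members in two generations
toyCohort <- function() {
  df <- data.frame(
    family_id = "G",
    individual_id = c("I-1", "I-2", "II-1", "II-2", "II-1S", "III-1", "III-2"),
    father_id = c(NA, NA, "I-1", "I-1", NA, "II-1", "II-1"),
    mother_id = c(NA, NA, "I-2", "I-2", NA, "II-1S", "II-1S"),
    sex = c("male", "female", "male", "female", "female", "female", "male"),
    affection = c("affected", "unaffected", "affected", "confirmed_negative",
                  "unaffected", "affected", "unaffected"),
    sequenced = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  df$cobb <- list(c(35), numeric(0), c(22, 31), numeric(0), numeric(0),
                  c(48), numeric(0))
  FamilyCohort(df)
}

# build an AnnotatedVariants object from compact per-variant specs.
# gts: named list variant -> named character vector of genotype states;
# samples not named in a vector default to hom_ref.
toyVariants <- function(meta, gts = NULL, samples = NULL) {
  meta <- as.data.frame(meta)
  if (is.null(samples)) {
    samples <- unique(unlist(lapply(gts, names)))
  }
  gt <- matrix("hom_ref", nrow = nrow(meta), ncol = length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_along(gts)) {
    g <- gts[[i]]
    gt[i, names(g)] <- g
  }
  AnnotatedVariants(meta, gt)
}

# one meta row with sensible defaults, overridable field by field
vrow <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                 gene = "GENE1", consequence = "nonsynonymous_SNV",
                 pop_af = 0.01, sift = "damaging", polyphen2 = "benign",
                 lrt = "benign", mutation_taster = "benign",
                 annotated_in_db = TRUE, artifact_flag = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             consequence = consequence, pop_af = pop_af, sift = sift,
             polyphen2 = polyphen2, lrt = lrt,
             mutation_taster = mutation_taster,
             annotated_in_db = annotated_in_db, artifact_flag = artifact_flag,
             stringsAsFactors = FALSE)
}

# brute-force cascade oracle: apply the five predicates independently and
# intersect, ignoring stage order entirely
bruteForceRetained <- function(variants, cohort, family_id,
                               config = filterConfig()) {
  keep <- passesConsequence(variants, config) &
    passesArtifact(variants, config) &
    passesFrequency(variants, config) &
    passesDamaging(variants, config) &
    sharedByAllSequenced(variants, cohort, family_id)
  sort(variantKeys(variants)[keep])
}

# exact hypergeometric right tail by direct summation with choose();
# exact in double arithmetic while every binomial stays below 2^53
exactRightTail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
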