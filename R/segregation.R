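#' Classify co-segregation of a variant with the affection phenotype
#'
#' Given genotypes of additionally genotyped family members (typically
#' confirmatory Sanger genotyping beyond the exome-sequenced discovery
#' set), tallies carriers among affected and unaffected members and calls
#' the segregation pattern:
#'
#' * `full` -- every genotyped affected member carries the variant AND no
#'   genotyped unaffected member does;
#' * `none` -- at least one genotyped affected member is a non-carrier AND
#'   at least one genotyped unaffected member is a carrier (both
#'   violations);
#' * `partial` -- exactly one of the two violations.
#'
#' `confirmed_negative` members are pooled with `unaffected`;
#' `unknown`-status members are excluded from the tallies, as are members
#' with missing genotypes.  A carrier is any member with at least one alt
#' allele (`het` or `hom_alt`).  Reduced penetrance and phenocopies are
#' deliberately not modeled: the three-way rule is a declared
#' classification convention, not a penetrance inference.
#'
#' @param variantGenotypes named character vector (individual_id ->
#'   genotype state) for the variant site, covering the genotyped members.
#' @param cohort a [FamilyCohort-class].
#' @param family_id the family being classified.
#' @param variant_key identifier echoed into the result (e.g.
#'   `"chr1:100:A:G"`).
#' @param gene gene symbol echoed into the result.
#' @param discovery_set individual ids of the exome discovery set; used
#'   only to flag low-information calls (no additional affected or no
#'   additional unaffected member genotyped beyond this set).  Defaults to
#'   the family's sequenced members.
#' @return One-row data.frame with the carrier tallies
#'   (`n_affected_genotyped`, `n_affected_carriers`,
#'   `n_unaffected_genotyped`, `n_unaffected_carriers`), the `call`, and
#'   `low_information`.
#' @examples
#' sim <- simulateCohort(simulationParams(n_families = 1, seed = 3))
#' fam <- familyIds(sim$cohort)[1]
#' gts <- genotypes(sim$variants)[1, ]
#' classifySegregation(gts, sim$cohort, fam,
#'                     variant_key = variantKeys(sim$variants)[1],
#'                     gene = genes(sim$variants)[1])
#' @export
classifySegregation <- function(variantGenotypes, cohort, family_id,
                                variant_key = NA_character_,
                                gene = NA_character_,
                                discovery_set = sequencedSamples(cohort, family_id)) {
  fam <- familyMembers(cohort, family_id)
  ids <- intersect(fam$individual_id, names(variantGenotypes))
  gts <- variantGenotypes[ids]
  genotyped <- ids[gts != "missing"]
  if (!length(genotyped)) {
    stop(sprintf("no genotyped member of family '%s' for variant %s",
                 family_id, variant_key))
  }
  aff <- fam$affection[match(genotyped, fam$individual_id)]
  status <- ifelse(aff == "affected", "affected",
                   ifelse(aff %in% c("unaffected", "confirmed_negative"),
                          "unaffected", NA))
  keep <- !is.na(status)
  genotyped <- genotyped[keep]
  status <- status[keep]
  carrier <- variantGenotypes[genotyped] %in% c("het", "hom_alt")
  nAffG <- sum(status == "affected")
  nAffC <- sum(carrier & status == "affected")
  nUnaffG <- sum(status == "unaffected")
  nUnaffC <- sum(carrier & status == "unaffected")
  affViolation <- nAffC < nAffG        # an affected non-carrier exists
  unaffViolation <- nUnaffC > 0        # an unaffected carrier exists
  call <- if (!affViolation && !unaffViolation) "full"
          else if (affViolation && unaffViolation) "none"
          else "partial"
  extra <- setdiff(genotyped, discovery_set)
  extraStatus <- status[match(extra, genotyped)]
  lowInfo <- !(any(extraStatus == "affected") && any(extraStatus == "unaffected"))
  data.frame(variant_key = variant_key, gene = gene, family_id = family_id,
             n_affected_genotyped = nAffG, n_affected_carriers = nAffC,
             n_unaffected_genotyped = nUnaffG, n_unaffected_carriers = nUnaffC,
             call = call, low_information = lowInfo,
             stringsAsFactors = FALSE)
}

#' Segregation calls for a set of candidate variants
#'
#' Runs [classifySegregation()] for each entry of `variants` in the given
#' family, using the variant genotype matrix (which may cover members
#' beyond the discovery set).
#'
#' @param variants an [AnnotatedVariants-class] object.
#' @param cohort a [FamilyCohort-class].
#' @param family_id the family to classify in.
#' @param discovery_set see [classifySegregation()].
#' @return data.frame, one row per variant entry.
#' @export
segregationTable <- function(variants, cohort, family_id,
                             discovery_set = sequencedSamples(cohort, family_id)) {
  gt <- genotypes(variants)
  keys <- variantKeys(variants)
  gs <- genes(variants)
  out <- lapply(seq_len(length(variants)), function(i) {
    classifySegregation(gt[i, ], cohort, family_id, variant_key = keys[i],
                        gene = gs[i], discovery_set = discovery_set)
  })
  do.call(rbind, out)
}
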