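#' Filter-cascade predicates
#'
#' The per-variant predicates of the family filter cascade, each vectorized
#' over the entries of an [AnnotatedVariants-class] object:
#'
#' * `passesConsequence()`: consequence class is on the whitelist
#'   (nonsynonymous SNVs, coding indels, stop gains, splice sites by
#'   default; synonymous and non-coding calls fall into `"other"` and are
#'   dropped).
#' * `passesArtifact()`: not flagged as a known artifact and not on the
#'   configured blacklist of variant keys (always TRUE when the artifact
#'   stage is switched off).
#' * `passesFrequency()`: population allele frequency strictly below the
#'   threshold, or novel (absent from the frequency database).
#' * `passesDamaging()`: for variants annotated in the prediction database,
#'   at least `damaging_min_predictors` of SIFT/Polyphen2/LRT/
#'   MutationTaster call "damaging"; variants absent from the database are
#'   not subject to the rule and pass iff `retain_if_unannotated`.
#'
#' @param variants an [AnnotatedVariants-class] object.
#' @param config a [FilterConfig-class] (see [filterConfig()]).
#' @return Logical vector, one element per variant entry.
#' @name cascadePredicates
NULL

#' @rdname cascadePredicates
#' @export
passesConsequence <- function(variants, config = filterConfig()) {
  variantMeta(variants)$consequence %in% config@consequence_whitelist
}

#' @rdname cascadePredicates
#' @export
passesArtifact <- function(variants, config = filterConfig()) {
  if (!config@drop_artifacts) return(rep(TRUE, length(variants)))
  df <- variantMeta(variants)
  !(df$artifact_flag | variantKeys(variants) %in% config@artifact_keys)
}

#' @rdname cascadePredicates
#' @export
passesFrequency <- function(variants, config = filterConfig()) {
  af <- popAF(variants)
  is.na(af) | af < config@maf_threshold
}

#' @rdname cascadePredicates
#' @export
passesDamaging <- function(variants, config = filterConfig()) {
  df <- variantMeta(variants)
  nDamaging <- rowSums(predictionMatrix(variants) == "damaging")
  ifelse(df$annotated_in_db,
         nDamaging >= config@damaging_min_predictors,
         config@retain_if_unannotated)
}

#' Number of predictors calling a variant damaging
#'
#' @inheritParams cascadePredicates
#' @return Integer vector of damaging calls (0-4) per variant entry.
#' @export
damagingPredictorCount <- function(variants) {
  as.integer(rowSums(predictionMatrix(variants) == "damaging"))
}

#' Shared-by-all-sequenced-members predicate
#'
#' TRUE for a variant entry iff every sequenced member of the family
#' carries the alt allele (genotype `het` or `hom_alt`).  A missing
#' genotype in any sequenced member fails the test (no imputation is
#' attempted).  A single sequenced member trivially shares its own
#' variants.
#'
#' @param variants an [AnnotatedVariants-class] object whose genotype
#'   matrix covers the family's sequenced members.
#' @param cohort a [FamilyCohort-class].
#' @param family_id which family's sequenced members to quantify over.
#' @return Logical vector, one element per variant entry.
#' @export
sharedByAllSequenced <- function(variants, cohort, family_id) {
  seqIds <- sequencedSamples(cohort, family_id)
  if (!length(seqIds)) {
    stop(sprintf("family '%s' has no sequenced member", family_id))
  }
  gt <- genotypes(variants)
  absent <- setdiff(seqIds, colnames(gt))
  if (length(absent)) {
    stop(sprintf("no genotypes for sequenced member(s) %s of family '%s'",
                 paste(absent, collapse = ", "), family_id))
  }
  sub <- gt[, seqIds, drop = FALSE]
  if (length(variants) &&
      any(rowSums(sub != "missing") == 0)) {
    bad <- which(rowSums(sub != "missing") == 0)[1]
    stop(sprintf("variant %s: no sequenced member of family '%s' genotyped",
                 variantKeys(variants)[bad], family_id))
  }
  rowSums(sub == "het" | sub == "hom_alt") == length(seqIds)
}

#' Run the per-family filter cascade
#'
#' Applies the five filter stages in order -- consequence whitelist,
#' known-artifact strip, population-frequency cutoff, damaging-prediction
#' rule, shared-by-all-sequenced-members -- and records a funnel of
#' input/output counts per stage.  Stage order affects only the funnel
#' counts: the retained set equals the intersection of the per-predicate
#' pass sets.  The cascade never looks across families; cross-family logic
#' lives in the aggregation step.
#'
#' @param variants an [AnnotatedVariants-class] object with genotypes for
#'   the family's sequenced members.
#' @param cohort a [FamilyCohort-class].
#' @param family_id the family to filter for.
#' @param config a [FilterConfig-class] (see [filterConfig()]).
#' @return A list with elements
#'   \describe{
#'     \item{retained}{[AnnotatedVariants-class] of retained entries,
#'       sorted by (chrom, pos, alt).}
#'     \item{funnel}{data.frame with columns `stage`, `n_in`, `n_out`;
#'       counts are monotone non-increasing.}
#'   }
#' @examples
#' sim <- simulateCohort(simulationParams(n_families = 2, seed = 1))
#' res <- runCascade(sim$variants, sim$cohort, familyIds(sim$cohort)[1])
#' res$funnel
#' @export
runCascade <- function(variants, cohort, family_id, config = filterConfig()) {
  # every predicate is row-wise, so the masks are computed once on the full
  # set and the funnel follows from their cumulative conjunction; this is
  # what makes stage order irrelevant for membership
  masks <- list(
    consequence = passesConsequence(variants, config),
    artifact    = passesArtifact(variants, config),
    frequency   = passesFrequency(variants, config),
    damaging    = passesDamaging(variants, config),
    family_sharing = sharedByAllSequenced(variants, cohort, family_id)
  )
  keep <- rep(TRUE, length(variants))
  funnel <- data.frame(stage = names(masks),
                       n_in = NA_integer_, n_out = NA_integer_)
  for (i in seq_along(masks)) {
    funnel$n_in[i] <- sum(keep)
    keep <- keep & masks[[i]]
    funnel$n_out[i] <- sum(keep)
  }
  retained <- variants[keep]
  df <- variantMeta(retained)
  ord <- order(df$chrom, df$pos, df$alt)
  list(retained = retained[ord], funnel = funnel)
}

#' Tabulate retained variants for one family
#'
#' Flat table of a family's retained variants as written by the pipeline:
#' coordinates, gene, consequence, population frequency (empty = novel),
#' number of damaging predictors, and the sequenced members' genotypes.
#'
#' @param retained [AnnotatedVariants-class] of retained entries.
#' @param cohort a [FamilyCohort-class].
#' @param family_id the family the entries were retained for.
#' @return data.frame, one row per retained entry.
#' @export
retainedTable <- function(retained, cohort, family_id) {
  df <- variantMeta(retained)
  seqIds <- sequencedSamples(cohort, family_id)
  gt <- genotypes(retained)[, seqIds, drop = FALSE]
  carriers <- apply(gt, 1, function(g) {
    paste(sprintf("%s=%s", seqIds, g), collapse = ",")
  })
  if (!length(carriers)) carriers <- character(0)
  data.frame(family_id = rep(family_id, nrow(df)),
             chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
             gene = df$gene, consequence = df$consequence,
             pop_af = ifelse(is.na(df$pop_af), "", as.character(df$pop_af)),
             n_damaging_predictors = damagingPredictorCount(retained),
             genotypes = carriers,
             stringsAsFactors = FALSE)
}
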