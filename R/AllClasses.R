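#' @import methods
NULL

#' Controlled vocabularies
#'
#' Character constants shared across the package: functional consequence
#' classes, the four in-silico predictors, normalized genotype states, and
#' affection states.  `defaultConsequenceWhitelist()` returns every
#' consequence class considered potentially protein-altering (all classes
#' except `"other"`, which absorbs synonymous and non-coding calls).
#'
#' @return Character vectors of the corresponding vocabulary.
#' @examples
#' consequenceClasses()
#' defaultConsequenceWhitelist()
#' @export
consequenceClasses <- function() {
  c("nonsynonymous_SNV", "nonframeshift_deletion", "nonframeshift_insertion",
    "frameshift_deletion", "frameshift_insertion", "stopgain", "splice_site",
    "other")
}

#' @rdname consequenceClasses
#' @export
defaultConsequenceWhitelist <- function() {
  setdiff(consequenceClasses(), "other")
}

#' @rdname consequenceClasses
#' @export
predictorNames <- function() {
  c("SIFT", "Polyphen2", "LRT", "MutationTaster")
}

#' @rdname consequenceClasses
#' @export
genotypeStates <- function() {
  c("hom_ref", "het", "hom_alt", "missing")
}

#' @rdname consequenceClasses
#' @export
affectionStates <- function() {
  c("affected", "unaffected", "confirmed_negative", "unknown")
}

.predictionStates <- c("damaging", "benign", "missing")

.predictionCols <- c("sift", "polyphen2", "lrt", "mutation_taster")

# ---------------------------------------------------------------------------
# FamilyCohort

.checkPedigreeAcyclic <- function(df) {
  # topological peel: repeatedly remove individuals whose parents are all
  # already removed; a stuck non-empty remainder means a parental cycle
  for (fam in unique(df$family_id)) {
    sub <- df[df$family_id == fam, , drop = FALSE]
    parent <- rbind(cbind(sub$individual_id, sub$father_id),
                    cbind(sub$individual_id, sub$mother_id))
    parent <- parent[!is.na(parent[, 2]), , drop = FALSE]
    remaining <- sub$individual_id
    while (length(remaining)) {
      hasInsideParent <- vapply(remaining, function(i) {
        any(parent[parent[, 1] == i, 2] %in% remaining)
      }, logical(1))
      if (all(hasInsideParent)) {
        return(sprintf("cyclic parental links in family '%s'", fam))
      }
      remaining <- remaining[hasInsideParent]
    }
  }
  TRUE
}

.validFamilyCohort <- function(object) {
  df <- object@members
  msgs <- character(0)
  need <- c("family_id", "individual_id", "father_id", "mother_id",
            "sex", "affection", "sequenced", "cobb")
  if (!all(need %in% names(df))) {
    return(sprintf("members must have columns: %s",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  }
  key <- paste(df$family_id, df$individual_id, sep = "/")
  if (anyDuplicated(key)) {
    msgs <- c(msgs, sprintf("duplicate individual_id within family: %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  if (!all(df$sex %in% c("male", "female", "unknown"))) {
    msgs <- c(msgs, "sex must be one of male/female/unknown")
  }
  if (!all(df$affection %in% affectionStates())) {
    msgs <- c(msgs, "affection must be one of the four affection states")
  }
  for (side in c("father_id", "mother_id")) {
    pid <- df[[side]]
    ok <- is.na(pid) | paste(df$family_id, pid, sep = "/") %in% key
    if (!all(ok)) {
      bad <- paste(df$family_id[!ok], pid[!ok], sep = "/")
      msgs <- c(msgs, sprintf("%s not found in family: %s", side,
                              paste(unique(bad), collapse = ", ")))
    }
  }
  # affected individuals with recorded curvature: every Cobb angle >= 10
  aff <- df$affection == "affected"
  angs <- unlist(df$cobb[aff], use.names = FALSE)
  if (length(angs) && any(angs < 10)) {
    msgs <- c(msgs, "affected individuals must have Cobb angles >= 10 degrees")
  }
  # discovery design: sequenced members are affected.  (A family with no
  # sequenced member is representable -- e.g. a plain 6-column pedigree
  # file -- but the filter cascade refuses to run on it.)
  if (any(df$sequenced & df$affection != "affected")) {
    bad <- unique(df$family_id[df$sequenced & df$affection != "affected"])
    msgs <- c(msgs, sprintf("sequenced members must be affected (family %s)",
                            paste(bad, collapse = ", ")))
  }
  if (!length(msgs)) {
    acy <- .checkPedigreeAcyclic(df)
    if (!isTRUE(acy)) msgs <- c(msgs, acy)
  }
  if (length(msgs)) msgs else TRUE
}

#' FamilyCohort: pedigree members of one or more families
#'
#' Container for pedigree information across a cohort of multiplex families.
#' Each row of `members` is one individual with family membership, parental
#' links (`NA` = founder/unknown), sex, four-state affection status, a flag
#' marking the exome-sequenced discovery set, and recorded Cobb angles
#' (degrees of spinal curvature; a list column, possibly empty per member).
#'
#' Validity enforces: unique individual ids within a family, parental ids
#' resolving within the same family, acyclic parental links, every family
#' having at least one sequenced member, sequenced members being affected
#' (the discovery design), and recorded curvatures of affected members being
#' at least 10 degrees (the diagnostic threshold for scoliosis).
#'
#' @slot members data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affection`, `sequenced`, `cobb`.
#' @export
setClass("FamilyCohort", representation(members = "data.frame"),
         validity = .validFamilyCohort)

#' Construct a FamilyCohort
#'
#' @param members data.frame as described for [FamilyCohort-class].  A
#'   missing `cobb` column is filled with empty angle lists.
#' @return A `FamilyCohort` object.
#' @examples
#' trio <- data.frame(
#'   family_id = "A", individual_id = c("F", "M", "C"),
#'   father_id = c(NA, NA, "F"), mother_id = c(NA, NA, "M"),
#'   sex = c("male", "female", "female"),
#'   affection = c("unaffected", "unaffected", "affected"),
#'   sequenced = c(FALSE, FALSE, TRUE)
#' )
#' FamilyCohort(trio)
#' @export
FamilyCohort <- function(members) {
  members <- as.data.frame(members)
  if (is.null(members$cobb)) {
    members$cobb <- replicate(nrow(members), numeric(0), simplify = FALSE)
  }
  members$family_id <- as.character(members$family_id)
  members$individual_id <- as.character(members$individual_id)
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  members$sequenced <- as.logical(members$sequenced)
  rownames(members) <- NULL
  new("FamilyCohort", members = members)
}

# ---------------------------------------------------------------------------
# AnnotatedVariants

.validAnnotatedVariants <- function(object) {
  df <- object@meta
  gt <- object@genotypes
  msgs <- character(0)
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "pop_af",
            .predictionCols, "annotated_in_db", "artifact_flag")
  if (!all(need %in% names(df))) {
    return(sprintf("meta must have columns: %s",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (nrow(df) != nrow(gt)) {
    return("genotype matrix must have one row per variant")
  }
  if (nrow(df)) {
    if (any(df$alt == df$ref)) msgs <- c(msgs, "alt allele must differ from ref")
    if (any(df$pos < 1)) msgs <- c(msgs, "pos must be >= 1 (1-based)")
    af <- df$pop_af
    if (any(!is.na(af) & (af < 0 | af > 1))) {
      msgs <- c(msgs, "pop_af must lie in [0, 1] when present")
    }
    if (!all(df$consequence %in% consequenceClasses())) {
      msgs <- c(msgs, "unknown consequence class")
    }
    for (p in .predictionCols) {
      if (!all(df[[p]] %in% .predictionStates)) {
        msgs <- c(msgs, sprintf("%s predictions must be damaging/benign/missing", p))
      }
    }
    unann <- !df$annotated_in_db
    if (any(unann)) {
      allMissing <- Reduce(`&`, lapply(.predictionCols,
                                       function(p) df[[p]] == "missing"))
      if (!all(allMissing[unann])) {
        msgs <- c(msgs, "variants not in the prediction database must have all predictions missing")
      }
    }
    if (length(gt) && !all(gt %in% genotypeStates())) {
      msgs <- c(msgs, "genotypes must be hom_ref/het/hom_alt/missing")
    }
  }
  if (length(msgs)) msgs else TRUE
}

#' AnnotatedVariants: annotated variant calls with per-sample genotypes
#'
#' One row per (site, alt allele): multiallelic VCF records are decomposed
#' on import.  `meta` carries the coordinates (1-based, VCF convention,
#' alleles as given by the caller), the assigned gene symbol, the functional
#' consequence class, the population allele frequency (`NA` = absent from
#' the reference frequency database, i.e. novel), the four in-silico
#' predictions (SIFT, Polyphen2, LRT, MutationTaster; each
#' damaging/benign/missing), whether the site is present in the prediction
#' database at all, and a known-artifact flag.  `genotypes` is a character
#' matrix (variants x samples) over the four normalized genotype states;
#' a carrier is any sample with at least one alt allele (het or hom_alt).
#'
#' @slot meta data.frame of per-variant annotations.
#' @slot genotypes character matrix, rows parallel to `meta`, columns named
#'   by sample id.
#' @export
setClass("AnnotatedVariants",
         representation(meta = "data.frame", genotypes = "matrix"),
         validity = .validAnnotatedVariants)

#' Construct an AnnotatedVariants object
#'
#' @param meta data.frame as described for [AnnotatedVariants-class].
#'   Missing `annotated_in_db` is inferred (TRUE iff any prediction is
#'   non-missing); missing `artifact_flag` defaults to FALSE; missing
#'   prediction columns default to "missing".
#' @param genotypes character matrix of normalized genotype states with one
#'   row per variant and one named column per sample.
#' @return An `AnnotatedVariants` object.
#' @export
AnnotatedVariants <- function(meta, genotypes = NULL) {
  meta <- as.data.frame(meta)
  for (p in .predictionCols) {
    if (is.null(meta[[p]])) meta[[p]] <- rep("missing", nrow(meta))
  }
  if (is.null(meta$annotated_in_db)) {
    meta$annotated_in_db <- Reduce(`|`, lapply(.predictionCols, function(p) {
      meta[[p]] != "missing"
    }))
    if (!nrow(meta)) meta$annotated_in_db <- logical(0)
  }
  if (is.null(meta$artifact_flag)) meta$artifact_flag <- rep(FALSE, nrow(meta))
  if (is.null(meta$pop_af)) meta$pop_af <- rep(NA_real_, nrow(meta))
  meta$pos <- as.integer(meta$pos)
  if (is.null(genotypes)) {
    genotypes <- matrix(character(0), nrow = nrow(meta), ncol = 0)
  }
  storage.mode(genotypes) <- "character"
  rownames(meta) <- NULL
  new("AnnotatedVariants", meta = meta, genotypes = genotypes)
}

# ---------------------------------------------------------------------------
# TermSets

.validTermSets <- function(object) {
  msgs <- character(0)
  n <- length(object@term_ids)
  if (length(object@term_names) != n || length(object@genes) != n) {
    return("term_ids, term_names and genes must have equal length")
  }
  if (anyDuplicated(object@term_ids)) msgs <- c(msgs, "duplicate term ids")
  sizes <- lengths(object@genes)
  if (any(sizes == 0)) msgs <- c(msgs, "every term must have a non-empty gene set")
  gg <- unlist(object@genes, use.names = FALSE)
  if (length(gg) && !identical(gg, toupper(gg))) {
    msgs <- c(msgs, "gene symbols must be uppercase-normalized")
  }
  if (length(msgs)) msgs else TRUE
}

#' TermSets: named gene sets (GMT-style)
#'
#' A collection of annotation terms, each a named set of gene symbols —
#' GO-like cellular-component terms and cytogenetic bands are both carried
#' this way.  Symbols are uppercase-normalized and deduplicated within a
#' term.  The union of all member genes defines the default background
#' universe for overrepresentation testing.
#'
#' @slot term_ids character vector of unique term identifiers.
#' @slot term_names character vector of human-readable descriptions.
#' @slot genes list of character vectors of member gene symbols, parallel
#'   to `term_ids`.
#' @export
setClass("TermSets",
         representation(term_ids = "character", term_names = "character",
                        genes = "list"),
         validity = .validTermSets)

#' Construct a TermSets collection
#'
#' @param term_ids,term_names character vectors, one entry per term.
#' @param genes list of character vectors of gene symbols (uppercased and
#'   deduplicated on construction).
#' @return A `TermSets` object.
#' @examples
#' TermSets("GO:0005874", "microtubule", list(c("INVS", "DNAH1")))
#' @export
TermSets <- function(term_ids, term_names, genes) {
  genes <- lapply(genes, function(g) unique(toupper(as.character(g))))
  names(genes) <- term_ids
  new("TermSets", term_ids = as.character(term_ids),
      term_names = as.character(term_names), genes = genes)
}

# ---------------------------------------------------------------------------
# FilterConfig

.validFilterConfig <- function(object) {
  msgs <- character(0)
  if (!(object@maf_threshold > 0 && object@maf_threshold <= 1)) {
    msgs <- c(msgs, "maf_threshold must satisfy 0 < t <= 1")
  }
  if (!(object@damaging_min_predictors >= 1L &&
        object@damaging_min_predictors <= 4L)) {
    msgs <- c(msgs, "damaging_min_predictors must be in 1..4")
  }
  if (!all(object@consequence_whitelist %in% consequenceClasses())) {
    msgs <- c(msgs, "consequence_whitelist contains unknown classes")
  }
  if (length(msgs)) msgs else TRUE
}

#' FilterConfig: thresholds and switches of the filter cascade
#'
#' @slot maf_threshold numeric; variants with a population allele frequency
#'   at or above this are dropped (novel variants always pass).  The default
#'   0.05 deliberately admits low-frequency as well as rare variants, on the
#'   hypothesis that a disease affecting 2-3% of the population can be
#'   driven by alleles too common for a strict rare-variant cutoff.
#' @slot consequence_whitelist character; consequence classes retained.
#' @slot damaging_min_predictors integer; minimum number of the four
#'   predictors calling "damaging" for a database-annotated variant to pass.
#' @slot retain_if_unannotated logical; whether variants absent from the
#'   prediction database bypass the damaging rule.
#' @slot drop_artifacts logical; whether the artifact stage is applied.
#' @slot artifact_keys character; blacklist of known-artifact variant keys
#'   (`"chrom:pos:ref:alt"`).
#' @export
setClass("FilterConfig",
         representation(maf_threshold = "numeric",
                        consequence_whitelist = "character",
                        damaging_min_predictors = "integer",
                        retain_if_unannotated = "logical",
                        drop_artifacts = "logical",
                        artifact_keys = "character"),
         validity = .validFilterConfig)

#' Construct a FilterConfig
#'
#' @param maf_threshold population-frequency cutoff (default 0.05); a
#'   variant passes iff its frequency is strictly below the threshold or
#'   it is novel (absent from the frequency database).
#' @param consequence_whitelist retained consequence classes; defaults to
#'   every class except `"other"` (nonsynonymous SNVs, coding indels,
#'   stop gains, splice sites).
#' @param damaging_min_predictors minimum damaging calls among SIFT,
#'   Polyphen2, LRT and MutationTaster (default 1).
#' @param retain_if_unannotated keep variants absent from the prediction
#'   database (default TRUE: the damaging rule is conditional on the variant
#'   being annotated there).
#' @param drop_artifacts apply the known-artifact strip (default TRUE).
#' @param artifact_keys character blacklist of `"chrom:pos:ref:alt"` keys
#'   (default empty).
#' @return A `FilterConfig` object.
#' @examples
#' filterConfig()
#' filterConfig(maf_threshold = 0.01, damaging_min_predictors = 2)
#' @export
filterConfig <- function(maf_threshold = 0.05,
                         consequence_whitelist = defaultConsequenceWhitelist(),
                         damaging_min_predictors = 1L,
                         retain_if_unannotated = TRUE,
                         drop_artifacts = TRUE,
                         artifact_keys = character(0)) {
  new("FilterConfig", maf_threshold = maf_threshold,
      consequence_whitelist = consequence_whitelist,
      damaging_min_predictors = as.integer(damaging_min_predictors),
      retain_if_unannotated = retain_if_unannotated,
      drop_artifacts = drop_artifacts,
      artifact_keys = as.character(artifact_keys))
}
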