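#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# FamilyCohort methods

#' @rdname accessors
#' @aliases members,FamilyCohort-method
#' @export
setMethod("members", "FamilyCohort", function(x, ...) x@members)

#' @rdname accessors
#' @export
setMethod("familyIds", "FamilyCohort", function(x) unique(x@members$family_id))

#' @rdname accessors
#' @export
setMethod("familyMembers", "FamilyCohort", function(x, family_id) {
  df <- x@members[x@members$family_id == family_id, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("no family '%s' in cohort", family_id))
  rownames(df) <- NULL
  df
})

#' @rdname accessors
#' @export
setMethod("sequencedSamples", "FamilyCohort", function(x, family_id) {
  df <- familyMembers(x, family_id)
  df$individual_id[df$sequenced]
})

#' @export
#' @describeIn FamilyCohort number of families in the cohort.
setMethod("length", "FamilyCohort", function(x) length(familyIds(x)))

setMethod("show", "FamilyCohort", function(object) {
  df <- object@members
  cat(sprintf("FamilyCohort: %d families, %d individuals (%d sequenced, %d affected)\n",
              length(unique(df$family_id)), nrow(df), sum(df$sequenced),
              sum(df$affection == "affected")))
  sizes <- table(df$family_id)
  cat("  family sizes: ", paste(sprintf("%s=%d", names(sizes), sizes),
                                collapse = " "), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# AnnotatedVariants methods

#' @export
#' @describeIn AnnotatedVariants number of variant entries (post
#'   multiallelic decomposition).
setMethod("length", "AnnotatedVariants", function(x) nrow(x@meta))

#' @rdname accessors
#' @export
setMethod("variantMeta", "AnnotatedVariants", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("variantKeys", "AnnotatedVariants", function(x) {
  with(x@meta, paste(chrom, pos, ref, alt, sep = ":"))
})

#' @rdname accessors
#' @export
setMethod("genes", "AnnotatedVariants", function(x, ...) x@meta$gene)

#' @rdname accessors
#' @export
setMethod("popAF", "AnnotatedVariants", function(x) x@meta$pop_af)

#' @rdname accessors
#' @export
setMethod("genotypes", "AnnotatedVariants", function(x) x@genotypes)

#' @rdname accessors
#' @export
setMethod("sampleIds", "AnnotatedVariants", function(x) colnames(x@genotypes))

#' @rdname accessors
#' @export
setMethod("predictionMatrix", "AnnotatedVariants", function(x) {
  m <- as.matrix(x@meta[, .predictionCols, drop = FALSE])
  colnames(m) <- predictorNames()
  m
})

#' @export
#' @describeIn AnnotatedVariants subset variant entries (rows).
setMethod("[", "AnnotatedVariants", function(x, i, j, ..., drop = FALSE) {
  meta <- x@meta[i, , drop = FALSE]
  rownames(meta) <- NULL
  gt <- x@genotypes[i, , drop = FALSE]
  new("AnnotatedVariants", meta = meta, genotypes = gt)
})

setMethod("show", "AnnotatedVariants", function(object) {
  df <- object@meta
  cat(sprintf("AnnotatedVariants: %d entries, %d samples\n",
              nrow(df), ncol(object@genotypes)))
  if (nrow(df)) {
    cat(sprintf("  genes: %d distinct; novel AF: %d; flagged artifacts: %d\n",
                length(unique(df$gene)), sum(is.na(df$pop_af)),
                sum(df$artifact_flag)))
    tab <- sort(table(df$consequence), decreasing = TRUE)
    cat("  consequences: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n",
        sep = "")
  }
})

# ---------------------------------------------------------------------------
# TermSets methods

#' @export
#' @describeIn TermSets number of terms.
setMethod("length", "TermSets", function(x) length(x@term_ids))

#' @rdname accessors
#' @export
setMethod("termIds", "TermSets", function(x) x@term_ids)

#' @rdname accessors
#' @export
setMethod("termNames", "TermSets", function(x) x@term_names)

#' @rdname accessors
#' @export
setMethod("termGenes", "TermSets", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("universeGenes", "TermSets", function(x) {
  sort(unique(unlist(x@genes, use.names = FALSE)))
})

#' @export
#' @describeIn TermSets subset terms.
setMethod("[", "TermSets", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@term_ids)
  new("TermSets", term_ids = x@term_ids[i], term_names = x@term_names[i],
      genes = x@genes[i])
})

setMethod("show", "TermSets", function(object) {
  sizes <- lengths(object@genes)
  cat(sprintf("TermSets: %d terms, %d distinct genes (term sizes %d-%d, median %g)\n",
              length(object@term_ids),
              length(unique(unlist(object@genes, use.names = FALSE))),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L,
              if (length(sizes)) stats::median(sizes) else 0))
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n")
  cat(sprintf("  MAF threshold (strict <): %g\n", object@maf_threshold))
  cat(sprintf("  consequence whitelist: %s\n",
              paste(object@consequence_whitelist, collapse = ", ")))
  cat(sprintf("  damaging rule: >= %d of %d predictors; unannotated %s\n",
              object@damaging_min_predictors, length(predictorNames()),
              if (object@retain_if_unannotated) "retained" else "dropped"))
  cat(sprintf("  artifact strip: %s (%d blacklisted keys)\n",
              if (object@drop_artifacts) "on" else "off",
              length(object@artifact_keys)))
})
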