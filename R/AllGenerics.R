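#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the package's S4 containers.  Slot access is never needed
#' by user code.
#'
#' @param x a `FamilyCohort`, `AnnotatedVariants` or `TermSets` object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname accessors
#' @export
setGeneric("familyMembers", function(x, family_id) standardGeneric("familyMembers"))

#' @rdname accessors
#' @export
setGeneric("sequencedSamples", function(x, family_id) standardGeneric("sequencedSamples"))

#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname accessors
#' @export
setGeneric("variantMeta", function(x) standardGeneric("variantMeta"))

#' @rdname accessors
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("popAF", function(x) standardGeneric("popAF"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("predictionMatrix", function(x) standardGeneric("predictionMatrix"))

#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))

#' @rdname accessors
#' @export
setGeneric("termGenes", function(x, ...) standardGeneric("termGenes"))

#' @rdname accessors
#' @export
setGeneric("universeGenes", function(x) standardGeneric("universeGenes"))
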