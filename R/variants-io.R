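#' VCF annotation dialect
#'
#' Names of the INFO keys carrying the per-site annotations consumed by
#' [readVariants()].  The defaults match the package's own written VCFs:
#' a gene symbol, a consequence-class token, a population allele frequency
#' (per alt allele; absent = novel), the four predictor calls in dbNSFP
#' letter codes, and a Flag marking presence in the prediction database.
#'
#' @param gene INFO key of the gene symbol (may be comma-separated; see
#'   `primary_gene`).
#' @param consequence INFO key of the consequence class.
#' @param af INFO key of the population allele frequency (`Number=A` or a
#'   single value).
#' @param sift,polyphen2,lrt,mutation_taster INFO keys of the predictor
#'   calls (`D`/`A` = damaging; `T`, `B`, `N`, `P` = benign; `.` = missing).
#' @param dbnsfp_flag INFO Flag key marking sites present in the prediction
#'   database; when the key is not declared in the header, presence is
#'   inferred from any non-missing predictor call.
#' @param primary_gene optional INFO key naming the primary gene symbol for
#'   sites annotated against transcripts of several genes; when `NULL`, the
#'   first symbol of a comma-separated `gene` value is taken and a warning
#'   reports how often that happened.
#' @return A named list understood by [readVariants()] and
#'   [writeVariantsVcf()].
#' @examples
#' vcfDialect()
#' @export
vcfDialect <- function(gene = "GENE", consequence = "CSQCLASS",
                       af = "EXAC_AF", sift = "SIFT_PRED",
                       polyphen2 = "PP2_PRED", lrt = "LRT_PRED",
                       mutation_taster = "MT_PRED", dbnsfp_flag = "DBNSFP",
                       primary_gene = NULL) {
  list(gene = gene, consequence = consequence, af = af, sift = sift,
       polyphen2 = polyphen2, lrt = lrt, mutation_taster = mutation_taster,
       dbnsfp_flag = dbnsfp_flag, primary_gene = primary_gene)
}

# dbNSFP letter codes -> three-state prediction
.decodePrediction <- function(x) {
  out <- rep("missing", length(x))
  out[!is.na(x) & x %in% c("D", "A")] <- "damaging"
  out[!is.na(x) & x %in% c("T", "B", "N", "P")] <- "benign"
  out
}

# normalize one GT string relative to alt-allele index `altIdx`
# (single-allele calls are hemizygous: any alt allele counts as hom_alt)
.normalizeGT <- function(gt, altIdx) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (!length(alleles) || any(!grepl("^[0-9]+$", alleles))) return(NA_character_)
  hits <- sum(alleles == as.character(altIdx))
  if (length(alleles) == 1) {
    if (hits > 0) "hom_alt" else "hom_ref"
  } else if (hits == 0) "hom_ref" else if (hits == 1) "het" else "hom_alt"
}

.infoPerAlt <- function(inf, key, rec, altIdx) {
  # pull INFO `key` for decomposed entries (record index `rec`, alt index
  # `altIdx`); tolerates Number=1 and Number=A encodings and absent keys
  n <- length(rec)
  if (is.null(key) || !key %in% names(inf)) return(rep(NA_character_, n))
  col <- inf[[key]]
  if (is.list(col) || methods::is(col, "List")) {
    col <- as.list(col)
    vapply(seq_len(n), function(i) {
      el <- col[[rec[i]]]
      val <- if (length(el) >= altIdx[i]) el[[altIdx[i]]]
             else if (length(el)) el[[1]] else NA
      if (is.null(val)) NA_character_ else as.character(val)
    }, character(1))
  } else {
    as.character(col)[rec]
  }
}

#' Read annotated variants from a VCF
#'
#' Parses a VCF v4.2 whose INFO fields carry gene, consequence,
#' population-frequency and in-silico prediction annotations under the key
#' names given by `dialect`.  Multiallelic records are decomposed into one
#' entry per alt allele; per-sample genotypes are normalized to
#' `hom_ref`/`het`/`hom_alt`/`missing` relative to that alt allele (a
#' sample called `1/2` is a het carrier of both decomposed entries).  A
#' missing frequency key means the site is absent from the reference
#' frequency database and is stored as `NA` ("novel").  Malformed genotype
#' strings are set to `missing` and their count reported via a message;
#' samples not present in `cohort` (when given) trigger a warning but their
#' genotypes are kept.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @param dialect INFO key names, see [vcfDialect()].
#' @param cohort optional [FamilyCohort-class] used only to warn about VCF
#'   samples absent from the pedigree.
#' @return An [AnnotatedVariants-class] object.
#' @export
readVariants <- function(path, dialect = vcfDialect(), cohort = NULL) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  v <- VariantAnnotation::readVcf(path, genome = "cohort")
  rr <- SummarizedExperiment::rowRanges(v)
  altList <- VariantAnnotation::alt(v)
  nAlt <- S4Vectors::elementNROWS(altList)
  rec <- rep(seq_along(nAlt), nAlt)
  altIdx <- sequence(nAlt)
  altChar <- as.character(unlist(altList))
  gtRaw <- VariantAnnotation::geno(v)$GT
  samples <- colnames(gtRaw)
  if (!is.null(cohort)) {
    missingPed <- setdiff(samples, members(cohort)$individual_id)
    if (length(missingPed)) {
      warning(sprintf("%d VCF sample(s) absent from pedigree: %s",
                      length(missingPed), paste(missingPed, collapse = ", ")))
    }
  }
  n <- length(rec)
  inf <- VariantAnnotation::info(v)
  pull <- function(key, default) {
    out <- .infoPerAlt(inf, key, rec, altIdx)
    out[is.na(out)] <- as.character(default)
    out
  }
  # multi-gene annotations (several transcripts of different genes) are
  # pipe-joined; without a primary-gene key the first symbol is taken
  geneRaw <- pull(dialect$gene, NA_character_)
  multi <- grepl("|", geneRaw, fixed = TRUE)
  if (is.null(dialect$primary_gene)) {
    if (any(multi)) {
      warning(sprintf("%d entr(ies) listed several gene symbols; first symbol taken",
                      sum(multi)))
    }
    gene <- sub("\\|.*$", "", geneRaw)
  } else {
    primary <- pull(dialect$primary_gene, NA_character_)
    gene <- ifelse(is.na(primary), sub("\\|.*$", "", geneRaw), primary)
  }
  af <- suppressWarnings(as.numeric(pull(dialect$af, NA)))
  preds <- lapply(c(sift = "sift", polyphen2 = "polyphen2", lrt = "lrt",
                    mutation_taster = "mutation_taster"), function(k) {
    .decodePrediction(pull(dialect[[k]], NA_character_))
  })
  inf <- VariantAnnotation::info(v)
  if (!is.null(dialect$dbnsfp_flag) && dialect$dbnsfp_flag %in% names(inf)) {
    inDb <- as.logical(inf[[dialect$dbnsfp_flag]])[rec]
    inDb[is.na(inDb)] <- FALSE
  } else {
    inDb <- Reduce(`|`, lapply(preds, function(p) p != "missing"))
  }
  # a flagged-in-db site may still have all-missing predictions; the reverse
  # (predictions without the flag) upgrades the flag for consistency
  inDb <- inDb | Reduce(`|`, lapply(preds, function(p) p != "missing"))
  meta <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[rec],
    pos = GenomicRanges::start(rr)[rec],
    ref = as.character(VariantAnnotation::ref(v))[rec],
    alt = altChar,
    gene = gene,
    consequence = pull(dialect$consequence, "other"),
    pop_af = af,
    sift = preds$sift, polyphen2 = preds$polyphen2, lrt = preds$lrt,
    mutation_taster = preds$mutation_taster,
    annotated_in_db = inDb,
    artifact_flag = FALSE,
    stringsAsFactors = FALSE
  )
  meta$consequence[!meta$consequence %in% consequenceClasses()] <- "other"
  # normalize genotypes via a per-(GT string, alt index) lookup so the cost
  # scales with distinct GT strings, not with the genotype matrix
  gt <- matrix("missing", nrow = n, ncol = length(samples),
               dimnames = list(NULL, samples))
  nMalformed <- 0L
  uniqGT <- unique(as.vector(gtRaw))
  for (a in unique(altIdx)) {
    lut <- vapply(uniqGT, .normalizeGT, character(1), altIdx = a)
    rows <- which(altIdx == a)
    mapped <- lut[match(gtRaw[rec[rows], , drop = FALSE], uniqGT)]
    nMalformed <- nMalformed + sum(is.na(mapped))
    mapped[is.na(mapped)] <- "missing"
    gt[rows, ] <- mapped
  }
  if (nMalformed > 0) {
    message(sprintf("readVariants: %d malformed genotype string(s) set to missing",
                    nMalformed))
  }
  AnnotatedVariants(meta, gt)
}

#' Write annotated variants as a VCF
#'
#' Writes one biallelic VCF v4.2 record per variant entry with the
#' annotation INFO keys of `dialect` (frequency omitted for novel sites,
#' prediction keys omitted for sites absent from the prediction database)
#' and per-sample GT fields.  Reading the file back with [readVariants()]
#' recovers an equivalent object.
#'
#' @param variants an [AnnotatedVariants-class] object.
#' @param path output file path.
#' @param dialect INFO key names, see [vcfDialect()].
#' @return `path`, invisibly.
#' @export
writeVariantsVcf <- function(variants, path, dialect = vcfDialect()) {
  df <- variantMeta(variants)
  gt <- genotypes(variants)
  samples <- colnames(gt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(df$chrom)),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            dialect$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence class\">",
            dialect$consequence),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Population allele frequency\">",
            dialect$af),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s call\">",
            c(dialect$sift, dialect$polyphen2, dialect$lrt,
              dialect$mutation_taster), predictorNames()),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Present in prediction database\">",
            dialect$dbnsfp_flag),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  encodePred <- function(p) c(damaging = "D", benign = "T", missing = ".")[p]
  gtCode <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    kv <- c(sprintf("%s=%s", dialect$gene, df$gene[i]),
            sprintf("%s=%s", dialect$consequence, df$consequence[i]))
    if (!is.na(df$pop_af[i])) {
      kv <- c(kv, sprintf("%s=%s", dialect$af, format(df$pop_af[i],
                                                      digits = 8,
                                                      scientific = FALSE)))
    }
    if (df$annotated_in_db[i]) {
      kv <- c(kv, dialect$dbnsfp_flag,
              sprintf("%s=%s",
                      c(dialect$sift, dialect$polyphen2, dialect$lrt,
                        dialect$mutation_taster),
                      encodePred(c(df$sift[i], df$polyphen2[i], df$lrt[i],
                                   df$mutation_taster[i]))))
    }
    fields <- c(df$chrom[i], df$pos[i], ".", df$ref[i], df$alt[i], ".",
                "PASS", paste(kv, collapse = ";"))
    if (length(samples)) fields <- c(fields, "GT", gtCode[gt[i, ]])
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
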