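#' Build the cross-family gene-sharing table
#'
#' Combines per-family retained variant sets into a gene-level table:
#' which families carry a retained variant in each gene, how many families
#' that is (distinct families -- two variants in one gene in one family
#' count once), and whether the *identical* variant (exact
#' chrom:pos:ref:alt key) was retained in two or more families.
#'
#' @param perFamilyRetained named list (family_id ->
#'   [AnnotatedVariants-class]) of retained entries per family, as produced
#'   by [runCascade()].
#' @return data.frame with columns `gene`, `n_families`, `families`
#'   (comma-joined ids) and `identical_variant`, sorted by decreasing
#'   `n_families` then gene.
#' @examples
#' sim <- simulateCohort(simulationParams(n_families = 3, seed = 7))
#' ret <- filterCohort(sim$variants, sim$cohort)$retained
#' head(buildSharingTable(ret))
#' @export
buildSharingTable <- function(perFamilyRetained) {
  stopifnot(length(perFamilyRetained) >= 1, !is.null(names(perFamilyRetained)))
  long <- do.call(rbind, lapply(names(perFamilyRetained), function(fam) {
    v <- perFamilyRetained[[fam]]
    if (!length(v)) return(NULL)
    data.frame(family_id = fam, gene = genes(v), key = variantKeys(v),
               stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    return(data.frame(gene = character(0), n_families = integer(0),
                      families = character(0), identical_variant = logical(0)))
  }
  famsByGene <- lapply(split(long$family_id, long$gene), unique)
  # identical variant: one key retained in >= 2 distinct families
  keyFams <- lapply(split(long$family_id, paste(long$gene, long$key, sep = "|")),
                    unique)
  sharedKeyGenes <- unique(sub("\\|.*$", "",
                               names(keyFams)[lengths(keyFams) >= 2]))
  out <- data.frame(
    gene = names(famsByGene),
    n_families = lengths(famsByGene),
    families = vapply(famsByGene, function(f) paste(sort(f), collapse = ","),
                      character(1)),
    identical_variant = names(famsByGene) %in% sharedKeyGenes,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_families, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of genes shared by at least t families
#'
#' @param sharingTable data.frame from [buildSharingTable()] (only the
#'   `n_families` column is used).
#' @param thresholds integer thresholds t (default `c(2, 3, 4, 5)`).
#' @return data.frame with columns `min_families` and `n_genes`, where
#'   `n_genes` counts genes shared by >= t distinct families; monotone
#'   non-increasing in t.
#' @export
sharingCensus <- function(sharingTable, thresholds = c(2L, 3L, 4L, 5L)) {
  data.frame(
    min_families = as.integer(thresholds),
    n_genes = vapply(thresholds, function(t) {
      sum(sharingTable$n_families >= t)
    }, integer(1))
  )
}

.mafBinLabels <- c("novel", "<0.001", "0.001-0.01", "0.01-0.05", ">=0.05")

.mafBin <- function(af) {
  # half-open upward bins; the top bin is only occupied under a
  # non-default frequency threshold
  out <- rep(.mafBinLabels[1], length(af))
  out[!is.na(af) & af < 0.001] <- .mafBinLabels[2]
  out[!is.na(af) & af >= 0.001 & af < 0.01] <- .mafBinLabels[3]
  out[!is.na(af) & af >= 0.01 & af < 0.05] <- .mafBinLabels[4]
  out[!is.na(af) & af >= 0.05] <- .mafBinLabels[5]
  factor(out, levels = .mafBinLabels)
}

#' Summarize retained variants across families
#'
#' The cohort-level reporting tables: per-consequence counts with half-up
#' integer percentages, minor-allele-frequency bin counts and percentages
#' over \{novel, <0.001, 0.001-0.01, 0.01-0.05\}, per-chromosome counts,
#' per-family counts with the median, and totals (variants summed over
#' families, distinct genes, and the count/percentage of "private" genes
#' seen in exactly one family, reported to one decimal).  Every retained
#' entry falls in exactly one consequence class and exactly one frequency
#' bin; percentages are computed on unrounded ratios.
#'
#' @param perFamilyRetained named list (family_id ->
#'   [AnnotatedVariants-class]) of retained entries per family.
#' @return A list of data.frames/values: `consequences`, `maf_bins`,
#'   `chromosomes`, `per_family`, and `totals` (a one-row data.frame with
#'   `total_variants`, `total_genes`, `median_per_family`,
#'   `private_genes`, `private_gene_pct`).
#' @export
summarizeRetained <- function(perFamilyRetained) {
  stopifnot(length(perFamilyRetained) >= 1, !is.null(names(perFamilyRetained)))
  metas <- lapply(names(perFamilyRetained), function(fam) {
    v <- perFamilyRetained[[fam]]
    df <- variantMeta(v)
    if (nrow(df)) df$family_id <- fam
    df
  })
  all <- do.call(rbind, metas[vapply(metas, nrow, integer(1)) > 0])
  perFam <- data.frame(family_id = names(perFamilyRetained),
                       n_variants = vapply(perFamilyRetained, length,
                                           integer(1)))
  rownames(perFam) <- NULL
  if (is.null(all)) {
    stop("summarizeRetained: no retained variants in any family")
  }
  csq <- table(factor(all$consequence, levels = consequenceClasses()))
  csq <- csq[csq > 0]
  consequences <- data.frame(consequence = names(csq),
                             n = as.integer(csq),
                             pct = as.numeric(percentOfTotal(as.integer(csq))))
  consequences <- consequences[order(-consequences$n), , drop = FALSE]
  rownames(consequences) <- NULL
  bins <- table(.mafBin(all$pop_af))
  bins <- bins[names(bins) != ">=0.05" | bins > 0]
  maf_bins <- data.frame(maf_bin = names(bins), n = as.integer(bins),
                         pct = as.numeric(percentOfTotal(as.integer(bins))))
  chrom <- table(all$chrom)
  chromosomes <- data.frame(chrom = names(chrom), n = as.integer(chrom))
  chromosomes <- chromosomes[order(-chromosomes$n), , drop = FALSE]
  rownames(chromosomes) <- NULL
  famsPerGene <- lengths(lapply(split(all$family_id, all$gene), unique))
  nGenes <- length(famsPerGene)
  nPrivate <- sum(famsPerGene == 1)
  totals <- data.frame(
    total_variants = nrow(all),
    total_genes = nGenes,
    median_per_family = stats::median(perFam$n_variants),
    private_genes = nPrivate,
    private_gene_pct = roundHalfUp(100 * nPrivate / nGenes, 1)
  )
  list(consequences = consequences, maf_bins = maf_bins,
       chromosomes = chromosomes, per_family = perFam, totals = totals)
}

#' Filter every family of a cohort
#'
#' Convenience wrapper running [runCascade()] for each family against a
#' shared variant set, returning the per-family retained sets and funnels.
#'
#' @param variants an [AnnotatedVariants-class] with genotypes for all
#'   sequenced members of the cohort.
#' @param cohort a [FamilyCohort-class].
#' @param config a [FilterConfig-class].
#' @return list with `retained` (named list family_id ->
#'   `AnnotatedVariants`) and `funnels` (data.frame with a `family_id`
#'   column stacking the per-family funnels).
#' @export
filterCohort <- function(variants, cohort, config = filterConfig()) {
  fams <- familyIds(cohort)
  retained <- vector("list", length(fams))
  names(retained) <- fams
  funnels <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    res <- runCascade(variants, cohort, fams[i], config)
    retained[[i]] <- res$retained
    funnels[[i]] <- cbind(family_id = fams[i], res$funnel)
  }
  list(retained = retained, funnels = do.call(rbind, funnels))
}
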