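#' Simulation parameters for a synthetic family cohort
#'
#' Defaults describe the cohort structure the pipeline is designed for:
#' 23 multigeneration families, three generations deep, each contributing
#' 3-5 exome-sequenced affected members, with per-family planted
#' (causal-candidate) variant counts spanning 11-128 with median 51, and a
#' population-frequency mixture of 12\% novel, 18\% below 0.001, 22\% in
#' 0.001-0.01 and 48\% in 0.01-0.05.  Planted variants are transmitted to
#' every sequenced member; four decoy classes each violate exactly one
#' filter stage (not shared by all sequenced members; frequency at or
#' above the threshold; all four predictors benign; non-whitelisted
#' consequence), in known per-family counts recorded in the truth table.
#'
#' @slot n_families number of families (default 23).
#' @slot sequenced_range min/max sequenced affected members per family
#'   (default 3-5).
#' @slot depth pedigree depth in generations (default 3; must be >= 2).
#' @slot n_background_genes size of the gene universe (default 12000).
#' @slot n_term_sets,genes_per_term term-set collection shape (default 60
#'   terms of 120 genes).
#' @slot planted_term_fold target fold enrichment of the planted term in
#'   the retained gene list (default 2.5, the magnitude of the strongest
#'   cellular-component enrichments such a cohort is expected to show).
#' @slot variants_median,variants_range,variants_logsd per-family planted
#'   variant counts: lognormal with this median and log-sd, clamped to the
#'   range (defaults 51, 11-128, 0.61).
#' @slot maf_mixture probability masses over the frequency bins
#'   \{novel, <0.001, 0.001-0.01, 0.01-0.05\}; must sum to 1.
#' @slot prediction_sensitivity P(a planted, database-annotated variant
#'   receives at least one damaging call) (default 1).
#' @slot unannotated_fraction fraction of planted variants absent from the
#'   prediction database (default 0.1).
#' @slot decoy_rates per-class decoy counts as a fraction of the family's
#'   planted count, named `unshared`, `high_af`, `benign`, `consequence`.
#' @slot recurrent_variant_prob probability that a planted variant reuses
#'   the identical variant key already planted in an earlier family
#'   (default 0.03), exercising the identical-variant flag.
#' @slot penetrance,phenocopy_rate affection-status knobs for
#'   non-sequenced members: carriers are affected with probability
#'   `penetrance`, non-carriers affected with probability `phenocopy_rate`
#'   (defaults 1 and 0: affection deterministically equals carrier
#'   status).
#' @slot contigs,contig_length toy contig set over which variant positions
#'   are drawn uniformly.
#' @slot seed integer seed fixing every random draw of the generator.
#' @export
setClass("SimulationParams",
         representation(n_families = "integer", sequenced_range = "integer",
                        depth = "integer", n_background_genes = "integer",
                        n_term_sets = "integer", genes_per_term = "integer",
                        planted_term_fold = "numeric",
                        variants_median = "numeric", variants_range = "integer",
                        variants_logsd = "numeric", maf_mixture = "numeric",
                        prediction_sensitivity = "numeric",
                        unannotated_fraction = "numeric",
                        decoy_rates = "numeric",
                        recurrent_variant_prob = "numeric",
                        penetrance = "numeric", phenocopy_rate = "numeric",
                        contigs = "character", contig_length = "integer",
                        seed = "integer"),
         validity = function(object) {
           msgs <- character(0)
           if (abs(sum(object@maf_mixture) - 1) > 1e-9) {
             msgs <- c(msgs, "maf_mixture masses must sum to 1")
           }
           if (object@depth < 2L) msgs <- c(msgs, "depth must be >= 2 generations")
           if (diff(object@sequenced_range) < 0 || object@sequenced_range[1] < 1) {
             msgs <- c(msgs, "sequenced_range must be a non-degenerate positive range")
           }
           if (diff(object@variants_range) < 0) {
             msgs <- c(msgs, "variants_range must be non-degenerate")
           }
           if (!all(c("unshared", "high_af", "benign", "consequence") %in%
                    names(object@decoy_rates))) {
             msgs <- c(msgs, "decoy_rates must name unshared/high_af/benign/consequence")
           }
           if (length(msgs)) msgs else TRUE
         })

#' Construct simulation parameters
#'
#' See [SimulationParams-class] for the meaning and rationale of each
#' parameter; the defaults are the cohort conditions the package is
#' validated under.
#'
#' @param n_families,sequenced_range,depth cohort structure.
#' @param n_background_genes,n_term_sets,genes_per_term annotation shape.
#' @param planted_term_fold planted-term effect size.
#' @param variants_median,variants_range,variants_logsd per-family planted
#'   counts.
#' @param maf_mixture frequency-bin masses (novel, <0.001, 0.001-0.01,
#'   0.01-0.05).
#' @param prediction_sensitivity,unannotated_fraction prediction model.
#' @param decoy_rates per-class decoy fractions.
#' @param recurrent_variant_prob identical-variant reuse probability.
#' @param penetrance,phenocopy_rate affection model for non-sequenced
#'   members.
#' @param contigs,contig_length toy contig set.
#' @param seed integer seed.
#' @return A `SimulationParams` object.
#' @examples
#' simulationParams(n_families = 4, seed = 11)
#' @export
simulationParams <- function(n_families = 23L,
                             sequenced_range = c(3L, 5L),
                             depth = 3L,
                             n_background_genes = 12000L,
                             n_term_sets = 60L,
                             genes_per_term = 120L,
                             planted_term_fold = 2.5,
                             variants_median = 51,
                             variants_range = c(11L, 128L),
                             variants_logsd = 0.61,
                             maf_mixture = c(novel = 0.12, rare = 0.18,
                                             low = 0.22, mid = 0.48),
                             prediction_sensitivity = 1.0,
                             unannotated_fraction = 0.1,
                             decoy_rates = c(unshared = 0.3, high_af = 0.3,
                                             benign = 0.2, consequence = 0.2),
                             recurrent_variant_prob = 0.03,
                             penetrance = 1.0, phenocopy_rate = 0.0,
                             contigs = paste0("chr", c(1:22, "X")),
                             contig_length = 50000000L,
                             seed = 1L) {
  new("SimulationParams", n_families = as.integer(n_families),
      sequenced_range = as.integer(sequenced_range), depth = as.integer(depth),
      n_background_genes = as.integer(n_background_genes),
      n_term_sets = as.integer(n_term_sets),
      genes_per_term = as.integer(genes_per_term),
      planted_term_fold = planted_term_fold,
      variants_median = variants_median,
      variants_range = as.integer(variants_range),
      variants_logsd = variants_logsd, maf_mixture = maf_mixture,
      prediction_sensitivity = prediction_sensitivity,
      unannotated_fraction = unannotated_fraction, decoy_rates = decoy_rates,
      recurrent_variant_prob = recurrent_variant_prob,
      penetrance = penetrance, phenocopy_rate = phenocopy_rate,
      contigs = contigs, contig_length = as.integer(contig_length),
      seed = as.integer(seed))
}

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf("SimulationParams: %d families, %d-%d sequenced/family, depth %d, seed %d\n",
              object@n_families, object@sequenced_range[1],
              object@sequenced_range[2], object@depth, object@seed))
  cat(sprintf("  universe %d genes, %d terms x %d genes, planted fold %.2f\n",
              object@n_background_genes, object@n_term_sets,
              object@genes_per_term, object@planted_term_fold))
})

# ---------------------------------------------------------------------------
# pedigree simulation

#' Simulate one multigeneration pedigree
#'
#' Builds an acyclic pedigree of `depth` generations (a founder couple,
#' their children with married-in spouses, grandchildren, ...), plants a
#' carrier lineage rooted in one founder, assigns affection status from
#' carrier status (full penetrance by default, with `penetrance` /
#' `phenocopy_rate` knobs applied to non-sequenced members), and marks the
#' requested number of affected members -- spread over at least two
#' generations -- as the sequenced discovery set.  Affected members
#' receive one or two Cobb angles in 15-65 degrees; a fraction of
#' examined, unaffected blood relatives is recorded as confirmed negative.
#'
#' @param params a [SimulationParams-class] object.
#' @param family_id family identifier (also prefixes member ids so that
#'   sample ids are unique cohort-wide).
#' @param seed optional integer; when given, seeds the RNG for a
#'   reproducible standalone pedigree.  Inside [simulateCohort()] the
#'   cohort seed governs.
#' @return list with `members` (a data.frame of pedigree rows), `lineage`
#'   (ids of the carrier lineage) and `generation` (named integer vector).
#' @export
simulatePedigree <- function(params, family_id = "F01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- params@depth
  if (depth < 2L) stop("pedigree depth must be >= 2 generations")
  nseq <- sample(seq(params@sequenced_range[1], params@sequenced_range[2]), 1)

  mid <- function(g, j, spouse = FALSE) {
    sprintf("%s-G%d-%d%s", family_id, g, j, if (spouse) "S" else "")
  }
  members <- data.frame(individual_id = c(mid(1, 1), mid(1, 2)),
                        father_id = NA_character_, mother_id = NA_character_,
                        sex = c("male", "female"),
                        generation = c(1L, 1L), stringsAsFactors = FALSE)
  couples <- list(list(father = mid(1, 1), mother = mid(1, 2), gen = 1L))
  idx <- 0L
  for (g in seq(2L, depth)) {
    newCouples <- list()
    for (cp in couples) {
      if (cp$gen != g - 1L) next
      nKids <- if (g == 2L) sample(3:4, 1) else sample(2:3, 1)
      for (k in seq_len(nKids)) {
        idx <- idx + 1L
        kid <- mid(g, idx)
        sex <- sample(c("male", "female"), 1)
        members <- rbind(members, data.frame(
          individual_id = kid, father_id = cp$father, mother_id = cp$mother,
          sex = sex, generation = g, stringsAsFactors = FALSE))
        if (g < depth) {
          sp <- mid(g, idx, spouse = TRUE)
          members <- rbind(members, data.frame(
            individual_id = sp, father_id = NA_character_,
            mother_id = NA_character_,
            sex = if (sex == "male") "female" else "male",
            generation = g, stringsAsFactors = FALSE))
          newCouples <- c(newCouples, list(list(
            father = if (sex == "male") kid else sp,
            mother = if (sex == "male") sp else kid, gen = g)))
        }
      }
    }
    couples <- c(couples, newCouples)
  }
  generation <- stats::setNames(members$generation, members$individual_id)
  isFounder <- is.na(members$father_id) & is.na(members$mother_id)
  isBlood <- !isFounder | members$individual_id %in% c(mid(1, 1), mid(1, 2))

  # carrier lineage: root founder plus a transmitted subset of descendants,
  # redrawn (then forced) until nseq carriers span >= 2 generations
  root <- mid(1, 1)
  drawLineage <- function() {
    lineage <- root
    for (i in seq_len(nrow(members))) {
      if (isFounder[i]) next
      if ((members$father_id[i] %in% lineage ||
           members$mother_id[i] %in% lineage) && stats::runif(1) < 0.5) {
        lineage <- c(lineage, members$individual_id[i])
      }
    }
    lineage
  }
  lineage <- NULL
  for (try in seq_len(60)) {
    cand <- drawLineage()
    descendants <- setdiff(cand, root)
    if (length(descendants) >= nseq - 1 &&
        length(unique(generation[cand])) >= 2) {
      lineage <- cand
      break
    }
  }
  if (is.null(lineage)) {
    # force transmission down the pedigree until enough carriers exist
    lineage <- root
    for (i in seq_len(nrow(members))) {
      if (isFounder[i]) next
      if (members$father_id[i] %in% lineage ||
          members$mother_id[i] %in% lineage) {
        lineage <- c(lineage, members$individual_id[i])
        if (length(lineage) > nseq + 2) break
      }
    }
  }
  if (length(lineage) < nseq) {
    stop(sprintf("family '%s': cannot place %d sequenced members in a pedigree of %d members",
                 family_id, nseq, nrow(members)))
  }

  # sequenced set: affected carriers across >= 2 generations
  gens <- unique(generation[lineage])
  pick <- c(sample(lineage[generation[lineage] == gens[1]], 1),
            sample(lineage[generation[lineage] == gens[2]], 1))
  rest <- setdiff(lineage, pick)
  if (nseq > 2) pick <- c(pick, sample(rest, nseq - 2))
  sequenced <- pick

  carrier <- members$individual_id %in% lineage
  affected <- carrier
  nonseq <- !(members$individual_id %in% sequenced)
  # penetrance / phenocopy knobs act on non-sequenced members only
  flip <- carrier & nonseq & stats::runif(nrow(members)) > params@penetrance
  affected[flip] <- FALSE
  pheno <- !carrier & nonseq & isBlood &
    stats::runif(nrow(members)) < params@phenocopy_rate
  affected[pheno] <- TRUE

  affection <- ifelse(affected, "affected", "unaffected")
  confNeg <- !affected & isBlood & stats::runif(nrow(members)) < 0.3
  affection[confNeg] <- "confirmed_negative"
  cobb <- lapply(seq_len(nrow(members)), function(i) {
    if (!affected[i]) return(numeric(0))
    round(stats::runif(sample(1:2, 1), 15, 65))
  })
  out <- data.frame(family_id = family_id,
                    individual_id = members$individual_id,
                    father_id = members$father_id,
                    mother_id = members$mother_id,
                    sex = members$sex, affection = affection,
                    sequenced = members$individual_id %in% sequenced,
                    stringsAsFactors = FALSE)
  out$cobb <- cobb
  list(members = out, lineage = lineage, generation = generation)
}

# prune `exclude` and every lineage member whose path to the root passes
# through it (members are in topological order within `ped`)
.pruneLineage <- function(ped, lineage, exclude) {
  eff <- character(0)
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    if (!(id %in% lineage) || id %in% exclude) next
    founder <- is.na(ped$father_id[i]) && is.na(ped$mother_id[i])
    if (founder || ped$father_id[i] %in% eff || ped$mother_id[i] %in% eff) {
      eff <- c(eff, id)
    }
  }
  eff
}

#' Mendelian transmission of genotypes through a family
#'
#' Assigns founder genotypes by binomial draws from each variant's founder
#' allele frequency and transmits alleles to descendants, one allele
#' inherited from each parent.  Variants flagged `planted` are instead
#' forced: the lineage root founder is heterozygous and the alt allele is
#' transmitted deterministically along the carrier lineage (every lineage
#' member heterozygous, everyone else homozygous reference), optionally
#' pruning `exclude` and its downstream lineage, so planted variants are
#' carried by exactly the (pruned) lineage.
#'
#' @param familyMembers data.frame of one family's pedigree rows (as in
#'   `members(cohort)`), parents listed before children.
#' @param founder_af numeric vector of founder allele frequencies, one per
#'   variant (`NA` treated as 0).
#' @param planted logical vector, one per variant.
#' @param lineage character ids of the carrier lineage (first element must
#'   be a founder); required when any variant is planted.
#' @param exclude character ids pruned from the lineage for planted
#'   transmission (default none).
#' @param seed optional integer seed.
#' @return Character matrix of genotype states (variants x members).
#' @examples
#' ped <- simulatePedigree(simulationParams(), "F01", seed = 5)
#' gt <- transmitGenotypes(ped$members, founder_af = c(0.2, NA),
#'                         planted = c(FALSE, TRUE), lineage = ped$lineage)
#' @export
transmitGenotypes <- function(familyMembers, founder_af,
                              planted = rep(FALSE, length(founder_af)),
                              lineage = character(0), exclude = character(0),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nv <- length(founder_af)
  ids <- familyMembers$individual_id
  if (any(planted)) {
    if (!length(lineage)) stop("planted variants require a carrier lineage")
    rootRow <- match(lineage[1], ids)
    if (is.na(rootRow) || !is.na(familyMembers$father_id[rootRow]) ||
        !is.na(familyMembers$mother_id[rootRow])) {
      stop("planted transmission infeasible: lineage root must be a founder of the family")
    }
    eff <- .pruneLineage(familyMembers, lineage, exclude)
  } else {
    eff <- character(0)
  }
  af <- ifelse(is.na(founder_af), 0, founder_af)
  alleles <- matrix(0L, nrow = nv, ncol = length(ids),
                    dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    fa <- familyMembers$father_id[j]
    mo <- familyMembers$mother_id[j]
    if (is.na(fa) && is.na(mo)) {
      draw <- stats::rbinom(nv, 2L, af)
      if (any(planted)) {
        draw[planted] <- if (ids[j] == lineage[1]) 1L else 0L
      }
      alleles[, j] <- draw
    } else {
      inherit <- function(pid) {
        if (is.na(pid)) return(stats::rbinom(nv, 1L, af))  # unlisted parent: population draw
        pc <- alleles[, match(pid, ids)]
        h <- stats::rbinom(nv, 1L, pc / 2)
        if (any(planted)) {
          inLin <- ids[j] %in% eff && pid %in% eff
          h[planted] <- if (inLin) as.integer(pc[planted] >= 1L) else 0L
        }
        h
      }
      alleles[, j] <- inherit(fa) + inherit(mo)
    }
  }
  states <- matrix(genotypeStates()[1:3][alleles + 1L], nrow = nv,
                   dimnames = list(NULL, ids))
  states
}

#' Offspring of a single cross
#'
#' Draws `n` independent offspring genotypes of a father x mother cross by
#' Mendelian sampling (one allele inherited from each parent).
#'
#' @param father_gt,mother_gt parental genotype states (`"hom_ref"`,
#'   `"het"`, `"hom_alt"`).
#' @param n number of offspring.
#' @param seed optional integer seed.
#' @return Character vector of `n` offspring genotype states.
#' @examples
#' table(mendelianCross("het", "hom_ref", 1000, seed = 1))
#' @export
mendelianCross <- function(father_gt, mother_gt, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  count <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  cf <- count[[father_gt]]
  cm <- count[[mother_gt]]
  off <- stats::rbinom(n, 1L, cf / 2) + stats::rbinom(n, 1L, cm / 2)
  genotypeStates()[1:3][off + 1L]
}

# ---------------------------------------------------------------------------
# cohort simulation

.consequenceProbs <- c(nonsynonymous_SNV = 1281, nonframeshift_deletion = 52,
                       nonframeshift_insertion = 34, frameshift_deletion = 25,
                       stopgain = 22, frameshift_insertion = 22,
                       splice_site = 12)

.sampleMaf <- function(n, mixture) {
  # mass 1 is "novel" (absent from the frequency database); the other bins
  # are log-uniform within their frequency range
  bin <- sample(4L, n, replace = TRUE, prob = mixture)
  out <- rep(NA_real_, n)
  seen <- bin > 1L
  lo <- c(NA, 1e-5, 1e-3, 1e-2)[bin[seen]]
  hi <- c(NA, 1e-3, 1e-2, 5e-2)[bin[seen]]
  out[seen] <- 10^(stats::runif(sum(seen), log10(lo), log10(hi)))
  out
}

.sampleAlleles <- function(consequence) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  if (consequence %in% c("nonframeshift_insertion", "frameshift_insertion")) {
    extra <- if (consequence == "nonframeshift_insertion") 3 else sample(c(1, 2, 4), 1)
    c(ref, paste0(ref, paste(sample(bases, extra, replace = TRUE), collapse = "")))
  } else if (consequence %in% c("nonframeshift_deletion", "frameshift_deletion")) {
    extra <- if (consequence == "nonframeshift_deletion") 3 else sample(c(1, 2, 4), 1)
    long <- paste0(ref, paste(sample(bases, extra, replace = TRUE), collapse = ""))
    c(long, ref)
  } else {
    c(ref, sample(setdiff(bases, ref), 1))
  }
}

# probability that a planted variant's gene is drawn from the planted term
# (in excess of its chance hit rate), calibrated by fixed-point iteration so
# the *realized* fold enrichment of the planted term in the distinct retained
# gene list matches targetFold.  Plain proportional excess would undershoot:
# repeated draws collapse to fewer distinct genes (term saturation), and the
# testing background is the term-covered universe C, not all G genes.
# V: total planted variants; K: planted-term size; G: gene universe size;
# C: covered-universe size.
.calibrateExcess <- function(V, K, G, C, targetFold) {
  e <- max(0, (targetFold - 1) * K / G)
  for (iter in seq_len(100)) {
    D <- V * (e + (1 - e) * K / G)               # expected term-gene draws
    k <- K * (1 - (1 - 1 / K)^D)                 # expected distinct term hits
    nOther <- (C - K) * (1 - (1 - 1 / G)^(V * (1 - e)))
    fold <- (k / (k + nOther)) / (K / C)
    if (abs(fold - targetFold) < 1e-8) break
    e <- min(0.9, max(1e-8, e * targetFold / fold))
  }
  e
}

.samplePredictions <- function(damaging) {
  # SIFT anchors a damaging call; the other three are weaker correlates
  if (damaging) {
    c("damaging", sample(c("damaging", "benign"), 3, replace = TRUE,
                         prob = c(0.4, 0.6)))
  } else {
    rep("benign", 4)
  }
}

#' Simulate an annotated family cohort with planted truths
#'
#' Generates the full synthetic input of the pipeline under one seed:
#' pedigrees ([simulatePedigree()]), a gene universe with term sets (one
#' designated planted term whose genes are oversampled among planted
#' variants to a configured fold enrichment), annotated variants
#' (positions over toy contigs, frequency mixture with novel sites,
#' consequence classes in realistic proportions, four-way predictions),
#' genotypes placing every planted variant in all sequenced members of its
#' family, and per-family decoys each violating exactly one filter stage.
#' A truth table records every variant's class and expected cascade
#' outcome.  The same seed reproduces the cohort exactly.
#'
#' @param params a [SimulationParams-class] object.
#' @return list with `cohort` ([FamilyCohort-class]), `variants`
#'   ([AnnotatedVariants-class]), `termSets` ([TermSets-class]), `truth`
#'   (data.frame: `family_id`, `key`, `gene`, `class`,
#'   `expected_retained`, `in_planted_term`), `planted_term`
#'   (the planted term id) and `params`.
#' @examples
#' sim <- simulateCohort(simulationParams(n_families = 2, seed = 42))
#' table(sim$truth$class)
#' @export
simulateCohort <- function(params) {
  set.seed(params@seed)
  geneIds <- sprintf("GENE%05d", seq_len(params@n_background_genes))
  termIdsV <- sprintf("TS%04d", seq_len(params@n_term_sets))
  termGenesL <- lapply(seq_len(params@n_term_sets), function(i) {
    sample(geneIds, params@genes_per_term)
  })
  termSets <- TermSets(termIdsV,
                       sprintf("synthetic term %d", seq_len(params@n_term_sets)),
                       termGenesL)
  plantedTerm <- termIdsV[1]
  plantedGenes <- termGenesL[[1]]

  peds <- list()
  famIds <- sprintf("F%02d", seq_len(params@n_families))
  nPlanted <- pmin(pmax(round(exp(log(params@variants_median) +
                                    stats::rnorm(params@n_families, 0,
                                                 params@variants_logsd))),
                        params@variants_range[1]), params@variants_range[2])
  excess <- .calibrateExcess(V = sum(nPlanted),
                             K = length(plantedGenes),
                             G = params@n_background_genes,
                             C = length(universeGenes(termSets)),
                             targetFold = params@planted_term_fold)

  nDecoyAll <- vapply(nPlanted, function(m) sum(round(params@decoy_rates * m)),
                      numeric(1))
  cap <- sum(nPlanted) + sum(nDecoyAll)  # recurrent reuse only shrinks this
  # flat accumulators: one slot per distinct variant (reg*) and one per
  # per-family truth row (tr*)
  reg <- list(chrom = character(cap), pos = integer(cap), ref = character(cap),
              alt = character(cap), gene = character(cap),
              consequence = character(cap), pop_af = rep(NA_real_, cap),
              sift = character(cap), polyphen2 = character(cap),
              lrt = character(cap), mutation_taster = character(cap),
              annotated_in_db = logical(cap))
  carriers <- vector("list", cap)
  nReg <- 0L
  tr <- list(family_id = character(cap), idx = integer(cap),
             class = character(cap), expected_retained = logical(cap))
  nTr <- 0L
  keyEnv <- new.env(hash = TRUE, parent = emptyenv())
  plantedPool <- integer(0)

  newVariant <- function(consequence, af, damagingCall, annotated, gene) {
    repeat {
      chrom <- sample(params@contigs, 1)
      pos <- sample.int(params@contig_length, 1)
      al <- .sampleAlleles(consequence)
      key <- .vkey(chrom, pos, al[1], al[2])
      if (!exists(key, envir = keyEnv, inherits = FALSE)) break
    }
    assign(key, TRUE, envir = keyEnv)
    i <- nReg + 1L
    nReg <<- i
    reg$chrom[i] <<- chrom; reg$pos[i] <<- pos
    reg$ref[i] <<- al[1]; reg$alt[i] <<- al[2]
    reg$gene[i] <<- gene; reg$consequence[i] <<- consequence
    reg$pop_af[i] <<- af
    preds <- if (annotated) .samplePredictions(damagingCall) else rep("missing", 4)
    reg$sift[i] <<- preds[1]; reg$polyphen2[i] <<- preds[2]
    reg$lrt[i] <<- preds[3]; reg$mutation_taster[i] <<- preds[4]
    reg$annotated_in_db[i] <<- annotated
    i
  }
  addTruth <- function(fam, idx, class, retained) {
    j <- nTr + 1L
    nTr <<- j
    tr$family_id[j] <<- fam; tr$idx[j] <<- idx
    tr$class[j] <<- class; tr$expected_retained[j] <<- retained
  }
  sampleCsq <- function(m) {
    sample(names(.consequenceProbs), m, replace = TRUE,
           prob = .consequenceProbs)
  }

  for (f in seq_along(famIds)) {
    fam <- famIds[f]
    ped <- simulatePedigree(params, fam)
    peds[[fam]] <- ped
    lineage <- ped$lineage
    seqIds <- ped$members$individual_id[ped$members$sequenced]
    # a sequenced member with no sequenced descendant, safe to prune
    prune <- {
      gen <- ped$generation[seqIds]
      names(sort(gen, decreasing = TRUE))[1]
    }
    prunedLineage <- .pruneLineage(ped$members, lineage, prune)
    poolSnapshot <- plantedPool  # recurrent keys come from earlier families

    # planted causal-candidate variants: carried by all sequenced members
    m <- nPlanted[f]
    recur <- length(poolSnapshot) > 0 &
      stats::runif(m) < params@recurrent_variant_prob
    fromTerm <- stats::runif(m) < excess
    csq <- sampleCsq(m)
    afs <- .sampleMaf(m, params@maf_mixture)
    annotated <- stats::runif(m) >= params@unannotated_fraction
    damaging <- stats::runif(m) < params@prediction_sensitivity
    for (v in seq_len(m)) {
      if (recur[v]) {
        idx <- poolSnapshot[sample.int(length(poolSnapshot), 1)]
        carriers[[idx]] <- c(carriers[[idx]], lineage)
        addTruth(fam, idx, "planted", TRUE)
        next
      }
      gene <- if (fromTerm[v]) plantedGenes[sample.int(length(plantedGenes), 1)]
              else geneIds[sample.int(length(geneIds), 1)]
      idx <- newVariant(csq[v], afs[v], damaging[v], annotated[v], gene)
      carriers[[idx]] <- lineage
      plantedPool <- c(plantedPool, idx)
      # an annotated planted variant with no damaging call is expected to
      # be (wrongly) filtered -- that is what prediction_sensitivity < 1 means
      addTruth(fam, idx, "planted", !annotated[v] || damaging[v])
    }

    # decoys: each class violates exactly one cascade stage
    nDecoy <- round(params@decoy_rates * m)
    decoySpec <- list(
      unshared = function() {
        idx <- newVariant(sampleCsq(1), .sampleMaf(1, params@maf_mixture),
                          TRUE, TRUE, geneIds[sample.int(length(geneIds), 1)])
        carriers[[idx]] <<- prunedLineage
        idx
      },
      high_af = function() {
        idx <- newVariant(sampleCsq(1), stats::runif(1, 0.05, 0.3),
                          TRUE, TRUE, geneIds[sample.int(length(geneIds), 1)])
        carriers[[idx]] <<- lineage
        idx
      },
      benign = function() {
        idx <- newVariant(sampleCsq(1), .sampleMaf(1, params@maf_mixture),
                          FALSE, TRUE, geneIds[sample.int(length(geneIds), 1)])
        carriers[[idx]] <<- lineage
        idx
      },
      consequence = function() {
        idx <- newVariant("other", .sampleMaf(1, params@maf_mixture),
                          TRUE, TRUE, geneIds[sample.int(length(geneIds), 1)])
        carriers[[idx]] <<- lineage
        idx
      }
    )
    for (cls in names(decoySpec)) {
      for (d in seq_len(nDecoy[[cls]])) {
        idx <- decoySpec[[cls]]()
        addTruth(fam, idx, paste0("decoy_", cls), FALSE)
      }
    }
  }

  membersAll <- do.call(rbind, lapply(peds, `[[`, "members"))
  rownames(membersAll) <- NULL
  cohort <- FamilyCohort(membersAll)

  meta <- data.frame(chrom = reg$chrom[seq_len(nReg)],
                     pos = reg$pos[seq_len(nReg)],
                     ref = reg$ref[seq_len(nReg)],
                     alt = reg$alt[seq_len(nReg)],
                     gene = reg$gene[seq_len(nReg)],
                     consequence = reg$consequence[seq_len(nReg)],
                     pop_af = reg$pop_af[seq_len(nReg)],
                     sift = reg$sift[seq_len(nReg)],
                     polyphen2 = reg$polyphen2[seq_len(nReg)],
                     lrt = reg$lrt[seq_len(nReg)],
                     mutation_taster = reg$mutation_taster[seq_len(nReg)],
                     annotated_in_db = reg$annotated_in_db[seq_len(nReg)],
                     artifact_flag = FALSE, stringsAsFactors = FALSE)
  gt <- matrix("hom_ref", nrow = nrow(meta), ncol = nrow(membersAll),
               dimnames = list(NULL, membersAll$individual_id))
  for (i in seq_along(carriers)) {
    if (length(carriers[[i]])) gt[i, carriers[[i]]] <- "het"
  }
  variants <- AnnotatedVariants(meta, gt)
  ord <- order(meta$chrom, meta$pos, meta$alt)
  ti <- tr$idx[seq_len(nTr)]
  truthDf <- data.frame(
    family_id = tr$family_id[seq_len(nTr)],
    key = .vkey(meta$chrom[ti], meta$pos[ti], meta$ref[ti], meta$alt[ti]),
    gene = meta$gene[ti],
    class = tr$class[seq_len(nTr)],
    expected_retained = tr$expected_retained[seq_len(nTr)],
    in_planted_term = meta$gene[ti] %in% plantedGenes,
    stringsAsFactors = FALSE)
  list(cohort = cohort, variants = variants[ord], termSets = termSets,
       truth = truthDf, planted_term = plantedTerm, params = params)
}

#' Write a simulated cohort to disk
#'
#' Runs [simulateCohort()] and writes `cohort.vcf`, `cohort.ped`,
#' `terms.gmt` and `truth.tsv` into `out_dir`.  Outputs are byte-identical
#' across runs with the same parameters (including the seed).
#'
#' @param params a [SimulationParams-class] object.
#' @param out_dir output directory (created if needed).
#' @return The simulation list of [simulateCohort()], invisibly, with a
#'   `paths` element added.
#' @export
simulateCohortFiles <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateCohort(params)
  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                ped = file.path(out_dir, "cohort.ped"),
                gmt = file.path(out_dir, "terms.gmt"),
                truth = file.path(out_dir, "truth.tsv"))
  writeVariantsVcf(sim$variants, paths$vcf)
  writePedigree(sim$cohort, paths$ped)
  writeTermSets(sim$termSets, paths$gmt)
  .writeTsv(sim$truth, paths$truth)
  sim$paths <- paths
  invisible(sim)
}
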