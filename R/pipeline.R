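#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either paths to real
#' inputs (`vcf` + `ped` + `gmt`) or simulation parameters (`sim_params`),
#' plus the filter configuration, enrichment options, output directory and
#' seed.  Exactly one input mode must be provided.
#'
#' @param out_dir output directory.
#' @param vcf,ped,gmt input file paths (annotated VCF, pedigree, GMT term
#'   sets); all three required in file mode.
#' @param sim_params a [SimulationParams-class] object for simulation
#'   mode; its seed is overridden by `seed`.
#' @param filter a [FilterConfig-class].
#' @param ease,min_count,adjust enrichment options, see [enrich()].
#' @param segregate whether to write segregation calls for variants in
#'   genes retained by two or more families (default TRUE).
#' @param seed integer seed governing any randomness (simulation mode).
#' @param verbose log stage progress via `message()` (default TRUE).
#' @return A `run_config` list.
#' @export
runConfig <- function(out_dir, vcf = NULL, ped = NULL, gmt = NULL,
                      sim_params = NULL, filter = filterConfig(),
                      ease = TRUE, min_count = 2L, adjust = "BH",
                      segregate = TRUE, seed = 1L, verbose = TRUE) {
  fileMode <- !is.null(vcf) || !is.null(ped) || !is.null(gmt)
  if (fileMode && is.null(sim_params)) {
    if (is.null(vcf) || is.null(ped) || is.null(gmt)) {
      stop("file mode requires vcf, ped and gmt paths")
    }
  } else if (is.null(sim_params)) {
    stop("provide either input paths (vcf/ped/gmt) or sim_params")
  } else if (fileMode) {
    stop("provide input paths or sim_params, not both")
  }
  structure(list(out_dir = out_dir, vcf = vcf, ped = ped, gmt = gmt,
                 sim_params = sim_params, filter = filter, ease = ease,
                 min_count = as.integer(min_count), adjust = adjust,
                 segregate = segregate, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

.configDigest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "verbose")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full prioritization pipeline
#'
#' Orchestrates simulate/read -> per-family filter -> cross-family sharing
#' and census -> summary -> enrichment -> optional segregation, writing
#' TSV outputs and a JSON run manifest into `config$out_dir`:
#' `retained_<family>.tsv`, `funnel.tsv`, `sharing.tsv`, `census.tsv`,
#' `summary_*.tsv`, `enrichment.tsv`, `segregation.tsv` (optional) and
#' `manifest.json` (seed, config digest, per-stage row counts).  Outputs
#' are pure functions of inputs and configuration: rerunning with the same
#' config and seed reproduces them byte for byte.  Any stage error aborts
#' the run with the failing stage named.
#'
#' @param config a [runConfig()] list.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `variants`, `termSets`, `retained`, `funnels`, `sharing`,
#'   `census`, `summary`, `enrichment`, `segregation`, `manifest`).
#' @examples
#' cfg <- runConfig(out_dir = tempfile(),
#'                  sim_params = simulationParams(n_families = 2),
#'                  segregate = FALSE, seed = 9, verbose = FALSE)
#' res <- runPipeline(cfg)
#' res$manifest$stage_counts
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim_params)) {
    log("simulating cohort (seed %d)", config$seed)
    params <- config$sim_params
    params@seed <- config$seed
    sim <- stage("simulate",
                 simulateCohortFiles(params, file.path(config$out_dir, "sim")))
    cohort <- sim$cohort; variants <- sim$variants; termSets <- sim$termSets
  } else {
    for (p in c(config$vcf, config$ped, config$gmt)) {
      if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
    }
    log("reading inputs")
    cohort <- stage("read_pedigree", readPedigree(config$ped))
    variants <- stage("read_variants",
                      readVariants(config$vcf, cohort = cohort))
    termSets <- stage("read_term_sets", readTermSets(config$gmt))
    sim <- NULL
  }

  log("filtering %d variants in %d families", length(variants), length(cohort))
  filt <- stage("filter", filterCohort(variants, cohort, config$filter))
  for (fam in names(filt$retained)) {
    .writeTsv(retainedTable(filt$retained[[fam]], cohort, fam),
              file.path(config$out_dir, sprintf("retained_%s.tsv", fam)))
  }
  .writeTsv(filt$funnels, file.path(config$out_dir, "funnel.tsv"))

  log("aggregating across families")
  sharing <- stage("share", buildSharingTable(filt$retained))
  census <- stage("census", sharingCensus(sharing))
  summry <- stage("report", summarizeRetained(filt$retained))
  .writeTsv(sharing, file.path(config$out_dir, "sharing.tsv"))
  .writeTsv(census, file.path(config$out_dir, "census.tsv"))
  for (nm in c("consequences", "maf_bins", "chromosomes", "per_family",
               "totals")) {
    .writeTsv(summry[[nm]],
              file.path(config$out_dir, sprintf("summary_%s.tsv", nm)))
  }

  geneList <- unique(unlist(lapply(filt$retained, genes), use.names = FALSE))
  log("enrichment over %d genes", length(geneList))
  enrichment <- stage("enrich",
                      enrich(geneList, termSets, ease = config$ease,
                             min_count = config$min_count,
                             adjust = config$adjust))
  .writeTsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))

  segregation <- NULL
  if (isTRUE(config$segregate)) {
    log("segregation calls for multi-family genes")
    multiGenes <- sharing$gene[sharing$n_families >= 2]
    segregation <- stage("segregate", {
      rows <- lapply(names(filt$retained), function(fam) {
        v <- filt$retained[[fam]]
        v <- v[genes(v) %in% multiGenes]
        if (!length(v)) return(NULL)
        segregationTable(v, cohort, fam)
      })
      do.call(rbind, rows)
    })
    if (!is.null(segregation)) {
      .writeTsv(segregation, file.path(config$out_dir, "segregation.tsv"))
    }
  }

  manifest <- list(
    package = "FamVarPrio",
    version = as.character(utils::packageVersion("FamVarPrio")),
    seed = config$seed,
    config_digest = .configDigest(config),
    stage_counts = list(
      n_families = length(cohort),
      n_input_variants = length(variants),
      n_retained = as.list(vapply(filt$retained, length, integer(1))),
      n_sharing_genes = nrow(sharing),
      n_enriched_terms = nrow(enrichment),
      n_segregation_calls = if (is.null(segregation)) 0L else nrow(segregation)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done: outputs in %s", config$out_dir)
  invisible(list(cohort = cohort, variants = variants, termSets = termSets,
                 retained = filt$retained, funnels = filt$funnels,
                 sharing = sharing, census = census, summary = summry,
                 enrichment = enrichment, segregation = segregation,
                 manifest = manifest, sim = sim))
}
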