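#' Pipeline configuration
#'
#' All thresholds default to the values the analysis is defined with:
#' binding frequency 0.10, cross-validation precision 0.50 (0.75 for
#' ions), pairwise similarity 80 percent, gaps 10 percent, minimum
#' orthogroup size 10, common-variant allele frequency 0.01, fold
#' enrichment 2, FDR 0.05. Overridden thresholds are recorded in the run
#' manifest.
#'
#' @param synthetic run on a freshly simulated study (default) instead
#'   of files
#' @param simConfig a \code{\link{simulationConfig}} for synthetic runs
#' @param msaDir,treeFile,profilesFile,matchesFile,variantsFile,goFile
#'   input paths for file-based runs
#' @param thresholds named list of analysis thresholds (partial
#'   overrides are merged over the defaults)
#' @param seed RNG seed for the run
#' @param outDir output directory, or NULL to skip writing
#' @return list of class \code{"ligevol_config"}
#' @export
pipelineConfig <- function(synthetic = TRUE, simConfig = NULL,
                           msaDir = NULL, treeFile = NULL,
                           profilesFile = NULL, matchesFile = NULL,
                           variantsFile = NULL, goFile = NULL,
                           thresholds = list(), seed = 1L,
                           outDir = NULL) {
  defaults <- list(binding_frequency = 0.10, precision = 0.50,
                   ion_precision = 0.75, similarity = 80, gaps = 10,
                   min_size = 10, maf = 0.01, fold = 2, fdr = 0.05)
  overridden <- intersect(names(thresholds), names(defaults))
  thr <- utils::modifyList(defaults, thresholds[overridden])
  if (synthetic && is.null(simConfig))
    simConfig <- simulationConfig(seed = seed)
  cfg <- list(synthetic = synthetic, simConfig = simConfig,
              msaDir = msaDir, treeFile = treeFile,
              profilesFile = profilesFile, matchesFile = matchesFile,
              variantsFile = variantsFile, goFile = goFile,
              thresholds = thr, overridden = overridden,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "ligevol_config"
  cfg
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

#' Run the full binding-site evolution pipeline
#'
#' Executes annotation, alignment QC, per-site metrics, the comparative
#' statistics battery, the lineage-specific fixed-site scans and the
#' variable-interface enrichment analysis in order, either on a
#' simulated study (\code{synthetic = TRUE}) or on user files. All
#' randomness derives from \code{config$seed}; identical configurations
#' produce identical results. When \code{config$outDir} is set, every
#' stage's table is written as TSV along with a JSON run manifest.
#'
#' @param config a \code{\link{pipelineConfig}}
#' @return list with components \code{annotations}, \code{qc},
#'   \code{retained}, \code{metrics} (pooled data.frame),
#'   \code{conservation}, \code{tests}, \code{ligandComparisons},
#'   \code{scans}, \code{enrichment}, \code{manifest} (and
#'   \code{study} for synthetic runs)
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "ligevol_config"))
  thr <- config$thresholds
  set.seed(config$seed)
  warningsSeen <- 0L
  countWarn <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      warningsSeen <<- warningsSeen + 1L
      invokeRestart("muffleWarning")
    })

  # ---- inputs -------------------------------------------------------------
  if (config$synthetic) {
    .stageLog("inputs", "simulating study (seed ", config$seed, ")")
    study <- simulateStudy(config$simConfig)
    phylogeny <- study$phylogeny
    orthogroups <- study$orthogroups
    profiles <- study$profiles; matches <- study$matches
    variants <- study$variants; go <- study$go
  } else {
    for (f in c(config$treeFile, config$profilesFile, config$matchesFile))
      if (!file.exists(f)) stop("input file not found: ", f)
    if (!dir.exists(config$msaDir))
      stop("MSA directory not found: ", config$msaDir)
    study <- NULL
    phylogeny <- loadReferenceTree(config$treeFile)
    files <- list.files(config$msaDir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    orthogroups <- lapply(files, readOrthogroup)
    names(orthogroups) <- vapply(orthogroups, orthogroupId, character(1))
    profiles <- readBindingProfiles(config$profilesFile)
    matches <- readDomainMatches(config$matchesFile)
    variants <- if (!is.null(config$variantsFile))
      readVariants(config$variantsFile) else
        data.frame(gene = character(), position = integer(),
                   allele_frequency = numeric(), disease_flag = logical())
    go <- if (!is.null(config$goFile)) readGoAnnotations(config$goFile)
          else data.frame(gene = character(), term_id = character())
  }
  model <- substitutionModel("JTT")

  # ---- annotation ---------------------------------------------------------
  .stageLog("annotate", length(orthogroups), " orthogroups")
  annotations <- lapply(orthogroups, annotateOrthogroup, matches, profiles,
                        frequencyCutoff = thr$binding_frequency,
                        precisionCutoff = thr$precision,
                        ionPrecisionCutoff = thr$ion_precision)

  # ---- QC -----------------------------------------------------------------
  .stageLog("qc", "pairwise similarity/gap and match-state checks")
  qcReports <- lapply(orthogroups, qcOrthogroup, matches,
                      minSimilarity = thr$similarity, maxGaps = thr$gaps,
                      minSize = thr$min_size)
  filtered <- mapply(filterOrthogroup, orthogroups, qcReports,
                     MoreArgs = list(minSize = thr$min_size),
                     SIMPLIFY = FALSE)
  retainedIds <- names(filtered)[vapply(filtered, `[[`, logical(1),
                                        "retained")]
  retained <- lapply(filtered[retainedIds], `[[`, "orthogroup")
  .stageLog("qc", length(retained), " of ", length(orthogroups),
            " orthogroups retained")

  # ---- per-site metrics ---------------------------------------------------
  .stageLog("rates", "entropy and ML evolutionary rates")
  metricsList <- lapply(retainedIds, function(id)
    countWarn(computeSiteMetrics(retained[[id]], phylogeny, model,
                                 annotations[[id]])))
  names(metricsList) <- retainedIds
  metrics <- do.call(rbind, lapply(metricsList, asMetricsFrame))
  if (!is.null(metrics)) {
    geneOf <- vapply(retained, humanGene, character(1))
    metrics$gene <- geneOf[metrics$orthogroup]
    rownames(metrics) <- NULL
  } else {
    metrics <- data.frame()
  }

  # ---- comparative statistics --------------------------------------------
  .stageLog("stats", "conservation table and test battery")
  conservation <- conservationTable(metrics)
  scored <- metrics[!is.na(metrics$variable) &
                      metrics$class %in% c("ligand_binding",
                                           "other_within_domain"), ,
                    drop = FALSE]
  isB <- scored$class == "ligand_binding"
  tests <- list()
  if (any(isB) && any(!isB)) {
    tests$fisher_binding_vs_within <- countWarn(conservationFisher(
      conservation, "ligand_binding", "other_sites_within_domains"))
    tests$fisher_binding_vs_other <- countWarn(conservationFisher(
      conservation, "ligand_binding", "other_sites"))
    tests$mwu_rate <- mannWhitneyU(scored$normalized_rate[isB],
                                   scored$normalized_rate[!isB])$p.value
    tests$mwu_entropy <- mannWhitneyU(scored$entropy[isB],
                                      scored$entropy[!isB])$p.value
  }
  lig <- metrics[!is.na(metrics$variable) &
                   metrics$class == "ligand_binding", , drop = FALSE]
  groups <- list()
  if (nrow(lig)) {
    ligSets <- strsplit(ifelse(is.na(lig$ligand_types), "",
                               as.character(lig$ligand_types)), ",")
    groups <- lapply(.LIGAND_TYPES, function(lt)
      lig$normalized_rate[vapply(ligSets, function(x) lt %in% x,
                                 logical(1))])
    names(groups) <- .LIGAND_TYPES
    groups <- groups[lengths(groups) > 1]
  }
  ligandComparisons <- NULL
  if (length(groups) >= 2) {
    kw <- kruskalWallis(groups)
    ligandComparisons <- list(kruskal = kw,
                              conover = conoverPosthoc(groups))
  }

  # ---- lineage-specific scans --------------------------------------------
  .stageLog("scan", "human- and great-ape-specific fixed sites")
  scanOne <- function(focal, mode, cladeName) {
    calls <- do.call(rbind, lapply(retainedIds, function(id)
      scanLineageSpecific(retained[[id]], annotations[[id]], focal,
                          mode = mode, cladeName = cladeName)))
    applyPopulationFilter(calls, variants, mafCutoff = thr$maf)
  }
  apes <- tryCatch(cladeSet(phylogeny, "great_apes"),
                   error = function(e) NULL)
  scans <- list(human_strict = scanOne("Homo_sapiens", "strict", "human"))
  if (!is.null(apes)) {
    scans$ape_strict <- scanOne(apes, "strict", "ape")
    scans$ape_relaxed <- scanOne(apes, "relaxed", "ape")
  }

  # ---- enrichment ---------------------------------------------------------
  .stageLog("enrich", "variable-interface genes and GO over-representation")
  backgroundGenes <- sort(unique(
    metrics$gene[metrics$class == "ligand_binding"]))
  varGenes <- variableInterfaceGenes(metrics, variants,
                                     mafCutoff = thr$maf)
  folds <- foldEnrichment(metrics, foldCutoff = thr$fold)
  goRes <- if (nrow(go) && length(varGenes))
    goOverrepresentation(varGenes, backgroundGenes, go,
                         fdrCutoff = thr$fdr) else NULL
  enrichment <- list(variable_genes = varGenes, folds = folds, go = goRes)

  # ---- manifest and outputs ----------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ligevol")),
    seed = config$seed, synthetic = config$synthetic,
    thresholds = thr, overridden_thresholds = config$overridden,
    n_orthogroups_in = length(orthogroups),
    n_orthogroups_retained = length(retained),
    n_columns_scored = nrow(metrics),
    n_binding_sites = sum(metrics$class == "ligand_binding",
                          na.rm = TRUE),
    n_variable_interface_genes = length(varGenes),
    n_fixed_site_calls = vapply(scans, nrow, integer(1)),
    warnings = warningsSeen)

  result <- list(annotations = annotations, qc = qcReports,
                 retained = retained, metrics = metrics,
                 conservation = conservation, tests = tests,
                 ligandComparisons = ligandComparisons, scans = scans,
                 enrichment = enrichment, manifest = manifest,
                 study = study)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- config$outDir
    if (config$synthetic) writeStudy(study, file.path(out, "inputs"))
    .writeTsv(metrics, file.path(out, "site_metrics.tsv"),
              "per-column conservation metrics")
    .writeTsv(conservation, file.path(out, "conservation_summary.tsv"),
              "conservation by site class")
    qcAll <- do.call(rbind, mapply(function(id, q)
      cbind(orthogroup = id, q), names(qcReports), qcReports,
      SIMPLIFY = FALSE))
    .writeTsv(qcAll, file.path(out, "qc_report.tsv"), "alignment QC")
    for (nm in names(scans))
      .writeTsv(scans[[nm]], file.path(out, paste0("scan_", nm, ".tsv")),
                paste("lineage-specific calls:", nm))
    .writeTsv(folds, file.path(out, "fold_enrichment.tsv"),
              "per-gene fold enrichment of variable binding sites")
    if (!is.null(goRes))
      .writeTsv(goRes, file.path(out, "go_enrichment.tsv"),
                "GO over-representation")
    if (!is.null(ligandComparisons))
      .writeTsv(ligandComparisons$conover,
                file.path(out, "ligand_pairwise.tsv"),
                "Conover-Iman pairwise ligand comparisons")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
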