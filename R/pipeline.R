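#' Run the full EET scan on one metagenome
#'
#' Chains the whole procedure: heme-motif scan, MHC classification,
#' homology search against the reference panel, signal-peptide prediction
#' and localization, PCC / outer-surface-MHC / Cyc2 calling, housekeeping
#' normalization, and the metagenome and MAG summaries.
#'
#' @param mg an [EETMetagenome-class].
#' @param params parameter list from [eetParams()].
#' @param refs reference panel from [eetReferences()].
#' @param hits optional precomputed hit table ([readHitsTable()]),
#'   replacing the built-in homology search verbatim.
#' @return list: `metagenome_id`, `scans`, `mhcCalls`, `hits`,
#'   `localizations`, `clusters`, `calls`, `abundance`,
#'   `metagenomeSummary`, `magSummary`, `params`.
#' @export
scanMetagenome <- function(mg, params = eetParams(), refs = eetReferences(),
                           hits = NULL) {
  stopifnot(is(mg, "EETMetagenome"))
  prot <- proteins(mg)
  ft <- geneFeatures(mg)
  mags <- magAssignment(mg)
  if (length(housekeepingGenes(mg)) == 0L)
    stop("metagenome '", metagenomeId(mg), "' has no housekeeping genes; ",
         "normalized abundance is undefined")

  scans <- scanHemeMotifs(prot, params$motifSpacers)
  mhcCalls <- classifyMHC(scans, mhcMin = params$mhcMin,
                          emphMin = params$emphMin,
                          binSplit = params$binSplit)
  if (is.null(hits))
    hits <- searchReferences(prot, refs,
                             minIdentity = params$minIdentity,
                             minCov = params$minCov,
                             gapOpening = params$gapOpening,
                             gapExtension = params$gapExtension)
  signal <- predictSignalPeptide(prot, hMin = params$hMin,
                                 nRegionLen = params$nRegionLen,
                                 minLength = params$signalMinLength)
  magOfGene <- setNames(unname(mags[ft$contig_id]), ft$gene_id)
  isMhc <- setNames(mhcCalls$is_mhc, mhcCalls$protein_id)
  loc <- assignLocalization(names(prot), signal,
                            annotation = mg@localization,
                            hits = hits, isMhc = isMhc, magOf = magOfGene,
                            monodermMags = mg@monodermMags)
  lens <- setNames(Biostrings::width(prot), names(prot))
  res <- callEETGenes(ft, mhcCalls, loc, hits, scans, lens, mags, params)
  ab <- normalizeAbundance(ft, contigCoverage(mg), housekeepingGenes(mg),
                           denominator = params$denominator)
  mgSummary <- summarizeMetagenome(res$calls, mhcCalls, ab, metagenomeId(mg))
  magSummary <- summarizeMags(res$calls, ab, mhcCalls, mags)
  list(metagenome_id = metagenomeId(mg),
       scans = scans, mhcCalls = mhcCalls, hits = hits,
       localizations = loc, clusters = res$clusters, calls = res$calls,
       abundance = ab, metagenomeSummary = mgSummary,
       magSummary = magSummary, params = params)
}

#' Read a pipeline run configuration from YAML
#'
#' Layout:
#' ```yaml
#' out_dir: results
#' params: {mhcMin: 5, maxGeneGap: 1}
#' metagenomes:
#'   - id: TH
#'     proteins: th/proteins.faa
#'     gff: th/genes.gff3
#'     coverage: th/coverage.tsv
#'     mags: th/mags.tsv             # optional
#'     housekeeping: th/housekeeping.tsv
#'     localization: th/localization.tsv   # optional
#' ```
#'
#' @param path YAML file.
#' @return validated config list for [runScanPipeline()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$metagenomes) || !length(cfg$metagenomes))
    stop("config lists no metagenomes")
  ids <- vapply(cfg$metagenomes, function(m) as.character(m$id), character(1))
  if (anyDuplicated(ids))
    stop("metagenome ids must be unique: ", paste(ids, collapse = ", "))
  for (m in cfg$metagenomes) {
    for (f in c("proteins", "gff", "coverage"))
      if (is.null(m[[f]]))
        stop("metagenome '", m$id, "' lacks required input '", f, "'")
    paths <- unlist(m[c("proteins", "gff", "coverage", "mags",
                        "housekeeping", "localization")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("metagenome '", m$id, "': input file(s) not found: ",
           paste(missing, collapse = ", "))
  }
  cfg
}

#' Orchestrate the scan over one or more metagenomes
#'
#' For each metagenome bundle: load inputs, run [scanMetagenome()], and
#' write the per-metagenome reports; finally emit a combined
#' cross-metagenome comparison table. Identical inputs and config yield
#' byte-identical reports.
#'
#' @param config either a config list ([readRunConfig()]) or a list of
#'   [EETMetagenome-class] objects.
#' @param outDir output directory; overrides `config$out_dir`. `NULL`
#'   skips report writing.
#' @param params parameter overrides as a named list (merged over
#'   [eetParams()] and any `config$params`).
#' @param refs reference panel.
#' @return list: `results` (per-metagenome [scanMetagenome()] outputs),
#'   `comparison` (combined metagenome summary `data.frame`).
#' @export
runScanPipeline <- function(config, outDir = NULL, params = list(),
                            refs = eetReferences()) {
  mgs <- list(); inputPaths <- list()
  if (is.list(config) && length(config) && is(config[[1]], "EETMetagenome")) {
    for (mg in config) mgs[[metagenomeId(mg)]] <- mg
    cfgParams <- list()
  } else {
    if (is.character(config)) config <- readRunConfig(config)
    cfgParams <- if (!is.null(config$params)) config$params else list()
    if (is.null(outDir)) outDir <- config$out_dir
    for (m in config$metagenomes) {
      mgs[[m$id]] <- loadMetagenome(
        m$id, m$proteins, m$gff, m$coverage,
        magPath = m$mags, housekeepingPath = m$housekeeping,
        localizationPath = m$localization,
        monodermMags = if (!is.null(m$monoderm_mags))
          as.character(m$monoderm_mags) else character())
      inputPaths[[m$id]] <- unlist(m[c("proteins", "gff", "coverage", "mags",
                                       "housekeeping", "localization")])
    }
  }
  p <- do.call(eetParams, modifyList(cfgParams, params))
  results <- list()
  comparison <- list()
  for (id in names(mgs)) {
    res <- tryCatch(scanMetagenome(mgs[[id]], params = p, refs = refs),
                    error = function(e) stop("metagenome '", id, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    results[[id]] <- res
    comparison[[id]] <- res$metagenomeSummary
    if (!is.null(outDir)) {
      writeReports(res$calls, res$magSummary, res$metagenomeSummary,
                   file.path(outDir, id),
                   knownContigs = unique(geneFeatures(mgs[[id]])$contig_id),
                   config = p,
                   inputPaths = if (length(inputPaths))
                     inputPaths[[id]] else character())
    }
  }
  comparison <- do.call(rbind, comparison)
  rownames(comparison) <- NULL
  if (!is.null(outDir))
    .writeTsv(comparison, file.path(outDir, "metagenome_summary.tsv"))
  list(results = results, comparison = comparison)
}
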