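#' Read predicted proteins from a FASTA file
#'
#' Sequences are uppercased, a trailing stop symbol (`*`) is stripped, and
#' the non-canonical letters `B`, `Z`, `U`, `J` are mapped to `X` so that
#' they can never satisfy a motif position. Protein ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a protein FASTA file.
#' @return a named [Biostrings::AAStringSet].
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("protein FASTA not found: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(aa) == 0L) return(aa)
  names(aa) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(aa)))
    stop("duplicate protein ids in '", path, "': ",
         paste(unique(names(aa)[duplicated(names(aa))]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*+$", "", seqs)
  seqs <- chartr("BZUJ", "XXXX", seqs)
  if (any(!nzchar(seqs)))
    stop("empty protein sequence(s) in '", path, "': ",
         paste(names(aa)[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad))
    stop("non-amino-acid characters in sequences: ",
         paste(names(aa)[bad], collapse = ", "))
  Biostrings::AAStringSet(setNames(seqs, names(aa)))
}

#' Read gene features from GFF3
#'
#' Imports `CDS`/`gene` features, requires an `ID` attribute, converts the
#' 1-based inclusive GFF3 coordinates to the internal 0-based half-open
#' convention, and assigns each gene its 0-based rank on its contig by
#' ascending start.
#'
#' @param path path to a GFF3 file.
#' @return `data.frame` with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
readGeneFeatures <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  empty <- data.frame(gene_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), rank = integer(),
                      stringsAsFactors = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("invalid GFF3 '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) return(empty)
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% c("CDS", "gene")]
  if (length(gr) == 0L) return(empty)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 feature(s) without an ID attribute in '", path, "'")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 strand must be '+' or '-' for all gene features")
  ft <- data.frame(
    gene_id   = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start     = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end       = GenomicRanges::end(gr),
    strand    = strand,
    stringsAsFactors = FALSE)
  if (anyDuplicated(ft$gene_id))
    stop("duplicate gene ids in '", path, "'")
  if (any(ft$start > ft$end)) stop("gene feature with start > end")
  ft$rank <- .assignRanks(ft)
  ft
}

#' Convert between internal and GFF3 coordinate conventions
#'
#' Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive.
#' The two functions are inverses of one another.
#'
#' @param start,end coordinate vectors in the source convention.
#' @return `data.frame(start, end)` in the target convention.
#' @export
internalToGff <- function(start, end) data.frame(start = start + 1L, end = end)

#' @rdname internalToGff
#' @export
gffToInternal <- function(start, end) data.frame(start = start - 1L, end = end)

.readTwoColTsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " table not found: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop(what, " table '", path, "' must have two columns")
  d
}

#' Read the per-contig coverage table
#'
#' Two-column TSV with a header: contig id and mean read depth.
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
readCoverageTable <- function(path) {
  d <- .readTwoColTsv(path, "coverage")
  cov <- suppressWarnings(as.numeric(d[[2L]]))
  if (anyNA(cov)) stop("non-numeric coverage values in '", path, "'")
  if (any(cov < 0)) stop("negative coverage values in '", path, "'")
  if (anyDuplicated(d[[1L]])) stop("duplicate contig ids in '", path, "'")
  setNames(cov, d[[1L]])
}

#' Read the contig-to-MAG membership table
#'
#' Two-column TSV with a header: contig id and MAG id. Contigs absent from
#' the table default to `"unbinned"` when the [EETMetagenome()] is built.
#'
#' @param path TSV path.
#' @return named character vector (contig id to MAG id).
#' @export
readMagTable <- function(path) {
  d <- .readTwoColTsv(path, "MAG")
  if (anyDuplicated(d[[1L]])) stop("duplicate contig ids in '", path, "'")
  setNames(as.character(d[[2L]]), d[[1L]])
}

#' Read the housekeeping-marker table
#'
#' Two-column TSV with a header: gene id and marker name (e.g. `gyrB`,
#' `recA`, ribosomal protein names). Only the gene ids are used for
#' normalization; marker names are kept for reporting.
#'
#' @param path TSV path.
#' @return character vector of gene ids, with marker names as names.
#' @export
readHousekeepingTable <- function(path) {
  d <- .readTwoColTsv(path, "housekeeping")
  setNames(as.character(d[[1L]]), as.character(d[[2L]]))
}

#' Read an external localization table
#'
#' Two-column TSV with a header: protein id and compartment label, one of
#' `cytoplasmic`, `periplasmic`, `outer_membrane`, `extracellular`,
#' `cell_wall`, `unknown`. These labels take precedence over the built-in
#' heuristic (see [assignLocalization()]).
#'
#' @param path TSV path.
#' @return `data.frame(protein_id, compartment)`.
#' @export
readLocalizationTable <- function(path) {
  d <- .readTwoColTsv(path, "localization")
  out <- data.frame(protein_id = as.character(d[[1L]]),
                    compartment = as.character(d[[2L]]),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$compartment), .COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment label(s) in '", path, "': ",
         paste(bad, collapse = ", "))
  out
}

#' Read a precomputed homology hit table
#'
#' Lets users substitute their own search stack (e.g. profile HMMs) for the
#' bundled pairwise-alignment search. Expected columns: `query_id`,
#' `family`, `identity`, `query_coverage`, `score`; a `role` column is added
#' from the built-in family-to-role map when absent.
#'
#' @param path TSV path.
#' @return hit `data.frame` compatible with [searchReferences()] output.
#' @export
readHitsTable <- function(path) {
  if (!file.exists(path)) stop("hits table not found: ", path)
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("query_id", "family", "identity", "query_coverage", "score")
  if (!all(need %in% names(d)))
    stop("hits table must have columns: ", paste(need, collapse = ", "))
  if (!"role" %in% names(d)) d$role <- familyRole(d$family)
  if (!"query_start" %in% names(d)) d$query_start <- NA_integer_
  if (!"query_end" %in% names(d)) d$query_end <- NA_integer_
  if (!"reference_coverage" %in% names(d)) d$reference_coverage <- NA_real_
  d
}

#' Load a metagenome input bundle from files
#'
#' @param metagenomeId identifier for the metagenome.
#' @param proteinFasta,gff,coveragePath paths to the protein FASTA, GFF3,
#'   and coverage TSV (all required).
#' @param magPath,housekeepingPath,localizationPath optional TSV paths.
#' @param monodermMags MAG ids flagged monoderm.
#' @return an [EETMetagenome-class] object.
#' @export
loadMetagenome <- function(metagenomeId, proteinFasta, gff, coveragePath,
                           magPath = NULL, housekeepingPath = NULL,
                           localizationPath = NULL,
                           monodermMags = character()) {
  prot <- readProteinFasta(proteinFasta)
  ft <- readGeneFeatures(gff)
  cov <- readCoverageTable(coveragePath)
  nocov <- setdiff(unique(ft$contig_id), names(cov))
  if (length(nocov))
    stop("contigs present in GFF3 but absent from the coverage table: ",
         paste(nocov, collapse = ", "))
  mags <- if (!is.null(magPath)) readMagTable(magPath) else NULL
  hk <- if (!is.null(housekeepingPath))
    unname(readHousekeepingTable(housekeepingPath)) else character()
  loc <- if (!is.null(localizationPath)) readLocalizationTable(localizationPath)
         else NULL
  EETMetagenome(metagenomeId, prot, ft, cov, mags = mags, housekeeping = hk,
                localization = loc, monodermMags = monodermMags)
}

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
}

#' Write the report tables for one pipeline run
#'
#' Emits `eet_calls.tsv` (gene-level calls), `mag_summary.tsv`,
#' `metagenome_summary.tsv`, and `run_metadata.yaml` recording the resolved
#' configuration, the seed, and md5 checksums of the input files. Re-running
#' on identical inputs produces byte-identical TSVs.
#'
#' @param calls gene-level call table from [callEETGenes()] /
#'   [scanMetagenome()].
#' @param magSummary MAG summary from [summarizeMags()].
#' @param metagenomeSummary metagenome summary from [summarizeMetagenome()].
#' @param outDir output directory (created if needed).
#' @param knownContigs optional character vector; calls referencing contigs
#'   outside it are a validation error.
#' @param config resolved parameter list to embed in the metadata file.
#' @param seed seed to record (may be `NA`).
#' @param inputPaths named character vector of input files to checksum.
#' @return invisibly, the paths written.
#' @export
writeReports <- function(calls, magSummary, metagenomeSummary, outDir,
                         knownContigs = NULL, config = list(), seed = NA,
                         inputPaths = character()) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  if (!is.null(knownContigs) && nrow(calls) > 0L) {
    bad <- setdiff(unique(calls$contig_id), knownContigs)
    if (length(bad))
      stop("calls reference unknown contig(s): ", paste(bad, collapse = ", "))
  }
  paths <- file.path(outDir, c("eet_calls.tsv", "mag_summary.tsv",
                               "metagenome_summary.tsv", "run_metadata.yaml"))
  .writeTsv(calls, paths[1L])
  .writeTsv(magSummary, paths[2L])
  .writeTsv(metagenomeSummary, paths[3L])
  sums <- if (length(inputPaths)) as.list(tools::md5sum(inputPaths)) else list()
  meta <- list(config = config,
               seed = if (is.na(seed)) "NA" else as.integer(seed),
               input_md5 = sums)
  writeLines(yaml::as.yaml(meta), paths[4L])
  invisible(paths)
}

#' Re-read a gene-level calls table written by [writeReports()]
#'
#' @param path path to `eet_calls.tsv`.
#' @return calls `data.frame`.
#' @export
readCallsTable <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(gene_id = "character", contig_id = "character",
                            mag_id = "character", call_class = "character",
                            cluster_id = "character",
                            cluster_type = "character",
                            family = "character", heme_count = "integer",
                            compartment = "character",
                            evidence = "character"))
}
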