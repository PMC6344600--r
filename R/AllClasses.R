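#' EETMetagenome: one metagenome's inputs for EET gene screening
#'
#' Container tying together the predicted proteome, gene coordinates, contig
#' read coverage, MAG membership, the housekeeping (single-copy marker) gene
#' set used for abundance normalization, and optional externally computed
#' subcellular-localization annotations.
#'
#' Gene coordinates are held 0-based half-open internally; all GFF3 I/O is
#' 1-based inclusive (see [readGeneFeatures()]). A gene inherits the mean
#' read coverage of its contig, reflecting read mapping against contigs
#' rather than genes. Contigs without a MAG assignment carry the reserved
#' label `"unbinned"`.
#'
#' @slot metagenomeId single identifier string.
#' @slot proteins [Biostrings::AAStringSet] of predicted proteins; names are
#'   protein ids, unique, sequences uppercase over the 20 canonical amino
#'   acids plus `X`.
#' @slot features `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `rank` (0-based ordinal
#'   of the gene on its contig by ascending start).
#' @slot coverage named numeric, contig id to mean read depth (>= 0).
#' @slot mags named character, contig id to MAG id (or `"unbinned"`).
#' @slot housekeeping character vector of gene ids flagged as single-copy
#'   conserved housekeeping markers.
#' @slot localization `data.frame` with columns `protein_id`, `compartment`
#'   (possibly empty) of externally supplied localization labels.
#' @slot monodermMags character vector of MAG ids flagged Gram-positive
#'   (monoderm); secreted MHCs in these MAGs localize to the cell wall.
#'
#' @seealso [EETMetagenome()], [loadMetagenome()], [scanMetagenome()]
#' @name EETMetagenome-class
#' @rdname EETMetagenome-class
#' @exportClass EETMetagenome
setClass("EETMetagenome",
  representation(
    metagenomeId = "character",
    proteins     = "AAStringSet",
    features     = "data.frame",
    coverage     = "numeric",
    mags         = "character",
    housekeeping = "character",
    localization = "data.frame",
    monodermMags = "character"
  )
)

.COMPARTMENTS <- c("cytoplasmic", "periplasmic", "outer_membrane",
                   "extracellular", "cell_wall", "unknown")

.validEETMetagenome <- function(object) {
  msg <- character()
  if (length(object@metagenomeId) != 1L || is.na(object@metagenomeId) ||
      !nzchar(object@metagenomeId))
    msg <- c(msg, "metagenomeId must be a single non-empty string")
  ids <- names(object@proteins)
  if (length(object@proteins) > 0L) {
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all proteins must be named")
    else if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate protein ids: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(Biostrings::width(object@proteins) == 0L))
      msg <- c(msg, "zero-length protein sequences are not allowed")
  }
  ft <- object@features
  need <- c("gene_id", "contig_id", "start", "end", "strand", "rank")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, sprintf("features must have columns: %s",
                          paste(need, collapse = ", ")))
  } else if (nrow(ft) > 0L) {
    if (anyDuplicated(ft$gene_id))
      msg <- c(msg, "duplicate gene ids in features")
    if (any(ft$start > ft$end))
      msg <- c(msg, "features with start > end")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
    missing_prot <- setdiff(ft$gene_id, ids)
    if (length(missing_prot))
      msg <- c(msg, sprintf("features reference proteins absent from the FASTA: %s",
        paste(head(missing_prot, 5L), collapse = ", ")))
    # rank must be a per-contig permutation consistent with start order
    ok <- vapply(split(ft, ft$contig_id), function(d) {
      identical(sort(d$rank), seq_len(nrow(d)) - 1L) &&
        !is.unsorted(d$start[order(d$rank)])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "per-contig ranks must be 0..n-1 ordered by ascending start")
    nocov <- setdiff(unique(ft$contig_id), names(object@coverage))
    if (length(nocov))
      msg <- c(msg, sprintf("contigs missing from the coverage table: %s",
        paste(head(nocov, 5L), collapse = ", ")))
  }
  if (length(object@coverage) && (anyNA(object@coverage) || any(object@coverage < 0)))
    msg <- c(msg, "coverage values must be non-negative")
  if (length(object@mags) && (is.null(names(object@mags)) || anyNA(object@mags)))
    msg <- c(msg, "mags must be a named character vector without NA")
  hk_missing <- setdiff(object@housekeeping, ft$gene_id)
  if (length(hk_missing))
    msg <- c(msg, sprintf("housekeeping gene ids absent from features: %s",
      paste(head(hk_missing, 5L), collapse = ", ")))
  loc <- object@localization
  if (!all(c("protein_id", "compartment") %in% names(loc))) {
    msg <- c(msg, "localization must have columns protein_id, compartment")
  } else if (nrow(loc) > 0L) {
    bad <- setdiff(unique(loc$compartment), .COMPARTMENTS)
    if (length(bad))
      msg <- c(msg, sprintf("unknown localization labels: %s",
        paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}

setValidity("EETMetagenome", .validEETMetagenome)

#' Construct an EETMetagenome
#'
#' @param metagenomeId identifier for this metagenome (e.g. `"TH"`).
#' @param proteins [Biostrings::AAStringSet] or named character vector of
#'   protein sequences.
#' @param features gene feature `data.frame` as returned by
#'   [readGeneFeatures()]; if the `rank` column is absent it is computed.
#' @param coverage named numeric vector of per-contig mean read depth.
#' @param mags named character vector, contig id to MAG id. Contigs present
#'   in `features` but absent here default to `"unbinned"`.
#' @param housekeeping character vector of housekeeping gene ids.
#' @param localization optional `data.frame(protein_id, compartment)` of
#'   externally computed localization labels.
#' @param monodermMags MAG ids flagged monoderm (Gram-positive).
#' @return a validated [EETMetagenome-class] object.
#' @examples
#' mg <- EETMetagenome("demo",
#'   proteins = c(g1 = "MKRLLAVLLAVFALMAGCAACHAACHAACHAACHAACHGG"),
#'   features = data.frame(gene_id = "g1", contig_id = "c1",
#'                         start = 0L, end = 120L, strand = "+"),
#'   coverage = c(c1 = 12))
#' mg
#' @export
EETMetagenome <- function(metagenomeId, proteins, features, coverage,
                          mags = NULL, housekeeping = character(),
                          localization = NULL,
                          monodermMags = character()) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"rank" %in% names(features) && nrow(features) > 0L)
    features$rank <- .assignRanks(features)
  if (!"rank" %in% names(features)) features$rank <- integer(0)
  contigs <- unique(features$contig_id)
  m <- setNames(rep("unbinned", length(contigs)), contigs)
  if (!is.null(mags) && length(mags)) {
    known <- intersect(names(mags), contigs)
    m[known] <- unname(mags[known])
  }
  if (is.null(localization))
    localization <- data.frame(protein_id = character(),
                               compartment = character(),
                               stringsAsFactors = FALSE)
  new("EETMetagenome",
      metagenomeId = as.character(metagenomeId),
      proteins     = proteins,
      features     = features,
      coverage     = coverage,
      mags         = m,
      housekeeping = as.character(housekeeping),
      localization = localization,
      monodermMags = as.character(monodermMags))
}

# rank genes 0-based per contig by ascending start (ties: end, then id)
.assignRanks <- function(features) {
  rank <- integer(nrow(features))
  for (ct in unique(features$contig_id)) {
    i <- which(features$contig_id == ct)
    o <- order(features$start[i], features$end[i], features$gene_id[i])
    rank[i[o]] <- seq_along(i) - 1L
  }
  rank
}

#' @describeIn EETMetagenome-class protein sequences as an `AAStringSet`.
#' @param x,object an `EETMetagenome`.
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname EETMetagenome-class
#' @export
setMethod("proteins", "EETMetagenome", function(x) x@proteins)

#' @describeIn EETMetagenome-class gene feature table (0-based half-open).
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname EETMetagenome-class
#' @export
setMethod("geneFeatures", "EETMetagenome", function(x) x@features)

#' @describeIn EETMetagenome-class named per-contig coverage vector.
#' @export
setGeneric("contigCoverage", function(x) standardGeneric("contigCoverage"))

#' @rdname EETMetagenome-class
#' @export
setMethod("contigCoverage", "EETMetagenome", function(x) x@coverage)

#' @describeIn EETMetagenome-class named contig-to-MAG assignment vector.
#' @export
setGeneric("magAssignment", function(x) standardGeneric("magAssignment"))

#' @rdname EETMetagenome-class
#' @export
setMethod("magAssignment", "EETMetagenome", function(x) x@mags)

#' @describeIn EETMetagenome-class housekeeping gene ids.
#' @export
setGeneric("housekeepingGenes", function(x) standardGeneric("housekeepingGenes"))

#' @rdname EETMetagenome-class
#' @export
setMethod("housekeepingGenes", "EETMetagenome", function(x) x@housekeeping)

#' @describeIn EETMetagenome-class metagenome identifier.
#' @export
setGeneric("metagenomeId", function(x) standardGeneric("metagenomeId"))

#' @rdname EETMetagenome-class
#' @export
setMethod("metagenomeId", "EETMetagenome", function(x) x@metagenomeId)

#' @rdname EETMetagenome-class
#' @export
setMethod("show", "EETMetagenome", function(object) {
  ft <- object@features
  cat("EETMetagenome '", object@metagenomeId, "'\n", sep = "")
  cat("  ", length(object@proteins), " proteins; ",
      nrow(ft), " gene features on ",
      length(unique(ft$contig_id)), " contigs\n", sep = "")
  mags <- setdiff(unique(object@mags), "unbinned")
  cat("  ", length(mags), " MAGs (+",
      sum(object@mags == "unbinned"), " unbinned contigs); ",
      length(object@housekeeping), " housekeeping genes\n", sep = "")
  if (nrow(object@localization))
    cat("  ", nrow(object@localization),
        " external localization annotations\n", sep = "")
  invisible(object)
})
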