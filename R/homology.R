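.FAMILY_ROLE <- c(
  MtrB = "porin", MtoB = "porin", PioB = "porin", OmbB = "porin",
  porin_other = "porin",
  MtrA = "periplasmic_MHC", MtoA = "periplasmic_MHC", PioA = "periplasmic_MHC",
  OmaB = "periplasmic_MHC",
  MtrC = "extracellular_MHC", OmcB = "extracellular_MHC",
  OmcE = "outer_surface_MHC", OmcS = "outer_surface_MHC",
  OmcZ = "outer_surface_MHC",
  Cyc2 = "cyc2")

# families whose hit marks a PCC cluster as known-family
.KNOWN_PCC_FAMILIES <- c("MtrA", "MtrB", "MtrC", "MtoA", "MtoB",
                         "PioA", "PioB", "OmaB", "OmbB", "OmcB")

.FAMILY_SYSTEM <- c(
  MtrA = "MtrABC", MtrB = "MtrABC", MtrC = "MtrABC",
  MtoA = "MtoAB", MtoB = "MtoAB",
  PioA = "PioAB", PioB = "PioAB",
  OmaB = "OmbB-OmaB-OmcB", OmbB = "OmbB-OmaB-OmcB", OmcB = "OmbB-OmaB-OmcB")

#' Map an EET protein family to its functional role
#'
#' Roles follow the described architecture of the characterized systems:
#' MtrB/MtoB/PioB/OmbB are the outer-membrane porins, MtrA/MtoA/PioA/OmaB
#' the periplasmic MHCs, MtrC/OmcB the extracellular/outer-membrane MHC
#' components, OmcE/OmcS/OmcZ outer-surface MHCs not part of a conduit, and
#' Cyc2 its own class.
#'
#' @param family character vector of family names.
#' @return character vector of roles (`NA` for unknown families).
#' @export
familyRole <- function(family) {
  unname(.FAMILY_ROLE[as.character(family)])
}

#' Load the bundled EET reference protein set
#'
#' The package ships a small synthetic reference panel (one entry per
#' family) constructed to mimic the length, heme-motif content, and
#' signal-peptide architecture of the characterized EET protein families;
#' see the `source_tag` column and the package vignette. Users reproducing
#' an analysis with curated reference sequences can supply their own FASTA
#' and sidecar TSV in the same layout, or bypass alignment entirely with a
#' precomputed hit table ([readHitsTable()]).
#'
#' @param fasta,meta optional paths overriding the bundled panel. The
#'   sidecar TSV must have columns `entry_id`, `family`, `role`, `hemes`,
#'   `source_tag`.
#' @return list with elements `seqs` (named `AAStringSet`) and `meta`
#'   (`data.frame`).
#' @export
eetReferences <- function(fasta = NULL, meta = NULL) {
  if (is.null(fasta))
    fasta <- system.file("extdata", "eet_references_synthetic.fasta",
                         package = "eetscan", mustWork = TRUE)
  if (is.null(meta))
    meta <- system.file("extdata", "eet_references_synthetic.tsv",
                        package = "eetscan", mustWork = TRUE)
  seqs <- readProteinFasta(fasta)
  info <- read.delim(meta, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("entry_id", "family", "role", "hemes", "source_tag")
  if (!all(need %in% names(info)))
    stop("reference sidecar must have columns: ", paste(need, collapse = ", "))
  if (!setequal(info$entry_id, names(seqs)))
    stop("reference FASTA ids and sidecar entry_id disagree")
  info <- info[match(names(seqs), info$entry_id), , drop = FALSE]
  rownames(info) <- NULL
  list(seqs = seqs, meta = info)
}

.alignStats <- function(pa, qlen, rlen) {
  alen <- Biostrings::nchar(pa)           # alignment length incl. gap columns
  nm <- Biostrings::nmatch(pa)
  qs <- BiocGenerics::start(Biostrings::pattern(pa))
  qe <- BiocGenerics::end(Biostrings::pattern(pa))
  rs <- BiocGenerics::start(Biostrings::subject(pa))
  re <- BiocGenerics::end(Biostrings::subject(pa))
  sc <- Biostrings::score(pa)
  emptyish <- alen == 0L | sc <= 0
  data.frame(
    score = pmax(sc, 0),
    identity = ifelse(emptyish, 0, nm / alen),
    query_coverage = ifelse(emptyish, 0, (qe - qs + 1L) / qlen),
    reference_coverage = ifelse(emptyish, 0, (re - rs + 1L) / rlen),
    query_start = ifelse(emptyish, NA_integer_, qs),
    query_end = ifelse(emptyish, NA_integer_, qe),
    stringsAsFactors = FALSE)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap penalties
#' (a gap of length L costs `gapOpening + L * gapExtension`; defaults 11 and
#' 1). Identity is the fraction of identical residues over alignment
#' columns (gap columns included); coverages are the aligned interval
#' length over each sequence's length. When no alignment scores above zero
#' the hit is empty with score 0.
#'
#' @param query,reference single protein sequences (character or
#'   `AAString`-coercible), non-empty.
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gapOpening,gapExtension affine gap parameters.
#' @return one-row `data.frame`: `score`, `identity`, `query_coverage`,
#'   `reference_coverage`, `query_start`, `query_end` (1-based, `NA` when
#'   empty), and the gapped traceback strings `query_aln`, `ref_aln`.
#' @export
localAlign <- function(query, reference, substitutionMatrix = "BLOSUM62",
                       gapOpening = 11, gapExtension = 1) {
  query <- as.character(query); reference <- as.character(reference)
  if (length(query) != 1L || length(reference) != 1L)
    stop("localAlign aligns one pair; use searchReferences() for sets")
  if (!nzchar(query) || !nzchar(reference))
    stop("cannot align empty sequences")
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "local",
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  st <- .alignStats(pa, nchar(query), nchar(reference))
  st$query_aln <- if (st$score > 0) as.character(Biostrings::pattern(pa))
                  else ""
  st$ref_aln <- if (st$score > 0) as.character(Biostrings::subject(pa))
                else ""
  st
}

#' Search proteins against the EET reference panel
#'
#' Aligns every query against every reference entry, discards hits below
#' the identity and query-coverage thresholds, and keeps the best-scoring
#' hit per query and role. The thresholds (30% identity, 50% query
#' coverage) are package defaults, reported with every run.
#'
#' @param proteins named character vector or `AAStringSet` of queries.
#' @param refs reference panel from [eetReferences()].
#' @param minIdentity,minCov filtering thresholds.
#' @param substitutionMatrix,gapOpening,gapExtension see [localAlign()].
#' @return `data.frame` with columns `query_id`, `family`, `role`, `score`,
#'   `identity`, `query_coverage`, `reference_coverage`, `query_start`,
#'   `query_end`; zero rows when nothing passes.
#' @export
searchReferences <- function(proteins, refs = eetReferences(),
                             minIdentity = 0.30, minCov = 0.50,
                             substitutionMatrix = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  if (inherits(proteins, "AAStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  out <- list()
  if (length(proteins)) {
    qlen <- nchar(proteins)
    for (i in seq_along(refs$seqs)) {
      rs <- as.character(refs$seqs[[i]])
      pa <- Biostrings::pairwiseAlignment(
        pattern = unname(proteins), subject = rs, type = "local",
        substitutionMatrix = substitutionMatrix,
        gapOpening = gapOpening, gapExtension = gapExtension)
      st <- .alignStats(pa, qlen, nchar(rs))
      st$query_id <- names(proteins)
      st$family <- refs$meta$family[i]
      st$role <- refs$meta$role[i]
      keep <- st$identity >= minIdentity & st$query_coverage >= minCov
      if (any(keep)) out[[length(out) + 1L]] <- st[keep, , drop = FALSE]
    }
  }
  cols <- c("query_id", "family", "role", "score", "identity",
            "query_coverage", "reference_coverage", "query_start", "query_end")
  if (!length(out)) {
    hits <- data.frame(query_id = character(), family = character(),
                       role = character(), score = numeric(),
                       identity = numeric(), query_coverage = numeric(),
                       reference_coverage = numeric(),
                       query_start = integer(), query_end = integer(),
                       stringsAsFactors = FALSE)
    return(hits)
  }
  hits <- do.call(rbind, out)[, cols]
  # best hit per (query, role) by score; deterministic tie-break on family
  o <- order(hits$query_id, hits$role, -hits$score, hits$family)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query_id", "role")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
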