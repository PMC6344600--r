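#' Heuristic signal-peptide prediction
#'
#' A transparent, deterministic stand-in for model-based signal-peptide
#' predictors, for self-contained runs: a protein is flagged when, within
#' its first `nRegionLen` residues, a run of at least `hMin` consecutive
#' hydrophobic residues (`A F I L M V W`) begins after at least one basic
#' residue (`K`/`R`) — i.e. a basic n-region followed by a hydrophobic
#' h-region. Proteins shorter than `minLength` residues are never flagged.
#' Users with a real predictor should supply its labels through the
#' localization table instead (see [assignLocalization()]).
#'
#' @param x named character vector or `AAStringSet`.
#' @param hMin minimum hydrophobic run length (default 7).
#' @param nRegionLen window from the N terminus searched (default 45).
#' @param minLength minimum protein length to consider (default 30).
#' @return named logical vector.
#' @export
predictSignalPeptide <- function(x, hMin = 7L, nRegionLen = 45L,
                                 minLength = 30L) {
  if (inherits(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  pre <- substr(x, 1L, nRegionLen)
  pat <- sprintf("[AFILMVW]{%d,}", hMin)
  flag <- vapply(pre, function(s) {
    m <- regexpr(pat, s)
    if (m == -1L) return(FALSE)
    grepl("[KR]", substr(s, 1L, as.integer(m) - 1L))
  }, logical(1), USE.NAMES = FALSE)
  flag[nchar(x) < minLength] <- FALSE
  setNames(flag, names(x))
}

#' Assign subcellular localization
#'
#' Resolves one compartment per protein with a strict precedence:
#' user-supplied annotation > homology-implied role (a porin or
#' outer-surface family hit implies `outer_membrane`, an
#' extracellular-MHC family hit implies `extracellular`, a Cyc2 hit implies
#' `outer_membrane`) > heuristic (signal peptide implies `periplasmic`,
#' otherwise `cytoplasmic`). For proteins in MAGs flagged monoderm
#' (Gram-positive), a secreted MHC resolved by homology or heuristic is
#' re-mapped to `cell_wall`, since these cells have no outer membrane. The
#' `evidence` column records which branch fired.
#'
#' @param proteinIds character vector of protein ids to localize.
#' @param signal named logical from [predictSignalPeptide()].
#' @param annotation optional `data.frame(protein_id, compartment)` of
#'   external labels (highest precedence). Unknown labels are an error.
#' @param hits optional hit table from [searchReferences()].
#' @param isMhc optional named logical (protein id to MHC status), used for
#'   the monoderm cell-wall rule.
#' @param magOf optional named character, protein id to MAG id.
#' @param monodermMags MAG ids flagged monoderm.
#' @return `data.frame`: `protein_id`, `compartment`,
#'   `has_signal_peptide`, `evidence` (`annotation`, `homology`, or
#'   `heuristic`).
#' @export
assignLocalization <- function(proteinIds, signal, annotation = NULL,
                               hits = NULL, isMhc = NULL, magOf = NULL,
                               monodermMags = character()) {
  n <- length(proteinIds)
  comp <- rep(NA_character_, n)
  evid <- rep(NA_character_, n)
  sig <- unname(signal[proteinIds])
  sig[is.na(sig)] <- FALSE

  if (!is.null(annotation) && nrow(annotation)) {
    bad <- setdiff(unique(annotation$compartment), .COMPARTMENTS)
    if (length(bad))
      stop("contradictory/unknown localization label(s): ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(annotation$protein_id)) {
      dup <- annotation[duplicated(annotation$protein_id) |
                        duplicated(annotation$protein_id, fromLast = TRUE), ]
      if (any(tapply(dup$compartment, dup$protein_id,
                     function(z) length(unique(z))) > 1L))
        stop("contradictory localization annotations for: ",
             paste(unique(dup$protein_id), collapse = ", "))
      annotation <- annotation[!duplicated(annotation$protein_id), ]
    }
    i <- match(proteinIds, annotation$protein_id)
    hasAnn <- !is.na(i)
    comp[hasAnn] <- annotation$compartment[i[hasAnn]]
    evid[hasAnn] <- "annotation"
  }

  if (!is.null(hits) && nrow(hits)) {
    roleComp <- c(porin = "outer_membrane",
                  outer_surface_MHC = "outer_membrane",
                  extracellular_MHC = "extracellular",
                  cyc2 = "outer_membrane")
    h <- hits[hits$role %in% names(roleComp), , drop = FALSE]
    if (nrow(h)) {
      # strongest role hit per query decides
      h <- h[order(h$query_id, -h$score), , drop = FALSE]
      h <- h[!duplicated(h$query_id), , drop = FALSE]
      i <- match(proteinIds, h$query_id)
      use <- !is.na(i) & is.na(comp)
      comp[use] <- unname(roleComp[h$role[i[use]]])
      evid[use] <- "homology"
    }
  }

  left <- is.na(comp)
  comp[left] <- ifelse(sig[left], "periplasmic", "cytoplasmic")
  evid[left] <- "heuristic"

  if (length(monodermMags) && !is.null(magOf)) {
    mhc <- if (is.null(isMhc)) rep(FALSE, n) else {
      v <- unname(isMhc[proteinIds]); v[is.na(v)] <- FALSE; v
    }
    mono <- unname(magOf[proteinIds]) %in% monodermMags
    remap <- mono & mhc & evid != "annotation" &
      comp %in% c("periplasmic", "outer_membrane", "extracellular")
    comp[remap] <- "cell_wall"
  }

  data.frame(protein_id = proteinIds, compartment = comp,
             has_signal_peptide = sig, evidence = evid,
             stringsAsFactors = FALSE, row.names = NULL)
}
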