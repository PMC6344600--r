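#' Default parameters for the EET scan
#'
#' One flat list of every tunable threshold, so each run can embed the
#' resolved configuration in its reports.
#'
#' @param ... overrides for any default (unknown names are an error).
#' @return named list of parameters.
#' @export
eetParams <- function(...) {
  p <- list(
    motifSpacers = 2L,       # CXXCH only; add 3:4 for CX3CH/CX4CH variants
    mhcMin = 5L,
    emphMin = 8L,
    binSplit = 10L,
    minIdentity = 0.30,
    minCov = 0.50,
    gapOpening = 11,
    gapExtension = 1,
    hMin = 7L,
    nRegionLen = 45L,
    signalMinLength = 30L,
    maxGeneGap = 1L,
    pccMhcMin = 5L,
    strandRequired = FALSE,
    nTermWindow = 60L,
    ctermCov = 0.40,
    cyc2LenMin = 150L,
    cyc2LenMax = 800L,
    denominator = "mean")    # or "median"
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  modifyList(p, dots)
}

#' Detect porin-cytochrome conduit (PCC) gene clusters
#'
#' Scans each contig's gene order for a porin-coding gene (porin-family
#' hit) within `maxGeneGap` intervening genes of a periplasmic-MHC
#' candidate (an MHC with at least `pccMhcMin` hemes carrying a signal
#' peptide). Clusters whose members hit the characterized MtrABC / MtoAB /
#' PioAB / OmbB-OmaB-OmcB families are typed `known_family`; clusters found
#' by gene organization alone are `novel_organization`, the signature used
#' to surface PCC systems with no sequence homology to known ones. An
#' extracellular-MHC-family gene inside the same window joins its cluster.
#' Each gene joins at most one cluster; assembly is greedy leftmost with
#' ties broken by smaller start coordinate.
#'
#' @param features gene feature table ([readGeneFeatures()]).
#' @param mhcCalls output of [classifyMHC()].
#' @param localizations output of [assignLocalization()] (supplies the
#'   signal-peptide flags).
#' @param hits hit table from [searchReferences()] / [readHitsTable()].
#' @param maxGeneGap maximum intervening genes between porin and MHC
#'   (default 1).
#' @param pccMhcMin minimum heme count of the periplasmic member
#'   (default 5).
#' @param strandRequired require porin and MHC on the same strand
#'   (default `FALSE`).
#' @return `data.frame`, one row per cluster: `cluster_id`, `contig_id`,
#'   `porin_gene`, `peri_mhc_gene`, `peri_heme_count`, `extra_mhc_gene`,
#'   `cluster_type`, `family`, `porin_rank`, `peri_rank`, `intergenic_bp`.
#' @export
detectPCCClusters <- function(features, mhcCalls, localizations, hits,
                              maxGeneGap = 1L, pccMhcMin = 5L,
                              strandRequired = FALSE) {
  empty <- data.frame(cluster_id = character(), contig_id = character(),
                      porin_gene = character(), peri_mhc_gene = character(),
                      peri_heme_count = integer(),
                      extra_mhc_gene = character(),
                      cluster_type = character(), family = character(),
                      porin_rank = integer(), peri_rank = integer(),
                      intergenic_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(features) == 0L) return(empty)

  hc <- setNames(mhcCalls$heme_count, mhcCalls$protein_id)
  sig <- setNames(localizations$has_signal_peptide, localizations$protein_id)
  roleOf <- function(role) unique(hits$query_id[hits$role == role])
  famOf <- function(gene) hits$family[hits$query_id == gene]

  porinGenes <- roleOf("porin")
  extraGenes <- roleOf("extracellular_MHC")
  g <- features
  g$is_porin <- g$gene_id %in% porinGenes
  g$heme <- unname(hc[g$gene_id]); g$heme[is.na(g$heme)] <- 0L
  g$sig <- unname(sig[g$gene_id]); g$sig[is.na(g$sig)] <- FALSE
  g$is_peri <- !g$is_porin & g$heme >= pccMhcMin & g$sig
  g$is_extra <- g$gene_id %in% extraGenes & g$heme >= pccMhcMin

  maxDelta <- maxGeneGap + 1L
  used <- character(0)
  rows <- list()
  for (ct in sort(unique(g$contig_id))) {
    d <- g[g$contig_id == ct, , drop = FALSE]
    d <- d[order(d$rank), , drop = FALSE]
    porins <- d[d$is_porin, , drop = FALSE]
    for (pi in seq_len(nrow(porins))) {
      p <- porins[pi, ]
      if (p$gene_id %in% used) next
      cand <- d[d$is_peri & !(d$gene_id %in% used) &
                abs(d$rank - p$rank) <= maxDelta, , drop = FALSE]
      if (strandRequired) cand <- cand[cand$strand == p$strand, , drop = FALSE]
      if (!nrow(cand)) next
      cand <- cand[order(abs(cand$rank - p$rank), cand$start), , drop = FALSE]
      m <- cand[1L, ]
      ex <- d[d$is_extra & !(d$gene_id %in% c(used, p$gene_id, m$gene_id)) &
              (abs(d$rank - p$rank) <= maxDelta |
               abs(d$rank - m$rank) <= maxDelta), , drop = FALSE]
      exGene <- if (nrow(ex)) {
        ex <- ex[order(pmin(abs(ex$rank - p$rank), abs(ex$rank - m$rank)),
                       ex$start), , drop = FALSE]
        ex$gene_id[1L]
      } else NA_character_
      members <- c(p$gene_id, m$gene_id, exGene)
      members <- members[!is.na(members)]
      fams <- unique(unlist(lapply(members, famOf)))
      knownFams <- intersect(fams, .KNOWN_PCC_FAMILIES)
      known <- length(knownFams) > 0L
      family <- if (known)
        paste(sort(unique(unname(.FAMILY_SYSTEM[knownFams]))), collapse = ";")
      else NA_character_
      lo <- if (p$start <= m$start) p else m
      hi <- if (p$start <= m$start) m else p
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = sprintf("pcc_%s_%02d", ct,
                             sum(vapply(rows, function(r)
                               r$contig_id == ct, logical(1))) + 1L),
        contig_id = ct,
        porin_gene = p$gene_id,
        peri_mhc_gene = m$gene_id,
        peri_heme_count = as.integer(m$heme),
        extra_mhc_gene = exGene,
        cluster_type = if (known) "known_family" else "novel_organization",
        family = family,
        porin_rank = p$rank,
        peri_rank = m$rank,
        intergenic_bp = as.integer(max(0L, hi$start - lo$end)),
        stringsAsFactors = FALSE)
      used <- c(used, members)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.clusterMembers <- function(clusters) {
  if (nrow(clusters) == 0L) return(character(0))
  m <- c(clusters$porin_gene, clusters$peri_mhc_gene, clusters$extra_mhc_gene)
  m[!is.na(m)]
}

#' Call outer-surface MHCs not associated with a PCC
#'
#' Every MHC located on the outer membrane, extracellular space, or cell
#' wall that is not a member of any PCC cluster is reported as a putative
#' outer-surface EET MHC.
#'
#' @param mhcCalls output of [classifyMHC()].
#' @param localizations output of [assignLocalization()].
#' @param clusters output of [detectPCCClusters()].
#' @return character vector of called gene ids.
#' @export
callOuterSurfaceMHCs <- function(mhcCalls, localizations, clusters) {
  surface <- c("outer_membrane", "extracellular", "cell_wall")
  comp <- setNames(localizations$compartment, localizations$protein_id)
  inCluster <- .clusterMembers(clusters)
  ids <- mhcCalls$protein_id[mhcCalls$is_mhc]
  ids <- ids[unname(comp[ids]) %in% surface]
  sort(setdiff(ids, inCluster))
}

#' Call Cyc2-like genes
#'
#' A protein is called Cyc2-like when it carries exactly one heme-binding
#' motif, located within the first `nTermWindow` residues; has a
#' Cyc2-family hit whose aligned query interval covers at least `ctermCov`
#' of the protein's C-terminal half (the operational proxy for the
#' predicted C-terminal porin structure); and has a length within
#' `[lenMin, lenMax]`.
#'
#' @param scans output of [scanHemeMotifs()].
#' @param hits hit table with `role == "cyc2"` rows carrying
#'   `query_start`/`query_end`.
#' @param lengths named integer vector of protein lengths.
#' @param nTermWindow N-terminal window for the single motif (default 60).
#' @param ctermCov required coverage of the C-terminal half (default 0.40).
#' @param lenMin,lenMax admissible protein length range (default 150-800).
#' @return character vector of called gene ids.
#' @export
callCyc2 <- function(scans, hits, lengths, nTermWindow = 60L,
                     ctermCov = 0.40, lenMin = 150L, lenMax = 800L) {
  ch <- hits[hits$role == "cyc2", , drop = FALSE]
  if (nrow(ch) == 0L) return(character(0))
  called <- character(0)
  pos <- setNames(scans$positions, scans$protein_id)
  for (i in seq_len(nrow(ch))) {
    id <- ch$query_id[i]
    L <- unname(lengths[id])
    if (is.na(L) || L < lenMin || L > lenMax) next
    p <- pos[[id]]
    if (is.null(p) || length(p) != 1L) next          # exactly one motif
    if (p > nTermWindow - 1L) next                   # 0-based start in window
    qs <- ch$query_start[i]; qe <- ch$query_end[i]
    if (is.na(qs) || is.na(qe)) next
    chalf <- floor(L / 2) + 1L                       # C-terminal half begins here
    ov <- max(0L, min(qe, L) - max(qs, chalf) + 1L)
    if (ov / (L - chalf + 1L) < ctermCov) next
    called <- c(called, id)
  }
  sort(unique(called))
}

#' Combine all evidence into the unified EET gene call table
#'
#' Runs the three callers and assembles one row per called gene with the
#' partition guarantee that a gene carries exactly one call class:
#' `pcc_component` takes precedence over `outer_surface_mhc`, which takes
#' precedence over `cyc2`.
#'
#' @param features gene feature table.
#' @param mhcCalls,localizations,hits,scans upstream evidence tables.
#' @param lengths named integer vector of protein lengths.
#' @param mags named contig-to-MAG vector.
#' @param params parameter list from [eetParams()].
#' @return list with elements `calls` (the gene-level table: `gene_id`,
#'   `contig_id`, `mag_id`, `call_class`, `cluster_id`, `cluster_type`,
#'   `family`, `heme_count`, `compartment`, `evidence`) and `clusters`
#'   (the [detectPCCClusters()] table).
#' @export
callEETGenes <- function(features, mhcCalls, localizations, hits, scans,
                         lengths, mags, params = eetParams()) {
  clusters <- detectPCCClusters(features, mhcCalls, localizations, hits,
                                maxGeneGap = params$maxGeneGap,
                                pccMhcMin = params$pccMhcMin,
                                strandRequired = params$strandRequired)
  osm <- callOuterSurfaceMHCs(mhcCalls, localizations, clusters)
  cyc2 <- callCyc2(scans, hits, lengths,
                   nTermWindow = params$nTermWindow,
                   ctermCov = params$ctermCov,
                   lenMin = params$cyc2LenMin, lenMax = params$cyc2LenMax)

  memb <- .clusterMembers(clusters)
  osm <- setdiff(osm, memb)
  cyc2 <- setdiff(cyc2, c(memb, osm))

  hcOf <- setNames(mhcCalls$heme_count, mhcCalls$protein_id)
  compOf <- setNames(localizations$compartment, localizations$protein_id)
  ftIdx <- match(c(memb, osm, cyc2), features$gene_id)
  ids <- c(memb, osm, cyc2)
  cls <- c(rep("pcc_component", length(memb)),
           rep("outer_surface_mhc", length(osm)),
           rep("cyc2", length(cyc2)))

  clOf <- character(0); ctOf <- character(0); famOf <- character(0)
  if (nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      mm <- c(clusters$porin_gene[i], clusters$peri_mhc_gene[i],
              clusters$extra_mhc_gene[i])
      mm <- mm[!is.na(mm)]
      clOf[mm] <- clusters$cluster_id[i]
      ctOf[mm] <- clusters$cluster_type[i]
      famOf[mm] <- clusters$family[i]
    }
  }
  famHit <- vapply(ids, function(g) {
    f <- sort(unique(hits$family[hits$query_id == g]))
    if (length(f)) paste(f, collapse = ";") else NA_character_
  }, character(1))
  family <- ifelse(cls == "pcc_component", unname(famOf[ids]), famHit)
  evidence <- vapply(seq_along(ids), function(i) {
    parts <- c(
      if (!is.na(famHit[i])) paste0("hits:", famHit[i]),
      if (cls[i] == "pcc_component") paste0("cluster:", clOf[[ids[i]]]),
      paste0("compartment:", compOf[ids[i]]))
    paste(parts, collapse = "|")
  }, character(1))

  calls <- data.frame(
    gene_id = ids,
    contig_id = features$contig_id[ftIdx],
    mag_id = unname(mags[features$contig_id[ftIdx]]),
    call_class = cls,
    cluster_id = ifelse(cls == "pcc_component", unname(clOf[ids]),
                        NA_character_),
    cluster_type = ifelse(cls == "pcc_component", unname(ctOf[ids]),
                          NA_character_),
    family = family,
    heme_count = {h <- unname(hcOf[ids]); h[is.na(h)] <- 0L; as.integer(h)},
    compartment = unname(compOf[ids]),
    evidence = evidence,
    stringsAsFactors = FALSE, row.names = NULL)
  calls$mag_id[is.na(calls$mag_id)] <- "unbinned"
  calls <- calls[order(calls$contig_id, calls$gene_id), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, clusters = clusters)
}
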