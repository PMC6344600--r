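#' Housekeeping-normalized gene abundance
#'
#' Each gene inherits its contig's mean read coverage; the normalized
#' abundance is that coverage divided by the average coverage of the
#' single-copy conserved housekeeping genes of the same metagenome. Values
#' are dimensionless and invariant under global rescaling of all coverages.
#'
#' @param features gene feature table.
#' @param coverage named per-contig coverage vector.
#' @param housekeeping character vector of housekeeping gene ids
#'   (non-empty; all must be present in `features`).
#' @param denominator `"mean"` (default) or `"median"` of the housekeeping
#'   coverages.
#' @param geneCoverage optional named per-gene coverage vector overriding
#'   contig inheritance for the named genes.
#' @return `data.frame`: `gene_id`, `contig_id`, `coverage`,
#'   `denominator`, `normalized`.
#' @export
normalizeAbundance <- function(features, coverage, housekeeping,
                               denominator = c("mean", "median"),
                               geneCoverage = NULL) {
  denominator <- match.arg(denominator)
  if (length(housekeeping) == 0L)
    stop("housekeeping gene set is empty; normalization is undefined")
  missing_hk <- setdiff(housekeeping, features$gene_id)
  if (length(missing_hk))
    stop("housekeeping genes absent from features: ",
         paste(missing_hk, collapse = ", "))
  geneCov <- unname(coverage[features$contig_id])
  if (!is.null(geneCoverage)) {
    i <- match(features$gene_id, names(geneCoverage))
    geneCov[!is.na(i)] <- unname(geneCoverage[i[!is.na(i)]])
  }
  if (anyNA(geneCov))
    stop("coverage missing for contigs: ",
         paste(unique(features$contig_id[is.na(geneCov)]), collapse = ", "))
  hkCov <- geneCov[match(housekeeping, features$gene_id)]
  den <- if (denominator == "mean") mean(hkCov) else median(hkCov)
  if (!is.finite(den) || den <= 0)
    stop("housekeeping coverage denominator is not positive (", den, ")")
  data.frame(gene_id = features$gene_id,
             contig_id = features$contig_id,
             coverage = geneCov,
             denominator = den,
             normalized = geneCov / den,
             stringsAsFactors = FALSE, row.names = NULL)
}

# the pair of bin labels in use (falling back to the defaults)
.binLabels <- function(bins) {
  labs <- unique(bins[!is.na(bins)])
  low <- labs[!startsWith(labs, ">")]
  high <- labs[startsWith(labs, ">")]
  c(if (length(low)) low[1L] else "5-10",
    if (length(high)) high[1L] else ">10")
}

.eetMhcGenes <- function(calls, mhcCalls) {
  isMhc <- setNames(mhcCalls$is_mhc, mhcCalls$protein_id)
  pcc <- calls$gene_id[calls$call_class == "pcc_component"]
  pccMhc <- pcc[unname(isMhc[pcc]) %in% TRUE]   # porin members excluded
  c(pccMhc, calls$gene_id[calls$call_class == "outer_surface_mhc"])
}

#' Metagenome-level abundance summary
#'
#' Aggregates normalized abundances into the three reporting panels: all
#' MHCs by heme bin, putative EET MHCs (MHC members of PCC clusters plus
#' outer-surface MHCs) by heme bin, and Cyc2-like genes. Panel values are
#' sums of member genes' normalized abundances, so that metagenome totals
#' equal the sum over MAG rows.
#'
#' @param calls gene-level call table from [callEETGenes()].
#' @param mhcCalls output of [classifyMHC()].
#' @param abundance output of [normalizeAbundance()].
#' @param metagenomeId identifier for the summary row.
#' @return one-row `data.frame`: `metagenome_id`, `mhc_5_10`, `mhc_gt10`,
#'   `eet_mhc_5_10`, `eet_mhc_gt10`, `cyc2_total`, `n_mhc`,
#'   `n_pcc_component`, `n_outer_surface_mhc`, `n_cyc2`.
#' @export
summarizeMetagenome <- function(calls, mhcCalls, abundance, metagenomeId) {
  ab <- setNames(abundance$normalized, abundance$gene_id)
  bins <- setNames(mhcCalls$bin, mhcCalls$protein_id)
  labs <- .binLabels(bins)
  lowLab <- labs[1L]; highLab <- labs[2L]
  sumOf <- function(ids, lab) {
    ids <- ids[!is.na(bins[ids]) & bins[ids] == lab]
    if (!length(ids)) 0 else sum(ab[ids])
  }
  allMhc <- mhcCalls$protein_id[mhcCalls$is_mhc]
  allMhc <- intersect(allMhc, abundance$gene_id)
  eetMhc <- intersect(.eetMhcGenes(calls, mhcCalls), abundance$gene_id)
  cyc2 <- intersect(calls$gene_id[calls$call_class == "cyc2"],
                    abundance$gene_id)
  data.frame(
    metagenome_id = metagenomeId,
    mhc_5_10 = sumOf(allMhc, lowLab),
    mhc_gt10 = sumOf(allMhc, highLab),
    eet_mhc_5_10 = sumOf(eetMhc, lowLab),
    eet_mhc_gt10 = sumOf(eetMhc, highLab),
    cyc2_total = if (length(cyc2)) sum(ab[cyc2]) else 0,
    n_mhc = length(allMhc),
    n_pcc_component = sum(calls$call_class == "pcc_component"),
    n_outer_surface_mhc = sum(calls$call_class == "outer_surface_mhc"),
    n_cyc2 = length(cyc2),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-MAG EET summary
#'
#' One row per MAG carrying at least one EET gene call, plus an
#' `"unbinned"` row (always present, zero when empty). Reports the count
#' of EET genes, their mean normalized abundance (the per-MAG statistic
#' used for occurrence reporting), per-class presence flags, and per-class
#' abundance sums supporting MAG-additivity checks against the metagenome
#' summary.
#'
#' @param calls gene-level call table.
#' @param abundance output of [normalizeAbundance()].
#' @param mhcCalls output of [classifyMHC()].
#' @param mags named contig-to-MAG vector.
#' @return `data.frame`, one row per MAG: `mag_id`, `n_eet_genes`,
#'   `mean_normalized`, `sum_normalized`, presence flags
#'   (`has_pcc_known`, `has_pcc_novel`, `has_outer_surface_mhc`,
#'   `has_cyc2`), and class sums (`sum_eet_mhc_5_10`, `sum_eet_mhc_gt10`,
#'   `sum_cyc2`).
#' @export
summarizeMags <- function(calls, abundance, mhcCalls, mags) {
  ab <- setNames(abundance$normalized, abundance$gene_id)
  bins <- setNames(mhcCalls$bin, mhcCalls$protein_id)
  eetMhc <- .eetMhcGenes(calls, mhcCalls)
  labs <- .binLabels(bins)
  lowLab <- labs[1L]; highLab <- labs[2L]
  magIds <- unique(c(calls$mag_id, "unbinned"))
  magIds <- c(sort(setdiff(magIds, "unbinned")), "unbinned")
  rows <- lapply(magIds, function(m) {
    d <- calls[calls$mag_id == m, , drop = FALSE]
    vals <- unname(ab[d$gene_id])
    em <- intersect(d$gene_id, eetMhc)
    binOf <- function(lab) {
      g <- em[!is.na(bins[em]) & bins[em] == lab]
      if (!length(g)) 0 else sum(ab[g])
    }
    cyc2 <- d$gene_id[d$call_class == "cyc2"]
    data.frame(
      mag_id = m,
      n_eet_genes = nrow(d),
      mean_normalized = if (nrow(d)) mean(vals) else 0,
      sum_normalized = if (nrow(d)) sum(vals) else 0,
      has_pcc_known = any(d$call_class == "pcc_component" &
                          d$cluster_type == "known_family", na.rm = TRUE),
      has_pcc_novel = any(d$call_class == "pcc_component" &
                          d$cluster_type == "novel_organization",
                          na.rm = TRUE),
      has_outer_surface_mhc = any(d$call_class == "outer_surface_mhc"),
      has_cyc2 = any(d$call_class == "cyc2"),
      sum_eet_mhc_5_10 = binOf(lowLab),
      sum_eet_mhc_gt10 = binOf(highLab),
      sum_cyc2 = if (length(cyc2)) sum(ab[cyc2]) else 0,
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  # drop zero-call MAG rows except the always-present unbinned row
  out[out$n_eet_genes > 0L | out$mag_id == "unbinned", , drop = FALSE]
}

#' Fraction of MAGs carrying putative EET genes
#'
#' @param magSummary output of [summarizeMags()].
#' @param mags named contig-to-MAG vector (defines the MAG universe).
#' @return named list: `n_eet_mags`, `n_mags`, `fraction`.
#' @export
fractionMagsWithEET <- function(magSummary, mags) {
  all_mags <- setdiff(unique(unname(mags)), "unbinned")
  eet_mags <- setdiff(magSummary$mag_id[magSummary$n_eet_genes > 0L],
                      "unbinned")
  list(n_eet_mags = length(eet_mags), n_mags = length(all_mags),
       fraction = if (length(all_mags)) length(eet_mags) / length(all_mags)
                  else NA_real_)
}
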