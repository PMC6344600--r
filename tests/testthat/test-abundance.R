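mkAbFeatures <- function() {
  data.frame(gene_id = c("g1", "hk1", "hk2"),
             contig_id = c("c1", "c2", "c3"),
             start = 0L, end = 300L, strand = "+", rank = 0L,
             stringsAsFactors = FALSE)
}

test_that("normalization divides by the mean housekeeping coverage", {
  ft <- mkAbFeatures()
  cov <- c(c1 = 12, c2 = 6, c3 = 6)
  ab <- normalizeAbundance(ft, cov, c("hk1", "hk2"))
  expect_equal(ab$normalized[ab$gene_id == "g1"], 2.0)
  expect_equal(unique(ab$denominator), 6)

  # gene coverage equal to every housekeeping coverage gives exactly 1
  for (c0 in c(0.5, 7, 123)) {
    ab1 <- normalizeAbundance(ft, c(c1 = c0, c2 = c0, c3 = c0),
                              c("hk1", "hk2"))
    expect_equal(ab1$normalized, rep(1, 3))
  }
})

test_that("normalized values are invariant under global coverage rescaling", {
  ft <- mkAbFeatures()
  cov <- c(c1 = 12, c2 = 4, c3 = 9)
  base <- normalizeAbundance(ft, cov, c("hk1", "hk2"))
  for (f in c(3, 0.1)) {
    scaled <- normalizeAbundance(ft, cov * f, c("hk1", "hk2"))
    expect_equal(scaled$normalized, base$normalized)
  }
})

test_that("normalization errors on empty or zero-coverage housekeeping sets", {
  ft <- mkAbFeatures()
  cov <- c(c1 = 12, c2 = 0, c3 = 0)
  expect_error(normalizeAbundance(ft, cov, character()), "empty")
  expect_error(normalizeAbundance(ft, cov, c("hk1", "hk2")), "not positive")
  expect_error(normalizeAbundance(ft, c(c1 = 1, c2 = 1, c3 = 1), "nope"),
               "absent")
})

test_that("per-gene coverage overrides contig inheritance when supplied", {
  ft <- mkAbFeatures()
  cov <- c(c1 = 12, c2 = 6, c3 = 6)
  ab <- normalizeAbundance(ft, cov, c("hk1", "hk2"),
                           geneCoverage = c(g1 = 24))
  expect_equal(ab$normalized[ab$gene_id == "g1"], 4.0)
})

test_that("metagenome summary sums member genes per bin", {
  calls <- data.frame(
    gene_id = c("m1", "m2"), contig_id = "c1", mag_id = "MAG1",
    call_class = "outer_surface_mhc", cluster_id = NA, cluster_type = NA,
    family = NA, heme_count = c(6L, 12L), compartment = "outer_membrane",
    evidence = "x", stringsAsFactors = FALSE)
  mhc <- classifyMHC(data.frame(protein_id = c("m1", "m2"),
                                heme_count = c(6L, 12L)))
  ab <- data.frame(gene_id = c("m1", "m2"), contig_id = "c1",
                   coverage = c(9, 3), denominator = 6,
                   normalized = c(1.5, 0.5))
  s <- summarizeMetagenome(calls, mhc, ab, "m")
  expect_equal(s$mhc_5_10, 1.5)
  expect_equal(s$mhc_gt10, 0.5)
  expect_equal(s$eet_mhc_5_10, 1.5)
  expect_equal(s$eet_mhc_gt10, 0.5)
  expect_equal(s$cyc2_total, 0)

  empty <- summarizeMetagenome(calls[0, ], mhc[0, ], ab[0, ], "m")
  expect_true(all(unlist(empty[, 2:6]) == 0))
})

test_that("MAG summary averages member genes and keeps an unbinned row", {
  calls <- data.frame(
    gene_id = c("a", "b", "c", "u"),
    contig_id = c("c1", "c1", "c1", "c9"),
    mag_id = c("MAG1", "MAG1", "MAG1", "unbinned"),
    call_class = c("outer_surface_mhc", "outer_surface_mhc", "cyc2",
                   "outer_surface_mhc"),
    cluster_id = NA, cluster_type = NA, family = NA,
    heme_count = c(6L, 11L, 1L, 7L),
    compartment = "outer_membrane", evidence = "x",
    stringsAsFactors = FALSE)
  mhc <- classifyMHC(data.frame(protein_id = c("a", "b", "c", "u"),
                                heme_count = c(6L, 11L, 1L, 7L)))
  ab <- data.frame(gene_id = c("a", "b", "c", "u"), contig_id = "c",
                   coverage = 1, denominator = 1,
                   normalized = c(2, 2, 2, 5))
  ms <- summarizeMags(calls, ab, mhc, c(c1 = "MAG1", c9 = "unbinned"))
  m1 <- ms[ms$mag_id == "MAG1", ]
  expect_equal(m1$mean_normalized, 2)
  expect_equal(m1$n_eet_genes, 3L)
  expect_true(m1$has_outer_surface_mhc && m1$has_cyc2)
  expect_false(m1$has_pcc_known)
  un <- ms[ms$mag_id == "unbinned", ]
  expect_equal(un$n_eet_genes, 1L)
  expect_equal(un$sum_normalized, 5)

  # a MAG with zero EET calls is absent
  expect_false("MAG2" %in% ms$mag_id)
  frac <- fractionMagsWithEET(ms, c(c1 = "MAG1", c2 = "MAG2",
                                    c9 = "unbinned"))
  expect_equal(frac$fraction, 0.5)
})

test_that("metagenome totals equal MAG sums plus the unbinned row", {
  cfg <- synthConfig(seed = 17, mhcHemeCounts = c(5L, 8L, 11L, 13L),
                     nPccKnown = 2L, nPccNovel = 2L, nCyc2 = 3L,
                     nDecoyNearMhc = 2L, nDecoyLonePorin = 2L,
                     nDecoyLoneMhcNoSignal = 2L, nDecoyCysRich = 2L,
                     nHousekeeping = 6L, nMags = 3L)
  g <- generateSyntheticMetagenome(cfg, refs = refPanel())
  res <- scanMetagenome(g$metagenome, refs = refPanel())
  s <- res$metagenomeSummary
  m <- res$magSummary
  expect_equal(sum(m$sum_eet_mhc_5_10), s$eet_mhc_5_10)
  expect_equal(sum(m$sum_eet_mhc_gt10), s$eet_mhc_gt10)
  expect_equal(sum(m$sum_cyc2), s$cyc2_total)

  # and the additivity survives a global coverage rescaling
  mg <- g$metagenome
  mg2 <- EETMetagenome(metagenomeId(mg), proteins(mg), geneFeatures(mg),
                       contigCoverage(mg) * 3, mags = magAssignment(mg),
                       housekeeping = housekeepingGenes(mg),
                       localization = mg@localization)
  res2 <- scanMetagenome(mg2, refs = refPanel())
  expect_equal(res2$metagenomeSummary[, 2:6], s[, 2:6])
})
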