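smallCfg <- function(seed = 5) {
  synthConfig(seed = seed, mhcHemeCounts = c(5L, 11L),
              nPccKnown = 1L, nPccNovel = 1L, nCyc2 = 1L,
              nDecoyNearMhc = 1L, nDecoyLonePorin = 1L,
              nDecoyLoneMhcNoSignal = 1L, nDecoyCysRich = 1L,
              nHousekeeping = 4L, nMags = 2L)
}

test_that("generation is byte-identical for the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateSyntheticMetagenome(smallCfg(), dir = d1, refs = refPanel())
  generateSyntheticMetagenome(smallCfg(), dir = d2, refs = refPanel())
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generateSyntheticMetagenome(smallCfg(seed = 6), dir = d3,
                              refs = refPanel())
  expect_false(identical(unname(tools::md5sum(file.path(d1, "proteins.faa"))),
                         unname(tools::md5sum(file.path(d3, "proteins.faa")))))
})

test_that("the emitted file bundle reloads into the same call set", {
  d <- withr::local_tempdir()
  g <- generateSyntheticMetagenome(smallCfg(), dir = d, refs = refPanel())
  mg <- loadMetagenome("synth",
                       proteinFasta = file.path(d, "proteins.faa"),
                       gff = file.path(d, "genes.gff3"),
                       coveragePath = file.path(d, "coverage.tsv"),
                       magPath = file.path(d, "mags.tsv"),
                       housekeepingPath = file.path(d, "housekeeping.tsv"),
                       localizationPath = file.path(d, "localization.tsv"))
  resMem <- scanMetagenome(g$metagenome, refs = refPanel())
  resFile <- scanMetagenome(mg, refs = refPanel())
  o1 <- resMem$calls[order(resMem$calls$gene_id), ]
  o2 <- resFile$calls[order(resFile$calls$gene_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # coverage is serialized at fixed precision; abundances agree to that
  expect_equal(resFile$abundance$normalized, resMem$abundance$normalized,
               tolerance = 1e-5)
})

test_that("truth heme counts match an independent motif scan of every protein", {
  g <- generateSyntheticMetagenome(smallCfg(), refs = refPanel())
  p <- as.character(proteins(g$metagenome))
  tr <- g$truth
  for (i in seq_len(nrow(tr))) {
    expect_equal(length(bruteForceHemePositions(p[[tr$gene_id[i]]])),
                 tr$heme_count[i], info = tr$gene_id[i])
  }
  expect_true(all(tr$certified_no_accidental_motif))
})

test_that("an all-zero plant config yields a valid empty-truth metagenome", {
  cfg <- synthConfig(seed = 9, mhcHemeCounts = integer(0),
                     nPccKnown = 0L, nPccNovel = 0L, nCyc2 = 0L,
                     nDecoyNearMhc = 0L, nDecoyLonePorin = 0L,
                     nDecoyLoneMhcNoSignal = 0L, nDecoyCysRich = 0L,
                     nHousekeeping = 4L, nMags = 2L)
  g <- generateSyntheticMetagenome(cfg, refs = refPanel())
  expect_true(all(g$truth$truth_class %in% c("housekeeping", "filler")))
  res <- scanMetagenome(g$metagenome, refs = refPanel())
  expect_equal(nrow(res$calls), 0L)
  ev <- evaluateCalls(res$calls, g$truth)
  expect_true(all(ev$precision == 1))
  expect_true(all(ev$recall == 1))
})

test_that("evaluateCalls arithmetic and error handling are exact", {
  truth <- data.frame(gene_id = c("a", "b", "c", "d"),
                      truth_class = c("cyc2", "cyc2", "filler",
                                      "outer_surface_mhc"),
                      heme_count = c(1L, 1L, 0L, 8L),
                      cluster_id = NA, cluster_type = NA, role = NA,
                      family = NA, stringsAsFactors = FALSE)
  mkCalls <- function(ids, cls) {
    data.frame(gene_id = ids, contig_id = "c", mag_id = "m",
               call_class = cls, cluster_id = NA, cluster_type = NA,
               family = NA, heme_count = 1L, compartment = "outer_membrane",
               evidence = "x", stringsAsFactors = FALSE)
  }
  # one of two cyc2 found: recall 0.5, precision 1
  ev <- evaluateCalls(mkCalls("a", "cyc2"), truth)
  expect_equal(ev$recall[ev$class == "cyc2"], 0.5)
  expect_equal(ev$precision[ev$class == "cyc2"], 1)
  # a decoy called: precision 0.5 and the decoy listed
  ev2 <- evaluateCalls(mkCalls(c("a", "c"), "cyc2"), truth)
  expect_equal(ev2$precision[ev2$class == "cyc2"], 0.5)
  expect_match(ev2$false_positive_ids[ev2$class == "cyc2"], "c")
  # unknown ids are an error
  expect_error(evaluateCalls(mkCalls("zz", "cyc2"), truth), "absent")
})

test_that("density scaling multiplies EET content only", {
  base <- smallCfg()
  s3 <- scaleSynthConfig(base, 3L)
  expect_length(s3$mhcHemeCounts, 3L * length(base$mhcHemeCounts))
  expect_equal(s3$nPccKnown, 3L * base$nPccKnown)
  expect_equal(s3$nCyc2, 3L * base$nCyc2)
  expect_equal(s3$nHousekeeping, base$nHousekeeping)
  expect_equal(s3$nDecoyCysRich, base$nDecoyCysRich)
})
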