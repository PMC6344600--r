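# helpers to build hand-crafted evidence tables -----------------------------

mkFeatures <- function(contigs) {
  # contigs: named list of gene-id vectors in gene order
  rows <- lapply(names(contigs), function(ct) {
    g <- contigs[[ct]]
    data.frame(gene_id = g, contig_id = ct,
               start = seq_along(g) * 1000L,
               end = seq_along(g) * 1000L + 900L,
               strand = "+", rank = seq_along(g) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

mkMhc <- function(ids, hemes) {
  classifyMHC(data.frame(protein_id = ids, heme_count = as.integer(hemes)))
}

mkLoc <- function(ids, signal, compartment = NULL) {
  data.frame(protein_id = ids,
             compartment = if (is.null(compartment))
               ifelse(signal, "periplasmic", "cytoplasmic") else compartment,
             has_signal_peptide = signal, evidence = "heuristic",
             stringsAsFactors = FALSE)
}

mkHit <- function(query, family, role, score = 200, identity = 0.6,
                  qcov = 0.9, qs = 1L, qe = 100L) {
  data.frame(query_id = query, family = family, role = role, score = score,
             identity = identity, query_coverage = qcov,
             reference_coverage = 0.9, query_start = qs, query_end = qe,
             stringsAsFactors = FALSE)
}

test_that("an adjacent porin + signal-peptide MHC forms a novel cluster", {
  ft <- mkFeatures(list(c1 = c("g1", "g2")))
  cl <- detectPCCClusters(ft, mkMhc(c("g1", "g2"), c(0, 8)),
                          mkLoc(c("g1", "g2"), c(FALSE, TRUE)),
                          mkHit("g1", "porin_other", "porin"))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$cluster_type, "novel_organization")
  expect_equal(cl$porin_gene, "g1")
  expect_equal(cl$peri_mhc_gene, "g2")
  expect_equal(cl$peri_heme_count, 8L)
  expect_true(is.na(cl$family))
})

test_that("MtrB + MtrA homolog pairs are typed known-family", {
  ft <- mkFeatures(list(c1 = c("g1", "g2", "g3")))
  hits <- rbind(mkHit("g1", "MtrB", "porin"),
                mkHit("g2", "MtrA", "periplasmic_MHC"),
                mkHit("g3", "MtrC", "extracellular_MHC"))
  cl <- detectPCCClusters(ft, mkMhc(c("g1", "g2", "g3"), c(0, 10, 10)),
                          mkLoc(c("g1", "g2", "g3"), c(FALSE, TRUE, TRUE)),
                          hits)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$cluster_type, "known_family")
  expect_equal(cl$family, "MtrABC")
  expect_equal(cl$extra_mhc_gene, "g3")
})

test_that("porin and MHC on different contigs never cluster", {
  ft <- mkFeatures(list(c1 = "g1", c2 = "g2"))
  cl <- detectPCCClusters(ft, mkMhc(c("g1", "g2"), c(0, 8)),
                          mkLoc(c("g1", "g2"), c(FALSE, TRUE)),
                          mkHit("g1", "porin_other", "porin"))
  expect_equal(nrow(cl), 0L)
})

test_that("the gene-gap window is enforced and monotone", {
  ft <- mkFeatures(list(c1 = c("g1", "f1", "f2", "g2")))  # gap of 2 genes
  mhc <- mkMhc(c("g1", "f1", "f2", "g2"), c(0, 0, 0, 8))
  loc <- mkLoc(c("g1", "f1", "f2", "g2"), c(FALSE, FALSE, FALSE, TRUE))
  hits <- mkHit("g1", "porin_other", "porin")
  expect_equal(nrow(detectPCCClusters(ft, mhc, loc, hits,
                                      maxGeneGap = 1L)), 0L)
  expect_equal(nrow(detectPCCClusters(ft, mhc, loc, hits,
                                      maxGeneGap = 2L)), 1L)
  # widening the window keeps every cluster found with a narrower one
  ft2 <- mkFeatures(list(c1 = c("g1", "g2"), c2 = c("g3", "f1", "g4")))
  mhc2 <- mkMhc(c("g1", "g2", "g3", "f1", "g4"), c(0, 8, 0, 0, 9))
  loc2 <- mkLoc(c("g1", "g2", "g3", "f1", "g4"),
                c(FALSE, TRUE, FALSE, FALSE, TRUE))
  hits2 <- rbind(mkHit("g1", "porin_other", "porin"),
                 mkHit("g3", "porin_other", "porin"))
  narrow <- detectPCCClusters(ft2, mhc2, loc2, hits2, maxGeneGap = 1L)
  wide <- detectPCCClusters(ft2, mhc2, loc2, hits2, maxGeneGap = 3L)
  expect_true(all(narrow$cluster_id %in% wide$cluster_id))
})

test_that("the periplasmic member must carry a signal peptide", {
  ft <- mkFeatures(list(c1 = c("g1", "g2")))
  cl <- detectPCCClusters(ft, mkMhc(c("g1", "g2"), c(0, 8)),
                          mkLoc(c("g1", "g2"), c(FALSE, FALSE)),
                          mkHit("g1", "porin_other", "porin"))
  expect_equal(nrow(cl), 0L)
})

test_that("each gene joins at most one cluster, leftmost first", {
  # porin, MHC, porin: the single MHC pairs with the left porin
  ft <- mkFeatures(list(c1 = c("g1", "g2", "g3")))
  hits <- rbind(mkHit("g1", "porin_other", "porin"),
                mkHit("g3", "porin_other", "porin"))
  cl <- detectPCCClusters(ft, mkMhc(c("g1", "g2", "g3"), c(0, 8, 0)),
                          mkLoc(c("g1", "g2", "g3"), c(FALSE, TRUE, FALSE)),
                          hits)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$porin_gene, "g1")
})

test_that("outer-surface MHC calls respect compartment and exclusivity", {
  mhc <- mkMhc(c("g1", "g2", "g3"), c(12, 12, 6))
  loc <- mkLoc(c("g1", "g2", "g3"), c(FALSE, TRUE, FALSE),
               compartment = c("outer_membrane", "periplasmic",
                               "cytoplasmic"))
  noClusters <- detectPCCClusters(mkFeatures(list(c1 = "g1")),
                                  mhc[1, ], loc[1, ],
                                  mkHit("none", "MtrB", "porin")[0, ])
  expect_equal(callOuterSurfaceMHCs(mhc, loc, noClusters), "g1")

  # a clustered MHC is a pcc_component, never outer-surface
  ft <- mkFeatures(list(c1 = c("p1", "m1")))
  mhc2 <- mkMhc(c("p1", "m1"), c(0, 12))
  loc2 <- mkLoc(c("p1", "m1"), c(FALSE, TRUE),
                compartment = c("outer_membrane", "outer_membrane"))
  cl <- detectPCCClusters(ft, mhc2, loc2, mkHit("p1", "porin_other", "porin"))
  expect_equal(nrow(cl), 1L)
  expect_equal(callOuterSurfaceMHCs(mhc2, loc2, cl), character(0))
})

test_that("Cyc2 calls require one N-terminal motif, a hit, and sane length", {
  mkScan <- function(ids, positions) {
    data.frame(protein_id = ids,
               heme_count = vapply(positions, length, integer(1)),
               positions = I(positions), stringsAsFactors = FALSE)
  }
  lens <- c(ok = 450L, twomotif = 450L, nohit = 450L, late = 450L,
            short = 100L, lowcov = 450L)
  scans <- mkScan(names(lens),
                  list(25L, c(25L, 200L), 25L, 70L, 25L, 25L))
  hits <- rbind(
    mkHit("ok", "Cyc2", "cyc2", qs = 10L, qe = 440L),
    mkHit("twomotif", "Cyc2", "cyc2", qs = 10L, qe = 440L),
    mkHit("late", "Cyc2", "cyc2", qs = 10L, qe = 440L),
    mkHit("short", "Cyc2", "cyc2", qs = 10L, qe = 95L),
    mkHit("lowcov", "Cyc2", "cyc2", qs = 1L, qe = 250L))  # 25/225 of C-half
  expect_equal(callCyc2(scans, hits, lens), "ok")
})

test_that("call classes partition the gene set and ignore input order", {
  cfg <- synthConfig(seed = 31, mhcHemeCounts = c(6L, 12L),
                     nPccKnown = 2L, nPccNovel = 2L, nCyc2 = 2L,
                     nDecoyNearMhc = 2L, nDecoyLonePorin = 2L,
                     nDecoyLoneMhcNoSignal = 2L, nDecoyCysRich = 2L,
                     nHousekeeping = 4L, nMags = 2L)
  g <- generateSyntheticMetagenome(cfg, refs = refPanel())
  res <- scanMetagenome(g$metagenome, refs = refPanel())
  expect_equal(anyDuplicated(res$calls$gene_id), 0L)

  # permute protein and feature order: the call set must not change
  mg <- g$metagenome
  set.seed(99)
  perm <- sample(length(proteins(mg)))
  ftperm <- geneFeatures(mg)[sample(nrow(geneFeatures(mg))), ]
  mg2 <- EETMetagenome(metagenomeId(mg), proteins(mg)[perm], ftperm,
                       contigCoverage(mg), mags = magAssignment(mg),
                       housekeeping = housekeepingGenes(mg),
                       localization = mg@localization)
  res2 <- scanMetagenome(mg2, refs = refPanel())
  o1 <- res$calls[order(res$calls$gene_id), ]
  o2 <- res2$calls[order(res2$calls$gene_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})
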