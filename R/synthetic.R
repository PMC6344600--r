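.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

# background residue frequencies, C/H-depleted so accidental CXXCH motifs
# are rare and rejection sampling converges fast
.bgFreqs <- function(c_freq = 0.005, h_freq = 0.01) {
  f <- setNames(rep((1 - c_freq - h_freq) / 18, 20), .AA20)
  f["C"] <- c_freq; f["H"] <- h_freq
  f
}

.sampleResidues <- function(n, freqs = .bgFreqs()) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

.countMotifs <- function(seq, spacers = 2L) {
  scanHemeMotifs(setNames(seq, "q"), spacers)$heme_count
}

# deterministic signal-peptide prefix satisfying the built-in heuristic:
# basic n-region then a hydrophobic h-region; contains no C or H so it can
# never contribute a heme motif
.SIGNAL_PREFIX <- "MKRLLAVLLAVFALMA"

# a random signal-peptide prefix satisfying the heuristic (basic n-region,
# then >= 7 hydrophobics); varied per protein, like real signal peptides,
# and free of C/H
.randomSignalPrefix <- function() {
  hyd <- c("A", "F", "I", "L", "M", "V", "W")
  paste0("M",
         paste(sample(c("K", "R"), sample(1:2, 1L), replace = TRUE),
               collapse = ""),
         paste(sample(hyd, sample(8:11, 1L), replace = TRUE), collapse = ""),
         paste(sample(c("A", "G", "S", "T"), 3L, replace = TRUE),
               collapse = ""))
}

# motif-free random protein (rejection-sampled, certification by re-scan)
.randProtein <- function(len, spacers = 2L, freqs = .bgFreqs(),
                         maxTries = 200L) {
  for (i in seq_len(maxTries)) {
    s <- .sampleResidues(len, freqs)
    if (.countMotifs(s, spacers) == 0L) return(s)
  }
  stop("rejection sampling failed to produce a motif-free background ",
       "after ", maxTries, " tries; lower the C/H frequencies")
}

# protein with exactly `hemes` planted CXXCH motifs (certified by re-scan)
.plantMotifs <- function(hemes, len = max(150L, 12L * hemes + 50L),
                         spacers = 2L, prefix = "", maxTries = 200L) {
  npre <- nchar(prefix)
  stopifnot(len > npre + 6L * max(1L, hemes))
  for (i in seq_len(maxTries)) {
    body <- .randProtein(len - npre, spacers)
    s <- paste0(prefix, body)
    if (hemes > 0L) {
      slack <- (len - 5L) - npre - 6L * (hemes - 1L)
      offs <- sort(sample.int(slack + 1L, hemes, replace = TRUE)) - 1L
      pos0 <- npre + offs + 6L * (seq_len(hemes) - 1L)   # 0-based starts
      ch <- strsplit(s, "")[[1L]]
      wob <- setdiff(.AA20, c("C", "H"))
      for (p in pos0) {
        ch[p + 1L] <- "C"
        ch[p + 2L] <- sample(wob, 1L)
        ch[p + 3L] <- sample(wob, 1L)
        ch[p + 4L] <- "C"
        ch[p + 5L] <- "H"
      }
      s <- paste(ch, collapse = "")
    }
    if (.countMotifs(s, spacers) == hemes) return(s)
  }
  stop("rejection sampling failed to plant exactly ", hemes,
       " motifs after ", maxTries, " tries")
}

# 1-based indices covered by heme motifs (to freeze them under mutation)
.motifFootprint <- function(seq, spacers = 2L) {
  pos0 <- scanHemeMotifs(setNames(seq, "q"), spacers)$positions[[1L]]
  if (!length(pos0)) return(integer(0))
  sort(unique(unlist(lapply(pos0, function(p)
    (p + 1L):(p + max(spacers) + 3L)))))
}

# point-mutate towards a target identity; mutations never introduce C or H
# so planted motif counts survive, verified by the caller's re-scan
.mutateSeq <- function(seq, identity, preserve = integer(0)) {
  ch <- strsplit(seq, "")[[1L]]
  cand <- setdiff(seq_along(ch), preserve)
  hit <- cand[runif(length(cand)) < (1 - identity)]
  sub <- setdiff(.AA20, c("C", "H"))
  for (i in hit) ch[i] <- sample(setdiff(sub, ch[i]), 1L)
  paste(ch, collapse = "")
}

.HK_MARKERS <- c("rpsA","rpsB","rpsC","rpsE","rpsK","rplA","rplB","rplC",
                 "rplD","rplE","rplF","rplK","rplM","rplN","rplP","rpoA",
                 "rpoB","gyrA","gyrB","recA","dnaK","infB","secY","ffh")

#' Configuration of the synthetic metagenome generator
#'
#' The defaults define one well-populated benchmark metagenome: 50 planted
#' outer-surface MHCs whose heme counts include 5, 8, 10, 11, and 51 (the
#' extremes and bin boundaries of interest), five known-family PCC operons
#' cycling through the MtrABC / MtoAB / PioAB / OmbB-OmaB-OmcB systems,
#' five novel-organization PCC operons (porin-like gene plus a
#' signal-peptide MHC with no family homology), five Cyc2-like genes, 32
#' decoys of four kinds (4-heme near-MHCs, lone porins, lone MHCs without
#' a signal peptide, cysteine-rich motif-free proteins), and 24
#' housekeeping genes. Contig coverage is lognormal with MAG-level
#' multipliers.
#'
#' @param seed mandatory integer seed; the generator is fully
#'   deterministic given the seed.
#' @param mhcHemeCounts integer vector; one planted outer-surface MHC per
#'   entry.
#' @param nPccKnown,nPccNovel,nCyc2 planted operon/gene counts.
#' @param nDecoyNearMhc,nDecoyLonePorin,nDecoyLoneMhcNoSignal,nDecoyCysRich
#'   decoy counts by type.
#' @param nHousekeeping,nMags housekeeping gene count and MAG count.
#' @param identityTarget target residue identity of mutated reference
#'   homologs, in (0, 1].
#' @param covMu,covSigma lognormal (meanlog/sdlog) contig coverage
#'   parameters.
#' @param magSigma sdlog of the MAG-level coverage multiplier.
#' @param fillerLenMin,fillerLenMax length range of motif-free filler
#'   proteins.
#' @param unbinnedEvery every n-th contig is left unbinned.
#' @param spacers heme-motif spacer set used for planting and
#'   certification.
#' @return a `synthConfig` list.
#' @export
synthConfig <- function(seed,
                        mhcHemeCounts = c(5L, 8L, 10L, 11L, 51L,
                          rep(c(6L, 7L, 9L, 12L, 15L, 5L, 8L, 10L, 11L, 13L),
                              length.out = 45L)),
                        nPccKnown = 5L, nPccNovel = 5L, nCyc2 = 5L,
                        nDecoyNearMhc = 8L, nDecoyLonePorin = 8L,
                        nDecoyLoneMhcNoSignal = 8L, nDecoyCysRich = 8L,
                        nHousekeeping = 24L, nMags = 6L,
                        identityTarget = 0.75,
                        covMu = 1.0, covSigma = 0.5, magSigma = 0.3,
                        fillerLenMin = 120L, fillerLenMax = 300L,
                        unbinnedEvery = 7L, spacers = 2L) {
  if (missing(seed) || is.na(seed)) stop("synthConfig requires a seed")
  cfg <- list(seed = as.integer(seed),
              mhcHemeCounts = as.integer(mhcHemeCounts),
              nPccKnown = nPccKnown, nPccNovel = nPccNovel, nCyc2 = nCyc2,
              nDecoyNearMhc = nDecoyNearMhc,
              nDecoyLonePorin = nDecoyLonePorin,
              nDecoyLoneMhcNoSignal = nDecoyLoneMhcNoSignal,
              nDecoyCysRich = nDecoyCysRich,
              nHousekeeping = nHousekeeping, nMags = nMags,
              identityTarget = identityTarget,
              covMu = covMu, covSigma = covSigma, magSigma = magSigma,
              fillerLenMin = fillerLenMin, fillerLenMax = fillerLenMax,
              unbinnedEvery = unbinnedEvery, spacers = as.integer(spacers))
  counts <- cfg[c("nPccKnown", "nPccNovel", "nCyc2", "nDecoyNearMhc",
                  "nDecoyLonePorin", "nDecoyLoneMhcNoSignal",
                  "nDecoyCysRich", "nHousekeeping")]
  if (any(unlist(counts) < 0L)) stop("all plant counts must be >= 0")
  if (identityTarget <= 0 || identityTarget > 1)
    stop("identityTarget must be in (0, 1]")
  class(cfg) <- c("synthConfig", "list")
  cfg
}

#' Scale the planted EET gene content of a config
#'
#' Multiplies the EET plant counts (outer-surface MHCs, both PCC operon
#' types, Cyc2) by an integer density factor, leaving decoys, housekeeping
#' genes, and coverage parameters untouched. Used to emulate an EET-gene
#' density gradient across metagenomes.
#'
#' @param config a [synthConfig()].
#' @param mult positive integer multiplier.
#' @return a new `synthConfig`.
#' @export
scaleSynthConfig <- function(config, mult) {
  mult <- as.integer(mult)
  stopifnot(mult >= 1L)
  config$mhcHemeCounts <- rep(config$mhcHemeCounts, times = mult)
  for (f in c("nPccKnown", "nPccNovel", "nCyc2"))
    config[[f]] <- config[[f]] * mult
  config
}

# ---- generator ------------------------------------------------------------

.newContig <- function(state) {
  state$ncontig <- state$ncontig + 1L
  sprintf("%s_c%03d", state$id, state$ncontig)
}

.newGene <- function(state) {
  state$ngene <- state$ngene + 1L
  sprintf("%s_g%04d", state$id, state$ngene)
}

#' Generate a synthetic metagenome with planted ground truth
#'
#' Emits a complete input bundle (protein FASTA, GFF3, coverage TSV, MAG
#' TSV, housekeeping TSV, localization TSV) plus a truth table describing
#' every planted item. All planted heme counts are certified by an
#' independent re-scan at emission, and every protein that must not match
#' the reference panel (novel-operon members, decoys, fillers) is verified
#' against it, with offenders resampled — so exact planted-truth recovery
#' is a hard expectation, not an approximate one. Deterministic given the
#' config seed.
#'
#' @param config a [synthConfig()].
#' @param dir optional directory; when given, all files are written there.
#' @param id prefix for contig/gene ids and the metagenome id.
#' @param refs reference panel ([eetReferences()]) used for homolog
#'   planting and non-matching certification.
#' @param certify verify non-matching proteins against the panel
#'   (default `TRUE`).
#' @return list with `metagenome` ([EETMetagenome-class]), `truth`
#'   (`data.frame`), `config`, and (when `dir` is given) `paths`.
#' @export
generateSyntheticMetagenome <- function(config, dir = NULL, id = "synth",
                                        refs = eetReferences(),
                                        certify = TRUE) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(config$seed)
  sp <- config$spacers
  state <- new.env()
  state$id <- id; state$ncontig <- 0L; state$ngene <- 0L

  proteins <- character()     # named
  truth <- list()
  contigs <- list()           # contig_id -> ordered gene ids
  annot <- list()             # localization annotation rows
  hk <- list()
  mustNotMatch <- character() # protein ids certified non-matching
  regenFun <- list()          # id -> closure regenerating the sequence

  addGene <- function(seq, class, heme, cluster_id = NA, cluster_type = NA,
                      role = NA, family = NA, certifyNoMatch = FALSE,
                      regen = NULL) {
    gid <- .newGene(state)
    proteins[[gid]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      gene_id = gid, truth_class = class, heme_count = as.integer(heme),
      cluster_id = cluster_id, cluster_type = cluster_type, role = role,
      family = family, stringsAsFactors = FALSE)
    if (certifyNoMatch) {
      mustNotMatch <<- c(mustNotMatch, gid)
      if (!is.null(regen)) regenFun[[gid]] <<- regen
    }
    gid
  }
  filler <- function() {
    len <- sample(config$fillerLenMin:config$fillerLenMax, 1L)
    addGene(.randProtein(len, sp), "filler", 0L)
  }
  addContig <- function(coreGenes, nFlank = TRUE) {
    ct <- .newContig(state)
    before <- if (nFlank) replicate(sample(0:2, 1L), filler()) else character()
    after <- if (nFlank) replicate(sample(0:2, 1L), filler()) else character()
    contigs[[ct]] <<- c(unlist(before), coreGenes, unlist(after))
    ct
  }
  refSeq <- function(family) {
    i <- which(refs$meta$family == family)[1L]
    list(seq = as.character(refs$seqs[[i]]), hemes = refs$meta$hemes[i])
  }
  mutantOf <- function(family, freezePrefix = FALSE) {
    r <- refSeq(family)
    pres <- .motifFootprint(r$seq, sp)
    if (freezePrefix) pres <- union(seq_len(nchar(.SIGNAL_PREFIX)), pres)
    for (i in 1:50) {
      m <- .mutateSeq(r$seq, config$identityTarget, pres)
      if (.countMotifs(m, sp) == r$hemes) return(list(seq = m, hemes = r$hemes))
    }
    stop("mutation kept creating spurious motifs for family ", family)
  }

  # -- outer-surface MHCs ---------------------------------------------------
  for (h in config$mhcHemeCounts) {
    gid <- addGene(.plantMotifs(h, spacers = sp), "outer_surface_mhc", h,
                   certifyNoMatch = certify,
                   regen = local({hh <- h; function() .plantMotifs(hh, spacers = sp)}))
    annot[[length(annot) + 1L]] <-
      data.frame(protein_id = gid, compartment = "outer_membrane")
    addContig(gid)
  }

  # -- known-family PCC operons --------------------------------------------
  systems <- list(
    list(porin = "MtrB", peri = "MtrA", extra = "MtrC", label = "MtrABC"),
    list(porin = "MtoB", peri = "MtoA", extra = NA, label = "MtoAB"),
    list(porin = "PioB", peri = "PioA", extra = NA, label = "PioAB"),
    list(porin = "OmbB", peri = "OmaB", extra = "OmcB",
         label = "OmbB-OmaB-OmcB"))
  for (i in seq_len(config$nPccKnown)) {
    sys <- systems[[(i - 1L) %% length(systems) + 1L]]
    cl <- sprintf("%s_truthpcc_known_%02d", id, i)
    p <- mutantOf(sys$porin)
    m <- mutantOf(sys$peri, freezePrefix = TRUE)
    gp <- addGene(p$seq, "pcc_component", p$hemes, cl, "known_family",
                  "porin", sys$label)
    core <- gp
    if (i %% 2L == 0L) core <- c(core, filler())  # exercise the gene gap
    gm <- addGene(m$seq, "pcc_component", m$hemes, cl, "known_family",
                  "periplasmic_MHC", sys$label)
    core <- c(core, gm)
    if (!is.na(sys$extra)) {
      e <- mutantOf(sys$extra, freezePrefix = TRUE)
      ge <- addGene(e$seq, "pcc_component", e$hemes, cl, "known_family",
                    "extracellular_MHC", sys$label)
      core <- c(core, ge)
    }
    addContig(core)
  }

  # -- novel-organization PCC operons --------------------------------------
  novelHemes <- rep(c(6L, 8L, 9L, 7L, 12L), length.out = config$nPccNovel)
  for (i in seq_len(config$nPccNovel)) {
    cl <- sprintf("%s_truthpcc_novel_%02d", id, i)
    p <- mutantOf("porin_other")
    h <- novelHemes[i]
    mhcSeq <- .plantMotifs(h, spacers = sp, prefix = .randomSignalPrefix())
    gp <- addGene(p$seq, "pcc_component", 0L, cl, "novel_organization",
                  "porin", NA)
    core <- gp
    if (i %% 2L == 1L) core <- c(core, filler())
    gm <- addGene(mhcSeq, "pcc_component", h, cl, "novel_organization",
                  "periplasmic_MHC", NA, certifyNoMatch = certify,
                  regen = local({hh <- h; function()
                    .plantMotifs(hh, spacers = sp,
                                 prefix = .randomSignalPrefix())}))
    core <- c(core, gm)
    addContig(core)
  }

  # -- Cyc2-like genes ------------------------------------------------------
  for (i in seq_len(config$nCyc2)) {
    m <- mutantOf("Cyc2", freezePrefix = TRUE)
    addContig(addGene(m$seq, "cyc2", m$hemes, role = "cyc2", family = "Cyc2"))
  }

  # -- decoys ---------------------------------------------------------------
  for (i in seq_len(config$nDecoyNearMhc)) {
    gid <- addGene(.plantMotifs(4L, spacers = sp), "decoy_near_mhc", 4L,
                   certifyNoMatch = certify,
                   regen = function() .plantMotifs(4L, spacers = sp))
    annot[[length(annot) + 1L]] <-
      data.frame(protein_id = gid, compartment = "outer_membrane")
    addContig(gid)
  }
  for (i in seq_len(config$nDecoyLonePorin)) {
    p <- mutantOf("porin_other")
    addContig(addGene(p$seq, "decoy_lone_porin", 0L))
  }
  noSignalMhc <- function(h) {
    for (i in 1:50) {
      s <- .plantMotifs(h, spacers = sp)
      if (!predictSignalPeptide(setNames(s, "q"))) return(s)
    }
    stop("could not generate a signal-free MHC decoy")
  }
  decoyHemes <- rep(c(5L, 7L, 9L, 12L), length.out = config$nDecoyLoneMhcNoSignal)
  for (i in seq_len(config$nDecoyLoneMhcNoSignal)) {
    h <- decoyHemes[i]
    addContig(addGene(noSignalMhc(h), "decoy_lone_mhc_no_signal", h,
                      certifyNoMatch = certify,
                      regen = local({hh <- h; function() noSignalMhc(hh)})))
  }
  cysFreqs <- .bgFreqs(c_freq = 0.15, h_freq = 0.01)
  for (i in seq_len(config$nDecoyCysRich)) {
    addContig(addGene(.randProtein(220L, sp, cysFreqs), "decoy_cys_rich", 0L,
                      certifyNoMatch = certify,
                      regen = function() .randProtein(220L, sp, cysFreqs)))
  }

  # -- housekeeping genes ---------------------------------------------------
  for (i in seq_len(config$nHousekeeping)) {
    len <- sample(220:350, 1L)
    gid <- addGene(.randProtein(len, sp), "housekeeping", 0L)
    hk[[length(hk) + 1L]] <- data.frame(
      gene_id = gid,
      marker = .HK_MARKERS[(i - 1L) %% length(.HK_MARKERS) + 1L],
      stringsAsFactors = FALSE)
    addContig(gid)
  }

  # -- certification: nothing in the non-matching set may hit the panel -----
  if (certify && length(mustNotMatch)) {
    toCheck <- mustNotMatch
    for (round in 1:10) {
      hits <- searchReferences(proteins[toCheck], refs)
      bad <- unique(hits$query_id)
      if (!length(bad)) break
      if (round == 10L)
        stop("certification failed: decoys kept matching the reference ",
             "panel: ", paste(bad, collapse = ", "))
      for (g in bad)
        proteins[[g]] <- if (!is.null(regenFun[[g]])) regenFun[[g]]()
                         else .randProtein(nchar(proteins[[g]]), sp)
      toCheck <- bad   # only re-verify the regenerated ones
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), truth_class = character(),
               heme_count = integer(), cluster_id = character(),
               cluster_type = character(), role = character(),
               family = character(), stringsAsFactors = FALSE)

  # -- contig layout, MAGs, coverage ---------------------------------------
  ftRows <- list()
  contigIds <- names(contigs)
  magOfContig <- character()
  for (ci in seq_along(contigIds)) {
    ct <- contigIds[ci]
    pos <- 0L
    for (g in contigs[[ct]]) {
      gap <- sample(20:120, 1L)
      glen <- 3L * (nchar(proteins[[g]]) + 1L)
      ftRows[[length(ftRows) + 1L]] <- data.frame(
        gene_id = g, contig_id = ct, start = pos + gap,
        end = pos + gap + glen, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      pos <- pos + gap + glen
    }
    magOfContig[ct] <-
      if (config$unbinnedEvery > 0L && ci %% config$unbinnedEvery == 0L)
        "unbinned"
      else sprintf("%s_MAG%02d", id, (ci %% max(1L, config$nMags)) + 1L)
  }
  features <- if (length(ftRows)) do.call(rbind, ftRows) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  magNames <- setdiff(unique(magOfContig), "unbinned")
  magMult <- setNames(exp(rnorm(length(magNames), 0, config$magSigma)),
                      magNames)
  coverage <- vapply(contigIds, function(ct) {
    mult <- if (magOfContig[ct] == "unbinned") 1 else magMult[[magOfContig[ct]]]
    mult * exp(rnorm(1L, config$covMu, config$covSigma))
  }, numeric(1))

  truth$contig_id <- features$contig_id[match(truth$gene_id, features$gene_id)]
  truth$mag_id <- unname(magOfContig[truth$contig_id])
  truth$certified_no_accidental_motif <- TRUE
  truth$certified_decoy_nonmatching <- truth$gene_id %in% mustNotMatch

  annot <- if (length(annot)) do.call(rbind, annot) else
    data.frame(protein_id = character(), compartment = character(),
               stringsAsFactors = FALSE)
  hk <- if (length(hk)) do.call(rbind, hk) else
    data.frame(gene_id = character(), marker = character(),
               stringsAsFactors = FALSE)

  mg <- EETMetagenome(id, proteins, features, coverage,
                      mags = magOfContig, housekeeping = hk$gene_id,
                      localization = annot)
  out <- list(metagenome = mg, truth = truth, config = config)

  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create directory: ", dir)
    paths <- c(proteins = file.path(dir, "proteins.faa"),
               gff = file.path(dir, "genes.gff3"),
               coverage = file.path(dir, "coverage.tsv"),
               mags = file.path(dir, "mags.tsv"),
               housekeeping = file.path(dir, "housekeeping.tsv"),
               localization = file.path(dir, "localization.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeLines(paste0(">", names(proteins), "\n", unname(proteins)),
               paths["proteins"])
    gffCoord <- internalToGff(features$start, features$end)
    writeLines(c("##gff-version 3",
                 sprintf("%s\teetscan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                         features$contig_id, gffCoord$start, gffCoord$end,
                         features$strand, features$gene_id)),
               paths["gff"])
    .writeTsv(data.frame(contig_id = contigIds,
                         coverage = sprintf("%.6f", coverage)),
              paths["coverage"])
    .writeTsv(data.frame(contig_id = contigIds,
                         mag_id = unname(magOfContig[contigIds])),
              paths["mags"])
    .writeTsv(hk, paths["housekeeping"])
    .writeTsv(annot, paths["localization"])
    .writeTsv(truth, paths["truth"])
    out$paths <- paths
  }
  out
}

#' Simulate a three-metagenome study with an EET-density gradient
#'
#' Builds three synthetic metagenomes emulating an oxic clear-water lake
#' epilimnion (low EET gene density), a humic-bog epilimnion
#' (intermediate), and a humic-bog hypolimnion (high), by scaling one base
#' config with integer density multipliers (default 1:2:4 for
#' ME/TE/TH-like). Housekeeping content and coverage parameters are
#' identical across the three, so normalized abundances are comparable.
#'
#' @param seed integer seed; each metagenome derives its own sub-seed.
#' @param dir optional directory; per-metagenome subdirectories are
#'   written beneath it.
#' @param multipliers named integer vector of density multipliers.
#' @param base base [synthConfig()]; defaults to a compact per-metagenome
#'   content (5 outer-surface MHCs, 2 + 2 PCC operons, 5 Cyc2 genes, a few
#'   decoys, 24 housekeeping genes) before scaling.
#' @param refs reference panel.
#' @return named list of [generateSyntheticMetagenome()] results, in
#'   multiplier order as given.
#' @export
simulateStudy <- function(seed, dir = NULL,
                          multipliers = c(ME = 1L, TE = 2L, TH = 4L),
                          base = NULL, refs = eetReferences()) {
  if (is.null(base))
    base <- synthConfig(seed, mhcHemeCounts = c(6L, 7L, 9L, 11L, 12L),
                        nPccKnown = 2L, nPccNovel = 2L, nCyc2 = 5L,
                        nDecoyNearMhc = 2L, nDecoyLonePorin = 2L,
                        nDecoyLoneMhcNoSignal = 2L, nDecoyCysRich = 2L,
                        nHousekeeping = 24L, nMags = 4L)
  out <- list()
  for (i in seq_along(multipliers)) {
    mId <- names(multipliers)[i]
    cfg <- scaleSynthConfig(base, multipliers[[i]])
    cfg$seed <- base$seed + i
    sub <- if (!is.null(dir)) file.path(dir, mId) else NULL
    out[[mId]] <- generateSyntheticMetagenome(cfg, dir = sub, id = mId,
                                              refs = refs)
  }
  out
}

#' Score pipeline calls against planted truth
#'
#' Computes per-class precision, recall, and confusion counts for the
#' three call classes, optionally for MHC status, and optionally for exact
#' PCC cluster composition. Conventions: empty classes score 1; a
#' precision below 1 lists the offending ids.
#'
#' @param calls gene-level call table from [callEETGenes()].
#' @param truth truth table from [generateSyntheticMetagenome()].
#' @param mhcCalls optional [classifyMHC()] output; adds an `mhc` row
#'   comparing MHC status against planted heme counts.
#' @param clusters optional [detectPCCClusters()] output; adds a
#'   `pcc_cluster_exact` row requiring exact member-set recovery.
#' @param mhcMin MHC threshold used for the `mhc` row.
#' @return `data.frame`: `class`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `false_positive_ids`, `false_negative_ids`.
#' @export
evaluateCalls <- function(calls, truth, mhcCalls = NULL, clusters = NULL,
                          mhcMin = 5L) {
  unknown <- setdiff(calls$gene_id, truth$gene_id)
  if (length(unknown))
    stop("calls reference gene ids absent from the truth table: ",
         paste(unknown, collapse = ", "))
  prf <- function(class, predicted, expected) {
    tp <- length(intersect(predicted, expected))
    fp <- setdiff(predicted, expected)
    fn <- setdiff(expected, predicted)
    data.frame(class = class, tp = tp, fp = length(fp), fn = length(fn),
               precision = if (tp + length(fp) == 0L) 1 else
                 tp / (tp + length(fp)),
               recall = if (tp + length(fn) == 0L) 1 else
                 tp / (tp + length(fn)),
               false_positive_ids = paste(fp, collapse = ";"),
               false_negative_ids = paste(fn, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (cls in c("pcc_component", "outer_surface_mhc", "cyc2")) {
    rows[[cls]] <- prf(cls,
                       calls$gene_id[calls$call_class == cls],
                       truth$gene_id[truth$truth_class == cls])
  }
  if (!is.null(mhcCalls)) {
    known <- intersect(mhcCalls$protein_id, truth$gene_id)
    pred <- intersect(mhcCalls$protein_id[mhcCalls$is_mhc], known)
    exp_ <- truth$gene_id[truth$heme_count >= mhcMin]
    rows[["mhc"]] <- prf("mhc", pred, exp_)
  }
  if (!is.null(clusters)) {
    key <- function(members) paste(sort(members), collapse = "+")
    predSets <- if (nrow(clusters)) vapply(seq_len(nrow(clusters)),
      function(i) key(stats::na.omit(c(clusters$porin_gene[i],
                                       clusters$peri_mhc_gene[i],
                                       clusters$extra_mhc_gene[i]))),
      character(1)) else character(0)
    tr <- truth[truth$truth_class == "pcc_component" & !is.na(truth$cluster_id), ]
    truthSets <- if (nrow(tr))
      vapply(split(tr$gene_id, tr$cluster_id), key, character(1))
    else character(0)
    rows[["pcc_cluster_exact"]] <- prf("pcc_cluster_exact", predSets,
                                       unname(truthSets))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
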