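test_that("self-alignment recovers the BLOSUM62 diagonal sum", {
  set.seed(1)
  for (i in 1:5) {
    s <- randomProtein(20L)
    hit <- localAlign(s, s)
    expect_equal(hit$score,
                 sum(diag(blosum62)[strsplit(s, "")[[1L]]]))
    expect_equal(hit$identity, 1.0)
    expect_equal(hit$query_coverage, 1.0)
    expect_equal(hit$reference_coverage, 1.0)
  }
})

test_that("all-negative scoring pairs give the empty local alignment", {
  hit <- localAlign("AAAA", "WWWW")
  expect_equal(hit$score, 0)
  expect_equal(hit$identity, 0)
  expect_equal(hit$query_coverage, 0)
  expect_true(is.na(hit$query_start))
})

test_that("alignment errors on empty input", {
  expect_error(localAlign("", "MKW"), "empty")
  expect_error(localAlign("MKW", ""), "empty")
})

test_that("alignment score is symmetric", {
  set.seed(2)
  for (i in 1:20) {
    a <- randomProtein(sample(10:60, 1L))
    b <- randomProtein(sample(10:60, 1L))
    expect_equal(localAlign(a, b)$score, localAlign(b, a)$score)
  }
})

test_that("scores match the independent dynamic-programming oracle", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(5:60, 1L)
    a <- randomProtein(n)
    b <- if (i %% 2 == 0) randomProtein(sample(5:60, 1L)) else {
      # related pair: mutate ~20% of a copy
      ch <- strsplit(a, "")[[1L]]
      hit <- runif(n) < 0.2
      ch[hit] <- sample(AA, sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }
    got <- localAlign(a, b)
    want <- oracleLocalAlign(a, b, blosum62)
    expect_equal(got$score, want$score, info = paste(a, b))
  }
})

test_that("reported identity and coverage are consistent with the traceback", {
  set.seed(4)
  for (i in 1:40) {
    a <- randomProtein(sample(20:60, 1L))
    ch <- strsplit(a, "")[[1L]]
    hit <- runif(length(ch)) < 0.2
    ch[hit] <- sample(AA, sum(hit), replace = TRUE)
    b <- paste(ch, collapse = "")
    got <- localAlign(a, b)
    if (got$score == 0) next
    qa <- strsplit(got$query_aln, "")[[1L]]
    ra <- strsplit(got$ref_aln, "")[[1L]]
    expect_equal(got$identity, sum(qa == ra & qa != "-") / length(qa))
    expect_equal(got$query_coverage,
                 (got$query_end - got$query_start + 1L) / nchar(a))
  }
})

test_that("mutating 20% of a reference yields identity near 0.8", {
  set.seed(5)
  ids <- replicate(100, {
    ref <- randomProtein(120L)
    ch <- strsplit(ref, "")[[1L]]
    hit <- runif(120L) < 0.2
    ch[hit] <- vapply(which(hit), function(j)
      sample(setdiff(AA, ch[j]), 1L), character(1))
    localAlign(paste(ch, collapse = ""), ref)$identity
  })
  # local alignment clips mismatching ends, so identities sit at or just
  # above the 0.8 residue-level value
  expect_true(median(ids) >= 0.75 && median(ids) <= 0.85)
  expect_true(all(ids >= 0.70 & ids <= 0.92))
})

test_that("reference search finds planted homologs and rejects shuffles", {
  refs <- refPanel()
  i <- which(refs$meta$family == "MtrA")
  mtra <- as.character(refs$seqs[[i]])
  ch <- strsplit(mtra, "")[[1L]]
  set.seed(6)
  hit <- runif(length(ch)) < 0.3
  ch[hit] <- sample(setdiff(AA, c("C", "H")), sum(hit), replace = TRUE)
  mut <- paste(ch, collapse = "")
  h <- searchReferences(c(q = mut), refs)
  peri <- h[h$role == "periplasmic_MHC", ]
  expect_equal(nrow(peri), 1L)
  expect_equal(peri$family, "MtrA")

  exact <- searchReferences(setNames(as.character(
    refs$seqs[[which(refs$meta$family == "Cyc2")]]), "q"), refs)
  expect_equal(exact$identity[exact$role == "cyc2"], 1.0)

  # empirical null: shuffled sequences of the same composition almost never hit
  nulls <- vapply(1:100, function(j) {
    shuf <- paste(sample(strsplit(mtra, "")[[1L]]), collapse = "")
    nrow(searchReferences(setNames(shuf, "s"), refs)) == 0L
  }, logical(1))
  expect_gte(mean(nulls), 0.95)
})

test_that("raising the identity threshold never adds hits", {
  refs <- refPanel()
  set.seed(7)
  qs <- setNames(c(vapply(1:5, function(i) randomProtein(200L), character(1)),
                   as.character(refs$seqs[["MtrA_syn"]])),
                 paste0("q", 1:6))
  h30 <- searchReferences(qs, refs, minIdentity = 0.30)
  h50 <- searchReferences(qs, refs, minIdentity = 0.50)
  expect_true(all(paste(h50$query_id, h50$family) %in%
                  paste(h30$query_id, h30$family)))
  expect_lte(nrow(h50), nrow(h30))
})

test_that("family-to-role mapping follows the characterized architectures", {
  expect_equal(familyRole(c("MtrB", "MtoB", "PioB", "OmbB")),
               rep("porin", 4))
  expect_equal(familyRole(c("MtrA", "MtoA", "PioA", "OmaB")),
               rep("periplasmic_MHC", 4))
  expect_equal(familyRole(c("MtrC", "OmcB")), rep("extracellular_MHC", 2))
  expect_equal(familyRole("Cyc2"), "cyc2")
  expect_true(is.na(familyRole("NotAFamily")))
})
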