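# Independent oracles and small fixture builders used across the suite.

AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

randomProtein <- function(len, alphabet = AA) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force heme-motif oracle: test every start index of C-X{k}-C-H
bruteForceHemePositions <- function(seq, spacers = 2L) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  hits <- integer(0)
  for (k in spacers) {
    L <- k + 3L
    if (n < L) next
    for (p0 in 0:(n - L)) {
      if (ch[p0 + 1L] == "C" && ch[p0 + k + 2L] == "C" &&
          ch[p0 + k + 3L] == "H")
        hits <- c(hits, p0)
    }
  }
  sort(unique(hits))
}

# quadratic-time Gotoh local alignment (gap of length L costs open + L*ext),
# with traceback; independent of Biostrings
oracleLocalAlign <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in query (consumes reference)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in reference (consumes query)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - (open + ext), E[i, j - 1L] - ext)
      F_[i, j] <- max(H[i - 1L, j] - (open + ext), F_[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[x[i - 1L], y[j - 1L]],
                     E[i, j], F_[i, j])
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1L, ]
  sc <- max(H)
  if (sc <= 0)
    return(list(score = 0, identity = 0, query_coverage = 0,
                reference_coverage = 0))
  # traceback from the best cell
  i <- best[1L]; j <- best[2L]; state <- "H"
  qa <- character(0); ra <- character(0)
  iEnd <- i - 1L; jEnd <- j - 1L
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag <- H[i - 1L, j - 1L] + mat[x[i - 1L], y[j - 1L]]
      if (H[i, j] == diag) {
        qa <- c(x[i - 1L], qa); ra <- c(y[j - 1L], ra)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) state <- "E"
      else state <- "F"
    } else if (state == "E") {
      qa <- c("-", qa); ra <- c(y[j - 1L], ra)
      from_h <- H[i, j - 1L] - (open + ext)
      state <- if (E[i, j] == from_h) "H" else "E"
      j <- j - 1L
    } else {
      qa <- c(x[i - 1L], qa); ra <- c("-", ra)
      from_h <- H[i - 1L, j] - (open + ext)
      state <- if (F_[i, j] == from_h) "H" else "F"
      i <- i - 1L
    }
  }
  qs <- i; rs <- j   # 1-based starts of the aligned intervals
  alen <- length(qa)
  nm <- sum(qa == ra & qa != "-")
  list(score = sc, identity = nm / alen,
       query_coverage = (iEnd - qs + 1L) / n,
       reference_coverage = (jEnd - rs + 1L) / m,
       query_start = qs, query_end = iEnd)
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# minimal metagenome builder for call-logic tests: genes laid out in the
# given order on one or more contigs
toyMetagenome <- function(genes, id = "toy", coverage = NULL, mags = NULL,
                          housekeeping = character(), localization = NULL,
                          monodermMags = character()) {
  # genes: data.frame(gene_id, contig_id, seq)
  ft <- do.call(rbind, lapply(split(genes, genes$contig_id), function(d) {
    pos <- 0L
    rows <- lapply(seq_len(nrow(d)), function(i) {
      glen <- 3L * (nchar(d$seq[i]) + 1L)
      r <- data.frame(gene_id = d$gene_id[i], contig_id = d$contig_id[i],
                      start = pos + 50L, end = pos + 50L + glen,
                      strand = "+", stringsAsFactors = FALSE)
      pos <<- pos + 50L + glen
      r
    })
    do.call(rbind, rows)
  }))
  rownames(ft) <- NULL
  if (is.null(coverage)) {
    cts <- unique(genes$contig_id)
    coverage <- stats::setNames(rep(10, length(cts)), cts)
  }
  EETMetagenome(id, stats::setNames(genes$seq, genes$gene_id), ft, coverage,
                mags = mags, housekeeping = housekeeping,
                localization = localization, monodermMags = monodermMags)
}

# cached bundled reference panel (loading it once keeps tests fast)
refPanel <- local({
  refs <- NULL
  function() {
    if (is.null(refs)) refs <<- eetReferences()
    refs
  }
})

# an MHC-like sequence with exactly n planted CXXCH motifs on a motif-free
# random background (verified), optionally with a signal-peptide N terminus
plantedMhcSeq <- function(n, len = max(150L, 12L * n + 50L),
                          signal = FALSE) {
  prefix <- if (signal) "MKRLLAVLLAVFALMAGST" else ""
  repeat {
    body <- randomProtein(len - nchar(prefix),
                          alphabet = setdiff(AA, c("C", "H")))
    s <- paste0(prefix, body)
    ch <- strsplit(s, "")[[1L]]
    npre <- nchar(prefix)
    slots <- seq(npre + 1L, len - 5L, by = 7L)
    if (length(slots) < n) stop("sequence too short for ", n, " motifs")
    for (p in slots[seq_len(n)]) {
      ch[p] <- "C"; ch[p + 3L] <- "C"; ch[p + 4L] <- "H"
    }
    s <- paste(ch, collapse = "")
    if (identical(bruteForceHemePositions(s), integer(0)) == (n == 0L) &&
        length(bruteForceHemePositions(s)) == n)
      return(s)
  }
}
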