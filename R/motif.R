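#' Scan proteins for heme-binding motifs
#'
#' Finds every start index at which a c-type heme-binding motif
#' `C-X{k}-C-H` matches, for each spacer length `k` in `spacers` (the
#' canonical motif is `CXXCH`, `k = 2`). Overlapping matches at distinct
#' start indices are all counted, so reported heme counts are deterministic
#' and order-independent. The letter `X` matches at wildcard slots but never
#' at the anchor `C`/`H` slots.
#'
#' @param x named character vector or [Biostrings::AAStringSet] of protein
#'   sequences (uppercase, canonical alphabet plus `X`).
#' @param spacers integer vector of spacer lengths `k >= 1`; default `2`
#'   (canonical `CXXCH` only).
#' @return `data.frame` with one row per protein: `protein_id`,
#'   `heme_count`, and a list-column `positions` of 0-based motif start
#'   indices (strictly increasing).
#' @examples
#' scanHemeMotifs(c(p = "MKCAACHAAGGCAACHW"))
#' @export
scanHemeMotifs <- function(x, spacers = 2L) {
  if (inherits(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("protein sequences must be named")
  spacers <- as.integer(spacers)
  if (length(spacers) == 0L || any(is.na(spacers)) || any(spacers < 1L))
    stop("spacers must be a non-empty set of integers >= 1")
  pats <- sprintf("(?=C.{%d}CH)", spacers)
  pos <- lapply(x, function(s) {
    hits <- integer(0)
    for (p in pats) {
      m <- gregexpr(p, s, perl = TRUE)[[1L]]
      if (m[1L] != -1L) hits <- c(hits, as.integer(m) - 1L)  # 0-based
    }
    sort(unique(hits))
  })
  data.frame(protein_id = names(x),
             heme_count = vapply(pos, length, integer(1)),
             positions = I(unname(pos)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify MHC status and heme-count bins
#'
#' A protein is a multiheme c-type cytochrome (MHC) when its heme count
#' reaches `mhcMin` (default 5). Counts are binned into `"5-10"`
#' (`mhcMin <= n <= binSplit`) and `">10"` (`n > binSplit`), the two bins
#' used for abundance reporting; `passes_8` flags the stricter
#' `>= emphMin` cut used to emphasize potential molecular-wire MHCs.
#'
#' @param scan output of [scanHemeMotifs()], or any `data.frame` with
#'   `protein_id` and `heme_count` columns.
#' @param mhcMin minimum heme count for MHC status (default 5).
#' @param emphMin threshold for the emphasized high-heme flag (default 8).
#' @param binSplit boundary between the two reporting bins (default 10).
#' @return `data.frame` with columns `protein_id`, `heme_count`, `is_mhc`,
#'   `bin` (`"5-10"`, `">10"`, or `NA`), `passes_8`.
#' @export
classifyMHC <- function(scan, mhcMin = 5L, emphMin = 8L, binSplit = 10L) {
  stopifnot(mhcMin >= 1L, binSplit >= mhcMin)
  hc <- scan$heme_count
  lowLab <- paste0(mhcMin, "-", binSplit)
  highLab <- paste0(">", binSplit)
  bin <- rep(NA_character_, length(hc))
  bin[hc >= mhcMin & hc <= binSplit] <- lowLab
  bin[hc > binSplit] <- highLab
  data.frame(protein_id = scan$protein_id,
             heme_count = hc,
             is_mhc = hc >= mhcMin,
             bin = bin,
             passes_8 = hc >= emphMin,
             stringsAsFactors = FALSE, row.names = NULL)
}
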