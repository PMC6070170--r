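# Target-site prediction by position-weighted complementarity, the
# standard plant-miRNA penalty scheme: near-perfect complementarity
# over the whole site, with the 5' seed region weighted double.

.pair_penalty <- function(mirna_base, site_base) {
  # site is mRNA sense strand; penalty for the miRNA base against the
  # site base it would pair with in the duplex
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  if (mirna_base %in% c("A", "C", "G", "U") &&
      identical(unname(wc[mirna_base]), site_base)) return(0)
  if ((mirna_base == "G" && site_base == "U") ||
      (mirna_base == "U" && site_base == "G")) return(0.5)
  1.0
}

#' Penalty score of a miRNA against one candidate target site
#'
#' Positions are numbered 1..L from the miRNA 5' end; the site is the
#' mRNA sense strand, so miRNA position i faces site position L+1-i.
#' Each mismatch costs 1.0 and each G:U wobble 0.5, doubled within the
#' seed-extended region (positions 2-13).  A perfect complement scores
#' exactly 0.  The regulation mode is `"translational"` when any of
#' positions 9-11 is a strict mismatch (cleavage requires central
#' pairing), `"cleavage"` otherwise.
#'
#' @param mirna,site character scalars of equal length.
#' @return list with `expectation` (penalty >= 0) and `mode`.
#' @export
score_site <- function(mirna, site) {
  m <- strsplit(unname(mirna[1L]), "", fixed = TRUE)[[1L]]
  s <- strsplit(unname(site[1L]), "", fixed = TRUE)[[1L]]
  if (length(m) != length(s))
    stop("score_site: miRNA and site must have equal length", call. = FALSE)
  L <- length(m)
  expectation <- 0
  central_mismatch <- FALSE
  for (i in seq_len(L)) {
    p <- .pair_penalty(m[i], s[L - i + 1L])
    if (i >= 2L && i <= 13L) p <- 2 * p
    expectation <- expectation + p
    if (i >= 9L && i <= 11L && .pair_penalty(m[i], s[L - i + 1L]) == 1.0)
      central_mismatch <- TRUE
  }
  list(expectation = expectation,
       mode = if (central_mismatch) "translational" else "cleavage")
}

#' Scan transcripts for candidate target sites of a miRNA
#'
#' Scores every ungapped window of miRNA length on the sense strand of
#' each transcript and reports windows with expectation at or below
#' `cutoff`, overlapping windows deduplicated to the best (lowest
#' expectation, then leftmost), sorted by (expectation, transcript,
#' start).  Lowering the cutoff never adds hits.
#'
#' @param mirna named character scalar.
#' @param transcripts named character vector.
#' @param cutoff maximum reported expectation (default 5.0, a standard
#'   default for plant target prediction).
#' @return data.frame with columns `mirna_id`, `transcript_id`, `start`,
#'   `end`, `expectation`, `mode`.
#' @export
scan_targets <- function(mirna, transcripts, cutoff = 5.0) {
  mid <- if (!is.null(names(mirna))) names(mirna)[1L] else "mirna"
  m <- strsplit(unname(mirna[1L]), "", fixed = TRUE)[[1L]]
  L <- length(m)
  weights <- ifelse(seq_len(L) >= 2L & seq_len(L) <= 13L, 2, 1)
  # per-position penalty lookup over the 5-letter alphabet
  pen <- lapply(m, function(b)
    vapply(.RNA_ALPHABET, function(x) .pair_penalty(b, x), numeric(1)))
  res <- list()
  for (tid in names(transcripts)) {
    s <- strsplit(unname(transcripts[[tid]]), "", fixed = TRUE)[[1L]]
    n <- length(s)
    if (n < L) next
    nw <- n - L + 1L
    expectation <- numeric(nw)
    central <- logical(nw)
    for (i in seq_len(L)) {
      # miRNA position i faces site index w + L - i for window start w
      sub <- s[(L - i + 1L):(n - i + 1L)]
      p <- pen[[i]][sub]
      expectation <- expectation + weights[i] * p
      if (i >= 9L && i <= 11L) central <- central | (p == 1.0)
    }
    keep <- which(expectation <= cutoff)
    if (!length(keep)) next
    df <- data.frame(mirna_id = mid, transcript_id = tid,
                     start = keep, end = keep + L - 1L,
                     expectation = expectation[keep],
                     mode = ifelse(central[keep], "translational", "cleavage"),
                     stringsAsFactors = FALSE)
    # deduplicate overlapping windows to the best hit per overlap group
    df <- df[order(df$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, df$start[-1L] > cummax(df$end)[-nrow(df)]))
    best <- unlist(lapply(split(seq_len(nrow(df)), grp), function(ix) {
      sub <- df[ix, , drop = FALSE]
      ix[order(sub$expectation, sub$start)][1L]
    }))
    res[[tid]] <- df[sort(best), , drop = FALSE]
  }
  if (!length(res))
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), mode = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$expectation, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
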