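# Homology search: deterministic, exhaustive replacements for the
# word-7 BLASTn mature scan and the word-28 precursor screen.
#
# For 17-25 nt queries at <= 2 mismatches a full-length Hamming scan over
# every transcript window is a superset of what seeded BLAST can find,
# and it is deterministic and dependency-free.  E-values play no role in
# the decision rule and are dropped.

#' Search configuration for the homology scans
#'
#' Defaults mirror standard conserved-miRNA homology practice: at most
#' 2 mismatches for mature queries of 17-25 nt, 150 nt of flank on each
#' side of a hit when cutting precursor windows, and a 28-nt exact seed
#' with >= 90% full-length identity for known-precursor screening.
#'
#' @param max_mismatches maximum Hamming distance for a mature hit.
#' @param min_mature_len,max_mature_len admissible mature query lengths (nt).
#' @param flank nt of flank on each side of a hit in [extract_window()].
#' @param seed_word exact seed length for [scan_precursor()] (nt).
#' @param min_precursor_identity minimum full-length identity fraction.
#' @param scan_reverse_complement scan the minus strand as well?
#' @return an object of class `search_config`.
#' @export
search_config <- function(max_mismatches = 2L, min_mature_len = 17L,
                          max_mature_len = 25L, flank = 150L,
                          seed_word = 28L, min_precursor_identity = 0.90,
                          scan_reverse_complement = TRUE) {
  stopifnot(max_mismatches >= 0L, min_mature_len <= max_mature_len,
            max_mismatches <= max_mature_len, flank >= 0L, seed_word >= 1L,
            min_precursor_identity > 0, min_precursor_identity <= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_mature_len = as.integer(min_mature_len),
                 max_mature_len = as.integer(max_mature_len),
                 flank = as.integer(flank),
                 seed_word = as.integer(seed_word),
                 min_precursor_identity = min_precursor_identity,
                 scan_reverse_complement = isTRUE(scan_reverse_complement)),
            class = "search_config")
}

.empty_hits <- function() {
  data.frame(query_id = character(), transcript_id = character(),
             start = integer(), end = integer(), strand = character(),
             mismatches = integer(), stringsAsFactors = FALSE)
}

# Hamming mismatch count of a query against every window of a transcript.
# N never matches (on either side).  Returns an integer vector indexed by
# window start, or a zero-length vector when the transcript is too short.
.window_mismatches <- function(qchars, tchars) {
  m <- length(qchars)
  n <- length(tchars)
  if (n < m) return(integer(0))
  starts <- seq_len(n - m + 1L)
  idx <- outer(seq_len(m) - 1L, starts, `+`)
  tm <- matrix(tchars[idx], nrow = m)
  mm <- (tm != qchars) | (tm == "N") | (qchars == "N")
  as.integer(colSums(mm))
}

#' Scan a transcript for mismatch-tolerant matches to a mature miRNA
#'
#' Every full-length window of the transcript (and of its reverse
#' complement when enabled) whose Hamming distance to the query is at
#' most `max_mismatches` is reported.  Minus-strand hits are reported in
#' plus-strand coordinates with `strand == "-"`.  Queries outside the
#' admissible mature length range are skipped with a warning, mirroring
#' the mature-length selection rule.
#'
#' @param query named character scalar (the mature miRNA).
#' @param transcript named character scalar.
#' @param cfg a [search_config()].
#' @return data.frame with columns `query_id`, `transcript_id`, `start`,
#'   `end`, `strand`, `mismatches`, sorted by coordinate.
#' @export
scan_mature <- function(query, transcript, cfg = search_config()) {
  qid <- if (!is.null(names(query))) names(query)[1L] else "query"
  tid <- if (!is.null(names(transcript))) names(transcript)[1L] else "transcript"
  q <- unname(query[1L]); t <- unname(transcript[1L])
  m <- nchar(q)
  if (m < cfg$min_mature_len || m > cfg$max_mature_len) {
    warning(sprintf("query '%s' length %d outside [%d, %d]; skipped",
                    qid, m, cfg$min_mature_len, cfg$max_mature_len))
    return(.empty_hits())
  }
  qchars <- strsplit(q, "", fixed = TRUE)[[1L]]
  tchars <- strsplit(t, "", fixed = TRUE)[[1L]]
  n <- length(tchars)
  res <- list()
  mm <- .window_mismatches(qchars, tchars)
  keep <- which(mm <= cfg$max_mismatches)
  if (length(keep))
    res[["+"]] <- data.frame(query_id = qid, transcript_id = tid,
                             start = keep, end = keep + m - 1L,
                             strand = "+", mismatches = mm[keep],
                             stringsAsFactors = FALSE)
  if (cfg$scan_reverse_complement) {
    rc <- rev(chartr("ACGUN", "UGCAN", tchars))
    mmr <- .window_mismatches(qchars, rc)
    keep <- which(mmr <= cfg$max_mismatches)
    if (length(keep)) {
      # window [s, s+m-1] on the reverse complement maps to plus-strand
      # span [n - (s+m-1) + 1, n - s + 1]
      res[["-"]] <- data.frame(query_id = qid, transcript_id = tid,
                               start = n - (keep + m - 1L) + 1L,
                               end = n - keep + 1L,
                               strand = "-", mismatches = mmr[keep],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.empty_hits())
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut a candidate precursor window around a mature hit
#'
#' Extracts `[start - flank, end + flank]`, silently clipped at the
#' transcript edges.  For minus-strand hits the reverse complement is
#' returned, so downstream folding always sees the mature sense strand;
#' the mature span is re-expressed on the returned sequence.
#'
#' @param transcript named character scalar.
#' @param hit one row of the data.frame returned by [scan_mature()].
#' @param cfg a [search_config()].
#' @return a list with elements `seq` (named character; the id records
#'   source transcript and coordinates), `window_start`, `window_end`
#'   (transcript coordinates), `mature_start`, `mature_end` (coordinates
#'   on the returned sequence) and `strand`.
#' @export
extract_window <- function(transcript, hit, cfg = search_config()) {
  t <- unname(transcript[1L])
  n <- nchar(t)
  stopifnot(hit$start >= 1L, hit$end <= n, hit$start <= hit$end)
  ws <- max(1L, hit$start - cfg$flank)
  we <- min(n, hit$end + cfg$flank)
  win <- substr(t, ws, we)
  if (identical(hit$strand, "-")) {
    win <- reverse_complement(win)
    ms <- we - hit$end + 1L
    me <- we - hit$start + 1L
  } else {
    ms <- hit$start - ws + 1L
    me <- hit$end - ws + 1L
  }
  id <- sprintf("%s:%d-%d(%s)", hit$transcript_id, ws, we, hit$strand)
  names(win) <- id
  list(seq = win, window_start = ws, window_end = we,
       mature_start = ms, mature_end = me, strand = hit$strand)
}

#' Screen a transcript for a known precursor by seed-and-extend
#'
#' Ungapped: every exact shared `seed_word`-mer anchors a full-length
#' ungapped alignment of the known precursor; alignments with identity
#' at or above `min_precursor_identity` are reported, deduplicated by
#' locus (overlapping hits collapse to the highest identity, then the
#' leftmost).  This is a screen, not an aligner: indel-containing loci
#' are missed by construction (documented limitation).
#'
#' @param known named character scalar (the known precursor).
#' @param transcript named character scalar.
#' @param cfg a [search_config()].
#' @return data.frame with columns `query_id`, `transcript_id`, `start`,
#'   `end`, `strand`, `identity`, `mismatches`.
#' @export
scan_precursor <- function(known, transcript, cfg = search_config()) {
  qid <- if (!is.null(names(known))) names(known)[1L] else "known"
  tid <- if (!is.null(names(transcript))) names(transcript)[1L] else "transcript"
  q <- unname(known[1L]); tr <- unname(transcript[1L])
  L <- nchar(q)
  if (L < cfg$seed_word)
    stop(sprintf("known precursor '%s' shorter than seed_word (%d < %d)",
                 qid, L, cfg$seed_word), call. = FALSE)
  qchars <- strsplit(q, "", fixed = TRUE)[[1L]]

  scan_strand <- function(seq, strand) {
    n <- nchar(seq)
    if (n < L) return(NULL)
    subject <- Biostrings::BString(seq)
    offsets <- integer(0)
    for (o in seq_len(L - cfg$seed_word + 1L)) {
      kmer <- substr(q, o, o + cfg$seed_word - 1L)
      if (grepl("N", kmer, fixed = TRUE)) next  # N never matches
      hits <- Biostrings::matchPattern(kmer, subject)
      if (length(hits))
        offsets <- c(offsets, Biostrings::start(hits) - o + 1L)
    }
    offsets <- unique(offsets)
    offsets <- offsets[offsets >= 1L & offsets + L - 1L <= n]
    if (!length(offsets)) return(NULL)
    schars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    rows <- lapply(offsets, function(s) {
      win <- schars[s:(s + L - 1L)]
      match <- (win == qchars) & (win != "N") & (qchars != "N")
      ident <- mean(match)
      if (ident < cfg$min_precursor_identity) return(NULL)
      if (strand == "+") {
        st <- s; en <- s + L - 1L
      } else {
        st <- n - (s + L - 1L) + 1L; en <- n - s + 1L
      }
      data.frame(query_id = qid, transcript_id = tid, start = st, end = en,
                 strand = strand, identity = ident,
                 mismatches = as.integer(sum(!match)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  out <- scan_strand(tr, "+")
  if (cfg$scan_reverse_complement)
    out <- rbind(out, scan_strand(reverse_complement(tr), "-"))
  if (is.null(out) || !nrow(out)) {
    return(data.frame(query_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  # deduplicate by locus: overlapping spans collapse to the best hit
  out <- out[order(out$start, out$end), , drop = FALSE]
  grp <- cumsum(c(TRUE, out$start[-1L] > cummax(out$end)[-nrow(out)]))
  keep <- unlist(lapply(split(seq_len(nrow(out)), grp), function(ix) {
    sub <- out[ix, , drop = FALSE]
    ix[order(-sub$identity, sub$start)][1L]
  }))
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
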