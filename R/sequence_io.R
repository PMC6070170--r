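# Sequence input/output and alphabet-safe primitives.
#
# Sequences are carried as named character vectors over the RNA alphabet
# {A,C,G,U} (plus N, kept and treated as unpairable/never matching).  DNA
# input (T) is silently normalized to U so transcriptome assemblies and
# miRBase-style RNA inputs interoperate.

.RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, maps T to U and validates that only A/C/G/U/N remain.
#' IUPAC ambiguity codes other than N are rejected: the downstream
#' filters are base-exact and expanding ambiguity codes would silently
#' change their meaning.
#'
#' @param seq character vector of sequences.
#' @param id optional identifier(s) used in error messages.
#' @return the normalized character vector (names preserved).
#' @export
normalize_rna <- function(seq, id = names(seq)) {
  if (is.null(id)) id <- rep("<unnamed>", length(seq))
  out <- chartr("t", "u", tolower(seq))
  out <- toupper(out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(out[i], regexpr("[^ACGUN]", out[i]))
    stop(sprintf("record '%s': illegal character '%s' (only A/C/G/T/U/N allowed)",
                 id[i], ch), call. = FALSE)
  }
  names(out) <- names(seq)
  out
}

#' Read a FASTA file of nucleotide sequences
#'
#' Records may be multi-line, DNA or RNA alphabet, mixed case; all are
#' normalized (T to U, uppercase).  Record order is preserved.  Empty
#' sequences and non-nucleotide characters (other than N) are format
#' errors naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  seqs <- as.character(set)
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop(sprintf("malformed FASTA '%s': record %d has an empty header",
                 path, which(!nzchar(ids))[1L]), call. = FALSE)
  if (any(!nzchar(seqs)))
    stop(sprintf("malformed FASTA '%s': record '%s' has an empty sequence",
                 path, ids[which(!nzchar(seqs))[1L]]), call. = FALSE)
  names(seqs) <- ids
  normalize_rna(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' G+C content of a sequence, in percent
#'
#' N counts in the denominator only, mirroring how published precursor
#' tables report G+C over the full precursor length.
#'
#' @param seq character vector of RNA sequences.
#' @return numeric vector of percentages in \[0, 100\].
#' @export
gc_percent <- function(seq) {
  n <- nchar(seq)
  if (any(n < 1L)) stop("gc_percent: empty sequence", call. = FALSE)
  gc <- nchar(gsub("[^GC]", "", seq))
  100 * gc / n
}

#' A+U content of a sequence, in percent
#' @inheritParams gc_percent
#' @export
au_percent <- function(seq) {
  n <- nchar(seq)
  if (any(n < 1L)) stop("au_percent: empty sequence", call. = FALSE)
  au <- nchar(gsub("[^AU]", "", seq))
  100 * au / n
}

#' Reverse complement of RNA sequences
#'
#' N is preserved.
#' @param seq character vector of RNA sequences.
#' @return character vector (names preserved).
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGUN", "UGCAN", seq)
  out <- vapply(strsplit(comp, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1))
  names(out) <- names(seq)
  out
}

#' Read a BED-like region annotation table
#'
#' Expects >= 4 tab-separated columns: reference, start, end, name, with
#' 0-based half-open coordinates on disk (BED convention).  Returned
#' coordinates are 1-based closed.  Regions on one reference must be
#' non-overlapping; they are returned sorted by start.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `reference`, `start`, `end`, `region`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop(sprintf("region file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  if (any(nfld < 4L))
    stop(sprintf("region file '%s', line %d: expected 4 tab-separated columns",
                 path, which(nfld < 4L)[1L]), call. = FALSE)
  df <- data.frame(
    reference = vapply(fields, `[`, character(1), 1L),
    start     = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L))),
    end       = suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L))),
    region    = vapply(fields, `[`, character(1), 4L),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$start) | is.na(df$end) | df$start < 0L | df$start >= df$end
  if (any(bad))
    stop(sprintf("region file '%s', line %d: need 0 <= start < end",
                 path, which(bad)[1L]), call. = FALSE)
  df$line <- seq_len(nrow(df))
  df$start <- df$start + 1L          # to 1-based closed
  validate_regions(df, source = path)
}

# shared validation for region tables already in 1-based closed coords
validate_regions <- function(df, source = "<regions>") {
  ord <- order(df$reference, df$start)
  df <- df[ord, , drop = FALSE]
  for (ref in unique(df$reference)) {
    sub <- df[df$reference == ref, , drop = FALSE]
    if (nrow(sub) > 1L) {
      overlap <- sub$start[-1L] <= sub$end[-nrow(sub)]
      if (any(overlap)) {
        ln <- if ("line" %in% names(sub)) sub$line[which(overlap)[1L] + 1L] else NA
        stop(sprintf("%s: overlapping regions on '%s'%s", source, ref,
                     if (!is.na(ln)) sprintf(" (line %d)", ln) else ""),
             call. = FALSE)
      }
    }
  }
  df$line <- NULL
  rownames(df) <- NULL
  df
}

#' Write a region annotation table as BED-like TSV
#'
#' Converts the in-memory 1-based closed coordinates back to 0-based
#' half-open on disk.
#' @param regions data.frame as returned by [read_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  out <- data.frame(regions$reference, regions$start - 1L, regions$end,
                    regions$region)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
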