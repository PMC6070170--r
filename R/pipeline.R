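# End-to-end orchestration: scan -> window -> fold -> trim -> evaluate
# -> deduplicate -> cluster/annotate, with TSV/JSON reporting.

#' Trim a folded window to the stem-loop enclosing the mature site
#'
#' Returns the span of the outermost base pair that encloses the whole
#' mature span (smallest start; largest partner on ties), or NULL when
#' no pair encloses the mature (the candidate then stays untrimmed and
#' is judged as-is).  Trimming recovers the precursor the field reports:
#' a +/-150 nt window carries flanking sequence that is not part of the
#' hairpin, and leaving it in would dilute AMFE/MFEI toward zero for
#' every candidate regardless of merit.
#'
#' @param h a `hairpin` (the folded window).
#' @param mature_span integer `c(start, end)` on the window.
#' @return integer `c(start, end)` or NULL.
#' @export
trim_to_hairpin <- function(h, mature_span) {
  ms <- mature_span[[1L]]; me <- mature_span[[2L]]
  pt <- h$pair_table
  i <- which(!is.na(pt) & pt > seq_along(pt))        # opening positions
  i <- i[i <= ms & pt[i] >= me]
  if (!length(i)) return(NULL)
  best <- i[order(i, -pt[i])][1L]
  c(start = best, end = pt[best])
}

# Shared candidate-evaluation path for one mature hit: extract the
# window, fold it, locate the mature, optionally trim to the enclosing
# stem-loop and refold, then evaluate.  Returns the report plus the
# precursor span in transcript coordinates.
.evaluate_locus <- function(transcript, query, hit, cfg = search_config(),
                            model = fold_model(),
                            criteria = filter_criteria(), trim = TRUE) {
  win <- extract_window(transcript, hit, cfg)
  h <- fold(win$seq, model)
  span <- tryCatch(
    locate_mature(win$seq, query, cfg$max_mismatches),
    error = function(e) c(start = win$mature_start, end = win$mature_end))
  precursor <- win$seq
  if (trim) {
    tspan <- trim_to_hairpin(h, span)
    if (!is.null(tspan)) {
      precursor <- substr(unname(win$seq), tspan[["start"]], tspan[["end"]])
      names(precursor) <- sprintf("%s|trim:%d-%d", names(win$seq),
                                  tspan[["start"]], tspan[["end"]])
      h <- fold(precursor, model)
      span <- c(start = span[["start"]] - tspan[["start"]] + 1L,
                end = span[["end"]] - tspan[["start"]] + 1L)
    } else tspan <- c(start = 1L, end = unname(nchar(win$seq)))
  } else tspan <- c(start = 1L, end = unname(nchar(win$seq)))
  report <- evaluate_candidate(precursor, query, h = h, criteria = criteria,
                               model = model,
                               max_locate_mismatches = cfg$max_mismatches)
  # precursor span back on the transcript (plus-strand coordinates)
  if (identical(hit$strand, "-")) {
    p_start <- win$window_end - tspan[["end"]] + 1L
    p_end <- win$window_end - tspan[["start"]] + 1L
  } else {
    p_start <- win$window_start + tspan[["start"]] - 1L
    p_end <- win$window_start + tspan[["end"]] - 1L
  }
  list(report = report, precursor = precursor, hairpin = h,
       start = p_start, end = p_end, window = win)
}

#' Assemble and validate a pipeline configuration
#'
#' `matures` and `transcriptome` may be FASTA file paths or named
#' character vectors; `regions` a BED-like TSV path or a region
#' data.frame (1-based closed).  Missing input files are a config error
#' raised before any computation.
#'
#' @param matures known mature miRNAs (path or named character vector).
#' @param transcriptome transcripts to scan (path or named character
#'   vector).
#' @param regions optional region annotation for cluster labelling.
#' @param search a [search_config()].
#' @param model a [fold_model()] or backend function.
#' @param criteria a [filter_criteria()].
#' @param max_gap cluster gap threshold (nt), default unlimited.
#' @param run_targets also scan accepted matures for target sites?
#' @param target_cutoff expectation cutoff for [scan_targets()].
#' @param trim trim windows to the mature-bearing stem-loop (default TRUE).
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param seed optional integer seed recorded in the run summary.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(matures, transcriptome, regions = NULL,
                            search = search_config(), model = fold_model(),
                            criteria = filter_criteria(), max_gap = Inf,
                            run_targets = FALSE, target_cutoff = 5.0,
                            trim = TRUE, out_dir = NULL, seed = NULL) {
  for (nm in c("matures", "transcriptome")) {
    x <- get(nm)
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        !file.exists(x))
      stop(sprintf("pipeline_config: %s file not found: %s", nm, x),
           call. = FALSE)
  }
  if (is.character(regions) && !file.exists(regions))
    stop(sprintf("pipeline_config: regions file not found: %s", regions),
         call. = FALSE)
  stopifnot(inherits(search, "search_config"),
            inherits(criteria, "filter_criteria"),
            max_gap >= 0, target_cutoff >= 0)
  structure(list(matures = matures, transcriptome = transcriptome,
                 regions = regions, search = search, model = model,
                 criteria = criteria, max_gap = max_gap,
                 run_targets = isTRUE(run_targets),
                 target_cutoff = target_cutoff, trim = isTRUE(trim),
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

.load_seqs <- function(x, what) {
  if (is.character(x) && length(x) == 0L) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x)))
    return(read_fasta(x))
  if (is.character(x) && !is.null(names(x))) return(normalize_rna(x))
  stop(sprintf("cannot interpret %s input", what), call. = FALSE)
}

#' Run the discovery pipeline end to end
#'
#' Stages: mature homology scan on both strands, +/-flank window
#' extraction, folding, mature localization, stem-loop trimming,
#' seven-criterion evaluation, per-locus deduplication of accepted
#' candidates (overlapping candidates collapse to the best MFEI, then
#' the leftmost), and -- when a region annotation is supplied -- cluster
#' detection with region labels.  Zero passing candidates is a valid
#' outcome, not an error.
#'
#' When `out_dir` is set, writes `candidates.tsv` (every evaluated
#' candidate with its verdicts), `accepted.tsv`, `rejected.tsv` (with
#' failed criteria named), `clusters.tsv` and `summary.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `summary` (stage counts, config echo, seed,
#'   version), `candidates`, `accepted`, `rejected`, `clusters`,
#'   `targets`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  matures <- .load_seqs(cfg$matures, "matures")
  transcripts <- .load_seqs(cfg$transcriptome, "transcriptome")
  regions <- cfg$regions
  if (is.character(regions)) regions <- read_regions(regions)

  qlen <- nchar(matures)
  skipped <- names(matures)[qlen < cfg$search$min_mature_len |
                              qlen > cfg$search$max_mature_len]
  for (q in skipped)
    warning(sprintf("query '%s' outside mature length bounds; skipped", q))
  queries <- matures[!names(matures) %in% skipped]

  hits <- list()
  for (q in names(queries))
    for (tx in names(transcripts)) {
      h <- scan_mature(queries[q], transcripts[tx], cfg$search)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  hits <- if (length(hits)) do.call(rbind, hits) else .empty_hits()

  rows <- list()
  for (k in seq_len(nrow(hits))) {
    hit <- hits[k, ]
    ev <- .evaluate_locus(transcripts[hit$transcript_id],
                          queries[hit$query_id], hit,
                          cfg$search, cfg$model, cfg$criteria, cfg$trim)
    st <- ev$report$stats
    rows[[k]] <- data.frame(
      query_id = hit$query_id, transcript_id = hit$transcript_id,
      strand = hit$strand, start = ev$start, end = ev$end,
      mature_sequence = unname(queries[hit$query_id]),
      au_percent = round_half_away(au_percent(ev$precursor), 2L),
      gc_percent = round_half_away(st$GC, 2L),
      lp = st$LP, mfe = round_half_away(st$MFE, 2L),
      amfe = round_half_away(st$AMFE, 2L),
      mfei = round_half_away(st$MFEI, 2L),
      arm = st$arm, accepted = ev$report$accepted,
      failed = paste(failed_criteria(ev$report), collapse = ","),
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), transcript_id = character(),
               strand = character(), start = integer(), end = integer(),
               mature_sequence = character(), au_percent = numeric(),
               gc_percent = numeric(), lp = integer(), mfe = numeric(),
               amfe = numeric(), mfei = numeric(), arm = character(),
               accepted = logical(), failed = character(),
               stringsAsFactors = FALSE)
  rownames(candidates) <- NULL

  rejected <- candidates[!candidates$accepted, , drop = FALSE]
  acc <- candidates[candidates$accepted, , drop = FALSE]
  # one accepted precursor per locus: overlapping spans on one
  # transcript collapse to the best MFEI, then the leftmost start
  if (nrow(acc) > 1L) {
    acc <- acc[order(acc$transcript_id, acc$start, acc$end), , drop = FALSE]
    keep <- logical(0)
    for (tx in unique(acc$transcript_id)) {
      sub <- acc[acc$transcript_id == tx, , drop = FALSE]
      grp <- cumsum(c(TRUE, sub$start[-1L] > cummax(sub$end)[-nrow(sub)]))
      sel <- unlist(lapply(split(seq_len(nrow(sub)), grp), function(ix) {
        s <- sub[ix, , drop = FALSE]
        ix[order(s$mfei, s$start)][1L]
      }))
      keep <- c(keep, seq_len(nrow(sub)) %in% sel)
    }
    accepted <- acc[keep, , drop = FALSE]
  } else accepted <- acc
  rownames(accepted) <- NULL
  rownames(rejected) <- NULL

  clusters <- NULL
  if (!is.null(regions) && nrow(accepted)) {
    located <- data.frame(id = accepted$query_id,
                          reference = accepted$transcript_id,
                          start = accepted$start, end = accepted$end,
                          stringsAsFactors = FALSE)
    clusters <- detect_clusters(located, cfg$max_gap)
    clusters$region <- "unannotated"
    clusters$boundary <- FALSE
    for (ref in unique(clusters$reference)) {
      reg <- regions[regions$reference == ref, , drop = FALSE]
      if (!nrow(reg)) next
      ix <- clusters$reference == ref
      lab <- assign_region(clusters$start[ix], clusters$end[ix], reg)
      clusters$region[ix] <- lab$region
      clusters$boundary[ix] <- lab$boundary
    }
  }

  targets <- NULL
  if (cfg$run_targets && nrow(accepted)) {
    tg <- lapply(unique(accepted$query_id), function(q)
      scan_targets(queries[q], transcripts, cfg$target_cutoff))
    targets <- do.call(rbind, tg)
  }

  summary <- list(
    counts = list(queries = length(queries), skipped_queries = length(skipped),
                  transcripts = length(transcripts), hits = nrow(hits),
                  windows = nrow(hits), evaluated = nrow(candidates),
                  accepted_pre_dedup = nrow(acc),
                  accepted = nrow(accepted), rejected = nrow(rejected),
                  clusters = if (is.null(clusters)) 0L else
                    length(cluster_calls(clusters))),
    config = list(max_mismatches = cfg$search$max_mismatches,
                  flank = cfg$search$flank, trim = cfg$trim,
                  max_gap = cfg$max_gap,
                  max_mfei = cfg$criteria$max_mfei,
                  max_mfe = cfg$criteria$max_mfe),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("plantmir")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(candidates, "candidates.tsv")
    wt(accepted, "accepted.tsv")
    wt(rejected, "rejected.tsv")
    if (!is.null(clusters)) wt(clusters, "clusters.tsv")
    if (!is.null(targets)) wt(targets, "targets.tsv")
    cfg_json <- summary
    cfg_json$config$max_gap <- if (is.finite(cfg$max_gap))
      cfg$max_gap else "unlimited"
    jsonlite::write_json(cfg_json, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(summary = summary, candidates = candidates, accepted = accepted,
       rejected = rejected, clusters = clusters, targets = targets)
}
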