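# Seven-criterion precursor filter and the Table-2-style summary
# statistics (LP, GC%, MFE, AMFE, MFEI, arm).

#' Thresholds of the precursor filter
#'
#' The seven selection criteria for conserved plant miRNA precursors,
#' plus the mature-length and duplex-pair bounds that accompany them:
#' (len) precursor length 60-400 nt; (i) a single stem-loop; (ii) fewer
#' than `max_duplex_mismatches` unpaired mature positions and a defined
#' duplex; (iii) mature wholly on the 5p or 3p arm; (iv) MFEI at or
#' below `max_mfei`; (v) MFE at or below `max_mfe` kcal/mol; (vi) no
#' bulge longer than `max_bulge` nt and no internal-loop asymmetry above
#' `max_asymmetry` nt; (vii) G+C between `gc_min` and `gc_max` percent;
#' with at least `min_duplex_pairs` mature:star pairs and a mature of
#' 17-25 nt.
#'
#' `max_mfei` defaults to -0.49, the least-negative value accepted in
#' the published Papaver survey bundled with this package; much of the
#' literature uses -0.85, so it is configurable.  A "mismatch" is a
#' mature position with no pairing partner; G:U wobble counts as paired,
#' consistent with plant miRNA practice.
#'
#' @param min_mature_len,max_mature_len mature length bounds (nt).
#' @param max_duplex_mismatches mature positions without a partner;
#'   candidates must stay strictly below this.
#' @param min_duplex_pairs minimum paired mature positions.
#' @param max_mfe maximum (least negative) folding energy, kcal/mol.
#' @param max_mfei maximum (least negative) MFEI.
#' @param gc_min,gc_max G+C bounds, percent.
#' @param max_bulge longest tolerated unpaired run in the duplex (nt).
#' @param max_asymmetry largest tolerated internal-loop asymmetry (nt).
#' @param min_precursor_len,max_precursor_len precursor length bounds (nt).
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_mature_len = 17L, max_mature_len = 25L,
                            max_duplex_mismatches = 6L,
                            min_duplex_pairs = 16L,
                            max_mfe = -15, max_mfei = -0.49,
                            gc_min = 24, gc_max = 71,
                            max_bulge = 3L, max_asymmetry = 2L,
                            min_precursor_len = 60L,
                            max_precursor_len = 400L) {
  stopifnot(min_mature_len <= max_mature_len, gc_min < gc_max,
            min_precursor_len <= max_precursor_len,
            is.finite(max_mfe), is.finite(max_mfei))
  structure(as.list(environment()), class = "filter_criteria")
}

#' Adjusted minimal folding free energy (AMFE)
#'
#' Energy per 100 nt: `100 * mfe / lp`.
#' @param mfe folding energy, kcal/mol.
#' @param lp precursor length, nt (>= 1).
#' @return AMFE in kcal/mol/100nt; vectorized.
#' @export
compute_amfe <- function(mfe, lp) {
  if (any(lp < 1)) stop("compute_amfe: lp must be >= 1", call. = FALSE)
  100 * mfe / lp
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = AMFE / GC%` with `AMFE = 100 * MFE / LP`.  The MFEI
#' discriminates miRNA precursors from other RNA species: precursors
#' fold more stably per nucleotide than their base composition alone
#' would suggest.
#'
#' @param mfe folding energy, kcal/mol.
#' @param lp precursor length, nt (>= 1).
#' @param gc G+C content in percent (> 0).
#' @return the MFEI; vectorized.
#' @export
compute_mfei <- function(mfe, lp, gc) {
  if (any(lp < 1)) stop("compute_mfei: lp must be >= 1", call. = FALSE)
  if (any(gc <= 0)) stop("compute_mfei: undefined for GC <= 0", call. = FALSE)
  compute_amfe(mfe, lp) / gc
}

# reporting convention: round half away from zero
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Locate a mature sequence on a precursor
#'
#' Best (fewest mismatches, then leftmost) full-length window of the
#' precursor matching the mature.
#'
#' @param precursor,mature character scalars.
#' @param max_mismatches tolerance; exceeding it is a not-found error.
#' @return integer vector `c(start, end)`, 1-based closed, with
#'   attribute `mismatches`.
#' @export
locate_mature <- function(precursor, mature, max_mismatches = 2L) {
  qchars <- strsplit(unname(mature[1L]), "", fixed = TRUE)[[1L]]
  tchars <- strsplit(unname(precursor[1L]), "", fixed = TRUE)[[1L]]
  mm <- .window_mismatches(qchars, tchars)
  if (!length(mm) || min(mm) > max_mismatches)
    stop(sprintf("mature not found on precursor within %d mismatches",
                 max_mismatches), call. = FALSE)
  s <- which.min(mm)  # leftmost among fewest-mismatch windows
  structure(c(start = s, end = s + length(qchars) - 1L),
            mismatches = as.integer(mm[s]))
}

#' Extract the miRNA:miRNA* duplex geometry from a folded precursor
#'
#' The star span is the minimal contiguous interval containing all
#' partners of paired mature positions; mismatches are unpaired mature
#' positions; bulges and internal-loop asymmetries are computed from
#' maximal unpaired runs strictly between the first and last paired
#' mature position (and their partners).
#'
#' @param h a `hairpin`.
#' @param mature_span integer `c(start, end)` on the precursor.
#' @return list with `mature_span`, `star_span`, `paired_count`,
#'   `mismatches`, `bulges` (data.frame side/length) and `asymmetry`
#'   (one value per internal loop).  A mature that straddles the
#'   terminal loop, or with zero paired positions, is a duplex-undefined
#'   error (condition class `plantmir_duplex_undefined`).
#' @export
extract_duplex <- function(h, mature_span) {
  ms <- as.integer(mature_span[[1L]]); me <- as.integer(mature_span[[2L]])
  stopifnot(ms >= 1L, me <= nchar(h$seq), ms <= me)
  arm <- arm_of(h, mature_span)
  if (arm == "ambiguous")
    stop(structure(class = c("plantmir_duplex_undefined", "error", "condition"),
                   list(message = "duplex undefined: mature straddles the terminal loop or structure is not a stem-loop",
                        call = NULL)))
  partners <- h$pair_table[ms:me]
  paired <- which(!is.na(partners))
  if (!length(paired))
    stop(structure(class = c("plantmir_duplex_undefined", "error", "condition"),
                   list(message = "duplex undefined: no paired mature position",
                        call = NULL)))
  p <- (ms:me)[paired]              # paired mature positions, ascending
  q <- h$pair_table[p]              # their partners, descending
  star_span <- c(start = min(q), end = max(q))
  paired_count <- length(p)
  mismatches <- (me - ms + 1L) - paired_count
  sides <- character(0); lens <- integer(0); asym <- integer(0)
  if (length(p) > 1L) {
    for (t in seq_len(length(p) - 1L)) {
      a <- p[t + 1L] - p[t] - 1L    # unpaired mature nt in this loop
      b <- q[t] - q[t + 1L] - 1L    # unpaired star nt in this loop
      if (a > 0L) { sides <- c(sides, "mature"); lens <- c(lens, a) }
      if (b > 0L) { sides <- c(sides, "star");   lens <- c(lens, b) }
      if (a > 0L || b > 0L) asym <- c(asym, abs(a - b))
    }
  }
  list(mature_span = c(start = ms, end = me), star_span = star_span,
       paired_count = paired_count, mismatches = mismatches,
       bulges = data.frame(side = sides, length = lens,
                           stringsAsFactors = FALSE),
       asymmetry = asym, arm = arm)
}

#' Which arm of the hairpin carries the mature sequence?
#'
#' `"5p"` if the mature ends before the terminal loop starts, `"3p"` if
#' it begins after the loop ends, `"ambiguous"` otherwise (including
#' structures without exactly one hairpin loop).
#'
#' @param h a `hairpin`.
#' @param mature_span integer `c(start, end)` on the precursor.
#' @return one of `"5p"`, `"3p"`, `"ambiguous"`.
#' @export
arm_of <- function(h, mature_span) {
  loops <- hairpin_loops(h)
  if (nrow(loops) != 1L) return("ambiguous")
  ms <- mature_span[[1L]]; me <- mature_span[[2L]]
  if (me <= loops$lp) return("5p")
  if (ms >= loops$rp) return("3p")
  "ambiguous"
}

#' Evaluate a folded candidate against the full criterion set
#'
#' Failures are verdicts, not exceptions: the report carries one row per
#' criterion with the measured value and a pass flag, and `accepted` is
#' TRUE iff all criteria pass.  Summary statistics (LP, GC, MFE, AMFE,
#' MFEI, arm) are always populated.
#'
#' @param precursor named character scalar.
#' @param mature named character scalar.
#' @param h optional pre-computed `hairpin` for `precursor` (folded with
#'   `model` otherwise).
#' @param criteria a [filter_criteria()].
#' @param model a [fold_model()] (used when `h` is NULL).
#' @param max_locate_mismatches tolerance when locating the mature on
#'   the precursor.
#' @return an object of class `filter_report`.
#' @export
evaluate_candidate <- function(precursor, mature, h = NULL,
                               criteria = filter_criteria(),
                               model = fold_model(),
                               max_locate_mismatches = 2L) {
  s <- unname(precursor[1L])
  if (is.null(h)) h <- fold(precursor, model)
  stopifnot(identical(h$seq, s))
  lp <- nchar(s)
  gc <- gc_percent(s)
  mfe <- h$energy
  amfe <- compute_amfe(mfe, lp)
  mfei <- if (gc > 0) compute_mfei(mfe, lp, gc) else NA_real_

  mature_len <- nchar(unname(mature[1L]))
  span <- tryCatch(locate_mature(s, mature, max_locate_mismatches),
                   error = function(e) NULL)
  duplex <- NULL
  arm <- "ambiguous"
  if (!is.null(span)) {
    arm <- arm_of(h, span)
    duplex <- tryCatch(extract_duplex(h, span), error = function(e) NULL)
  }

  crit <- function(name, value, threshold, pass) {
    data.frame(criterion = name, value = value, threshold = threshold,
               pass = isTRUE(pass), stringsAsFactors = FALSE)
  }
  verdicts <- rbind(
    crit("length", lp,
         sprintf("[%d, %d]", criteria$min_precursor_len, criteria$max_precursor_len),
         lp >= criteria$min_precursor_len && lp <= criteria$max_precursor_len),
    crit("i_single_hairpin", as.numeric(is_single_hairpin(h)), "TRUE",
         is_single_hairpin(h)),
    crit("ii_duplex_mismatches",
         if (is.null(duplex)) NA_real_ else duplex$mismatches,
         sprintf("< %d", criteria$max_duplex_mismatches),
         !is.null(duplex) && duplex$mismatches < criteria$max_duplex_mismatches),
    crit("iii_arm", NA_real_, "5p or 3p", arm %in% c("5p", "3p")),
    crit("iv_mfei", mfei, sprintf("<= %.2f", criteria$max_mfei),
         !is.na(mfei) && mfei <= criteria$max_mfei),
    crit("v_mfe", mfe, sprintf("<= %.1f", criteria$max_mfe),
         mfe <= criteria$max_mfe),
    crit("vi_bulges",
         if (is.null(duplex)) NA_real_ else
           if (nrow(duplex$bulges)) max(duplex$bulges$length) else 0,
         sprintf("bulge <= %d, asymmetry <= %d",
                 criteria$max_bulge, criteria$max_asymmetry),
         !is.null(duplex) &&
           (!nrow(duplex$bulges) || max(duplex$bulges$length) <= criteria$max_bulge) &&
           (!length(duplex$asymmetry) || max(duplex$asymmetry) <= criteria$max_asymmetry)),
    crit("vii_gc", gc, sprintf("[%g, %g]", criteria$gc_min, criteria$gc_max),
         gc >= criteria$gc_min && gc <= criteria$gc_max),
    crit("duplex_pairs",
         if (is.null(duplex)) NA_real_ else duplex$paired_count,
         sprintf(">= %d", criteria$min_duplex_pairs),
         !is.null(duplex) && duplex$paired_count >= criteria$min_duplex_pairs),
    crit("mature_length", mature_len,
         sprintf("[%d, %d]", criteria$min_mature_len, criteria$max_mature_len),
         mature_len >= criteria$min_mature_len &&
           mature_len <= criteria$max_mature_len)
  )
  rownames(verdicts) <- NULL
  structure(list(
    accepted = all(verdicts$pass),
    verdicts = verdicts,
    stats = list(LP = lp, GC = gc, MFE = mfe, AMFE = amfe, MFEI = mfei,
                 arm = if (!is.null(span)) arm else "ambiguous"),
    duplex = duplex,
    mature_span = span
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s\n",
              if (x$accepted) "ACCEPTED" else "rejected"))
  cat(sprintf("  LP %d nt | GC %.2f%% | MFE %.2f | AMFE %.2f | MFEI %s | arm %s\n",
              x$stats$LP, x$stats$GC, x$stats$MFE, x$stats$AMFE,
              if (is.na(x$stats$MFEI)) "NA" else sprintf("%.2f", x$stats$MFEI),
              x$stats$arm))
  failed <- x$verdicts$criterion[!x$verdicts$pass]
  if (length(failed)) cat("  failed:", paste(failed, collapse = ", "), "\n")
  invisible(x)
}

#' Failed criteria of a filter report
#' @param report a `filter_report`.
#' @return character vector of failed criterion names.
#' @export
failed_criteria <- function(report) {
  report$verdicts$criterion[!report$verdicts$pass]
}

#' Bundled reference table of published Papaver miRNA precursors
#'
#' A 22-row survey of conserved miRNAs identified in opium poppy
#' (*Papaver somniferum*) and *P. bracteatum*, with the printed A+U%,
#' G+C%, precursor length (LP), minimal folding free energy (MFE) and
#' MFEI of each precursor, shipped as plain TSV in `extdata`.
#'
#' @return data.frame with columns `name`, `mature_sequence`,
#'   `p_somniferum`, `p_bracteatum`, `au_percent`, `gc_percent`, `lp`,
#'   `mfe`, `mfei`.
#' @export
papaver_mirna_table <- function() {
  path <- system.file("extdata", "papaver_mirna_table.tsv",
                      package = "plantmir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute MFEI for a published precursor table and flag inconsistencies
#'
#' Recomputes `AMFE = 100*MFE/LP` and `MFEI = AMFE/GC` from the printed
#' MFE, LP and G+C columns and flags rows whose printed MFEI does not
#' follow from its own columns (published tables mix rounding and
#' truncation, so agreement within 0.015 after 2-dp rounding counts as
#' consistent).  Inconsistent rows are flagged, never forced.
#'
#' @param table data.frame with columns `mfe`, `lp`, `gc_percent` and
#'   optionally `mfei` (defaults to the bundled table).
#' @param tol absolute tolerance on the 2-dp recomputed value.
#' @return the table with added columns `amfe`, `mfei_recomputed` (2 dp)
#'   and `mfei_consistent`.
#' @export
annotate_mfei <- function(table = papaver_mirna_table(), tol = 0.015) {
  stopifnot(all(c("mfe", "lp", "gc_percent") %in% names(table)))
  table$amfe <- compute_amfe(table$mfe, table$lp)
  table$mfei_recomputed <- round_half_away(
    compute_mfei(table$mfe, table$lp, table$gc_percent), 2L)
  table$mfei_consistent <- if ("mfei" %in% names(table))
    abs(table$mfei_recomputed - table$mfei) <= tol else NA
  table
}
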