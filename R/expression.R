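# Relative-quantification arithmetic for validation experiments:
# Livak 2^-ddCt for qRT-PCR and reference-normalized band densitometry
# for semi-quantitative RT-PCR.

#' Livak 2^-ddCt fold change
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,cal -
#' Ct_ref,cal)`; the fold change is `2^-ddCt`.  By construction the
#' calibrator maps to 1.  No efficiency correction (Pfaffl) is applied:
#' this is the plain Livak model.  Vectorized.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene
#'   in the sample of interest (cycles).
#' @param ct_target_cal,ct_ref_cal Ct of target and reference gene in
#'   the calibrator.
#' @return fold change(s), dimensionless and > 0.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_cal, ct_ref_cal) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_cal, ct_ref_cal)
  if (any(!is.finite(cts)))
    stop("ddct_fold_change: all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Reference-normalized relative band density
#'
#' `(d_target / d_ref) / (d_target_cal / d_ref_cal)`.  An undetected
#' target band (`d_target = 0`) yields 0; a zero reference or calibrator
#' density is a domain error.
#'
#' @param d_target,d_ref band densities in the sample.
#' @param d_target_cal,d_ref_cal band densities in the calibrator.
#' @return relative level(s); 0 flags an undetected band.
#' @export
band_relative <- function(d_target, d_ref, d_target_cal, d_ref_cal) {
  if (any(d_ref <= 0) || any(d_ref_cal <= 0) || any(d_target_cal <= 0))
    stop("band_relative: reference and calibrator densities must be > 0",
         call. = FALSE)
  if (any(d_target < 0))
    stop("band_relative: negative density", call. = FALSE)
  (d_target / d_ref) / (d_target_cal / d_ref_cal)
}

#' Relative expression across tissues from a Ct table
#'
#' Technical replicates are averaged on the Ct scale (standard Livak
#' practice) before the 2^-ddCt formula; the calibrator tissue is a
#' required input, never inferred, because published designs calibrate
#' on different tissues per experiment.
#'
#' @param ct data.frame with columns `gene`, `tissue`, `replicate`,
#'   `ct` (0 < ct < 60).
#' @param target_gene gene to quantify.
#' @param reference_gene internal-control gene (e.g. 5.8S rRNA).
#' @param calibrator tissue used as calibrator.
#' @return data.frame with columns `gene`, `tissue`, `relative_level`,
#'   `method` (`"ddct"`); the calibrator row is exactly 1.
#' @export
relative_expression <- function(ct, target_gene, reference_gene, calibrator) {
  stopifnot(all(c("gene", "tissue", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 60))
    stop("relative_expression: Ct values must lie in (0, 60)", call. = FALSE)
  mean_ct <- function(gene, tissue) {
    v <- ct$ct[ct$gene == gene & ct$tissue == tissue]
    if (!length(v))
      stop(sprintf("no Ct for gene '%s' in tissue '%s'", gene, tissue),
           call. = FALSE)
    mean(v)
  }
  tissues <- unique(ct$tissue[ct$gene == target_gene])
  if (!calibrator %in% tissues)
    stop(sprintf("calibrator tissue '%s' absent for gene '%s'",
                 calibrator, target_gene), call. = FALSE)
  tcal <- mean_ct(target_gene, calibrator)
  rcal <- mean_ct(reference_gene, calibrator)
  out <- data.frame(
    gene = target_gene, tissue = tissues,
    relative_level = vapply(tissues, function(ti)
      ddct_fold_change(mean_ct(target_gene, ti), mean_ct(reference_gene, ti),
                       tcal, rcal), numeric(1)),
    method = "ddct", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a Ct / density table from CSV
#' @param path CSV with columns gene, tissue, replicate, ct (or density).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an expression table as TSV
#' @param expr data.frame from [relative_expression()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
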