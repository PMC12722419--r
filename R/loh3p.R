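# Chromosome-3p LOH calling from the 74-locus B-allele / read-depth panel.
#
# Copy loss shows consistent mirrored B-allele frequencies near the
# purity-attenuated expectation 1/(2 - TP) together with a depressed log
# fold-change read depth versus the panel of normals; copy-neutral isodisomy
# shows the BAF shift with lfc near 0; retention shows BAF near 0.5.  The
# study adjudicated these plots by hand with 0-3 confidence scores; here the
# thresholds are explicit and the confidence score is computed from the
# dispersion (MAD) of the per-locus summaries.

#' Thresholds for the LOH3p caller
#'
#' @param baf_tolerance How far below the expected LOH mirrored BAF
#'   (`1/(2 - TP)` when purity is supplied) the calling threshold sits.
#' @param fixed_baf_threshold Mirrored-BAF threshold used when no purity is
#'   supplied.
#' @param lfc_margin Half-width of the "approximately 0" lfc band separating
#'   isodisomy from copy loss.
#' @param min_depth Minimum total depth for a locus to enter the summaries.
#' @param min_loci Minimum number of informative loci for a non-zero
#'   confidence call.
#' @param mad_baf_bounds,mad_lfc_bounds Decreasing dispersion bounds for
#'   confidence 3, 2, 1 (a sample must satisfy both at a level, and the
#'   locus-count bound, to reach it).
#' @param n_loci_bounds Minimum informative-locus counts for confidence
#'   3, 2, 1.
#' @return List of class `loh3p_thresholds`.
#' @export
loh3p_thresholds <- function(baf_tolerance = 0.08,
                             fixed_baf_threshold = 0.62,
                             lfc_margin = 0.15,
                             min_depth = 30,
                             min_loci = 10,
                             mad_baf_bounds = c(0.04, 0.08, 0.15),
                             mad_lfc_bounds = c(0.30, 0.50, 0.90),
                             n_loci_bounds = c(30, 15, 5)) {
  stopifnot(baf_tolerance > 0, lfc_margin > 0, min_depth >= 1,
            min_loci >= 1,
            all(diff(mad_baf_bounds) > 0), all(diff(mad_lfc_bounds) > 0),
            all(diff(n_loci_bounds) < 0))
  structure(list(baf_tolerance = baf_tolerance,
                 fixed_baf_threshold = fixed_baf_threshold,
                 lfc_margin = lfc_margin, min_depth = min_depth,
                 min_loci = min_loci, mad_baf_bounds = mad_baf_bounds,
                 mad_lfc_bounds = mad_lfc_bounds,
                 n_loci_bounds = n_loci_bounds),
            class = "loh3p_thresholds")
}

#' Per-locus mirrored B-allele frequency and depth log fold-change
#'
#' For each panel locus computes `baf = alt/(alt+ref)`, the mirrored BAF
#' `max(baf, 1-baf)` and `lfc = log2(total depth / normals reference depth)`.
#' Loci below `min_depth` or flagged uninformative (germline homozygous) are
#' marked unusable for the call summaries but retained in the output.
#'
#' @param panel Data frame for one sample: `locus_id`, `ref_count`,
#'   `alt_count`, `normals_depth`, `informative` (logical; assumed all
#'   informative when absent).
#' @param min_depth Minimum total depth for a usable locus.
#' @return Data frame with `locus_id`, `baf`, `mirrored_baf`, `lfc`,
#'   `informative`, `usable`.
#' @examples
#' p <- data.frame(locus_id = "L1", ref_count = 50, alt_count = 50,
#'                 normals_depth = 100, informative = TRUE)
#' compute_baf_lfc(p)  # mirrored_baf 0.5, lfc 0
#' @export
compute_baf_lfc <- function(panel, min_depth = 30) {
  total <- panel$ref_count + panel$alt_count
  baf <- ifelse(total > 0, panel$alt_count / total, NA_real_)
  informative <- if ("informative" %in% names(panel)) panel$informative
  else rep(TRUE, nrow(panel))
  data.frame(locus_id = panel$locus_id,
             baf = baf,
             mirrored_baf = pmax(baf, 1 - baf),
             lfc = log2(total / panel$normals_depth),
             informative = informative,
             usable = informative & total >= min_depth & is.finite(baf),
             stringsAsFactors = FALSE)
}

#' Confidence score (0-3) for an LOH3p call
#'
#' Maps the dispersion of the usable per-locus summaries to the study's
#' very-low/low/medium/high scale: a score is awarded at the highest level
#' whose MAD(mirrored BAF), MAD(lfc) and informative-locus-count bounds are
#' all met, so injected noise can never raise the score and more loci or
#' depth can never lower it on average.  Scores of 2 or 3 mark the call
#' usable for downstream analyses.
#'
#' @param per_locus Output of [compute_baf_lfc()].
#' @param thresholds A [loh3p_thresholds()] object.
#' @return Integer 0, 1, 2 or 3.
#' @export
score_confidence <- function(per_locus, thresholds = loh3p_thresholds()) {
  u <- per_locus[per_locus$usable, , drop = FALSE]
  n <- nrow(u)
  if (n < thresholds$min_loci) return(0L)
  mb <- stats::mad(u$mirrored_baf)
  ml <- stats::mad(u$lfc)
  for (lvl in 1:3) {
    if (mb <= thresholds$mad_baf_bounds[lvl] &&
        ml <= thresholds$mad_lfc_bounds[lvl] &&
        n >= thresholds$n_loci_bounds[lvl])
      return(4L - lvl)
  }
  1L
}

#' Call chromosome-3p status for one sample
#'
#' Summarises the usable loci by median mirrored BAF and median lfc, then:
#' loss when the BAF median reaches the threshold and the lfc median is
#' below `-lfc_margin`; isodisomy when the BAF median reaches the threshold
#' with `|median lfc| <= lfc_margin`; retention otherwise.  When tumor
#' purity is supplied, the BAF threshold is the purity-aware expectation
#' `1/(2 - TP) - baf_tolerance` (normal-cell admixture bounds the observed
#' BAF below 1, so the literal 100% reading would miss LOH at realistic
#' purity); otherwise a fixed threshold is used.
#'
#' @param panel Panel data frame for one sample (see [compute_baf_lfc()]).
#' @param tp Tumor purity in (0, 1], or `NULL`/`NA` for the fixed threshold.
#' @param thresholds A [loh3p_thresholds()] object.
#' @return Object of class `loh3p_call`: `sample_id`, `status`
#'   (`"retention"`, `"loss"`, `"isodisomy"`), `confidence` (0-3),
#'   `median_mirrored_baf`, `median_lfc`, `n_informative`, `usable`
#'   (confidence >= 2), `baf_threshold`.
#' @export
call_loh3p <- function(panel, tp = NULL, thresholds = loh3p_thresholds()) {
  sid <- if ("sample_id" %in% names(panel) && nrow(panel) > 0)
    panel$sample_id[1] else NA_character_
  pl <- compute_baf_lfc(panel, thresholds$min_depth)
  u <- pl[pl$usable, , drop = FALSE]
  conf <- score_confidence(pl, thresholds)

  baf_thr <- if (!is.null(tp) && length(tp) == 1 && !is.na(tp)) {
    stopifnot(tp > 0, tp <= 1)
    1 / (2 - tp) - thresholds$baf_tolerance
  } else thresholds$fixed_baf_threshold

  if (nrow(u) == 0) {
    out <- list(sample_id = sid, status = "retention", confidence = 0L,
                median_mirrored_baf = NA_real_, median_lfc = NA_real_,
                n_informative = 0L, usable = FALSE, baf_threshold = baf_thr)
    class(out) <- "loh3p_call"
    return(out)
  }

  mb <- stats::median(u$mirrored_baf)
  ml <- stats::median(u$lfc)
  status <- if (mb >= baf_thr) {
    if (ml < -thresholds$lfc_margin) "loss"
    else if (abs(ml) <= thresholds$lfc_margin) "isodisomy"
    else "retention"   # BAF shift with depth gain: not a 3p-loss pattern
  } else "retention"

  out <- list(sample_id = sid, status = status, confidence = conf,
              median_mirrored_baf = mb, median_lfc = ml,
              n_informative = nrow(u), usable = conf >= 2L,
              baf_threshold = baf_thr)
  class(out) <- "loh3p_call"
  out
}

#' @export
print.loh3p_call <- function(x, ...) {
  cat(sprintf(
    "Sample %s: 3p %s (confidence %d%s)\n  median mirrored BAF %.3f, median lfc %+.3f, %d informative loci\n",
    x$sample_id, x$status, x$confidence,
    if (x$usable) ", usable" else "", x$median_mirrored_baf,
    x$median_lfc, x$n_informative))
  invisible(x)
}

#' Call LOH3p across a cohort panel table
#'
#' @param panel Long panel data frame for many samples (as produced by
#'   [simulate_cohort()]).
#' @param purity Optional data frame with `sample_id` and `tp` used for the
#'   purity-aware BAF threshold.
#' @param thresholds A [loh3p_thresholds()] object.
#' @return Data frame with one row per sample: the fields of
#'   [call_loh3p()].
#' @export
call_loh3p_cohort <- function(panel, purity = NULL,
                              thresholds = loh3p_thresholds()) {
  ids <- unique(panel$sample_id)
  rows <- lapply(ids, function(sid) {
    tp <- if (!is.null(purity)) purity$tp[match(sid, purity$sample_id)]
    else NULL
    cl <- call_loh3p(panel[panel$sample_id == sid, , drop = FALSE], tp,
                     thresholds)
    data.frame(sample_id = cl$sample_id, status = cl$status,
               confidence = cl$confidence,
               median_mirrored_baf = cl$median_mirrored_baf,
               median_lfc = cl$median_lfc,
               n_informative = cl$n_informative, usable = cl$usable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
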