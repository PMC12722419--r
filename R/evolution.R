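# Evolutionary-state classifiers and cohort reports: small-tumor flagging,
# small-vs-large contrasts, Class-transition states from the discriminant
# score, oncoprint tables and per-case timelines.

#' Flag small tumors
#'
#' A tumor is "small" when thickness <= 2.5 mm AND diameter <= 12 mm
#' (boundaries inclusive), the size stratum in which most uveal melanomas
#' are sampled early in their genetic evolution.
#'
#' @param thickness_mm,diameter_mm Positive tumor dimensions (vectorised).
#' @return Logical vector.
#' @examples
#' flag_small_tumor(2.5, 12)   # TRUE (inclusive boundary)
#' flag_small_tumor(1.0, 12.1) # FALSE (conjunction)
#' @export
flag_small_tumor <- function(thickness_mm, diameter_mm) {
  if (any(thickness_mm <= 0) || any(diameter_mm <= 0))
    stop("tumor dimensions must be positive", call. = FALSE)
  thickness_mm <= 2.5 & diameter_mm <= 12
}

#' Small-versus-larger tumor contrasts
#'
#' Contrasts the small-tumor stratum against the remainder: categorical
#' features (GEP class, PRAME, BAP1 mutation, any BSE mutation) through the
#' chi-square/Fisher switching rule; continuous features (purity when
#' available, discriminant score within each class) through the rank-sum
#' test.  The direction of each contrast is reported as the difference of
#' small-group minus large-group proportions or means.
#'
#' @param cohort Cohort data frame with `thickness_mm`, `diameter_mm`,
#'   `gep_class`, `prame`, `mut_BAP1`, `mut_SF3B1`, `mut_EIF1AX`, `dscore`,
#'   optionally `purity`.
#' @return Data frame: `feature`, `test_used`, `p_value`, `direction`
#'   (small minus large), `untestable`.
#' @export
small_vs_large_contrast <- function(cohort) {
  small <- flag_small_tumor(cohort$thickness_mm, cohort$diameter_mm)
  if (all(small) || !any(small))
    stop("both size strata must be non-empty", call. = FALSE)
  rows <- list()
  add <- function(feature, test_used, p, direction, untestable = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      feature = feature, test_used = test_used, p_value = p,
      direction = direction, untestable = untestable,
      stringsAsFactors = FALSE)
  }
  cat_feat <- list(
    class1 = cohort$gep_class == "Class1",
    prame_negative = cohort$prame == "negative",
    bap1_mutant = cohort$mut_BAP1,
    any_bse = cohort$mut_BAP1 | cohort$mut_SF3B1 | cohort$mut_EIF1AX)
  for (nm in names(cat_feat)) {
    x <- cat_feat[[nm]]
    if (length(unique(x)) < 2) {
      add(nm, NA_character_, NA_real_, NA_real_, untestable = TRUE)
      next
    }
    res <- categorical_test(table(small, x))
    add(nm, res$test_used, res$p_value,
        mean(x[small]) - mean(x[!small]))
  }
  cont <- list()
  if ("purity" %in% names(cohort)) cont$purity <- cohort$purity
  for (nm in names(cont)) {
    x <- cont[[nm]]
    wt <- stats::wilcox.test(x ~ small, exact = FALSE)
    add(nm, "wilcoxon", wt$p.value, mean(x[small], na.rm = TRUE) -
          mean(x[!small], na.rm = TRUE))
  }
  for (cl in c("Class1", "Class2")) {
    sel <- cohort$gep_class == cl
    if (length(unique(small[sel])) < 2) {
      add(paste0("dscore_", cl), NA_character_, NA_real_, NA_real_, TRUE)
      next
    }
    wt <- stats::wilcox.test(cohort$dscore[sel] ~ small[sel], exact = FALSE)
    add(paste0("dscore_", cl), "wilcoxon", wt$p.value,
        mean(cohort$dscore[sel & small]) - mean(cohort$dscore[sel & !small]))
  }
  do.call(rbind, rows)
}

#' Classify the Class-1 to Class-2 transition state of a tumor
#'
#' A low discriminant score on either side of the SVM decision boundary
#' marks a tumor potentially in transition between the two expression
#' states.  Rules: Class 1 with dscore below the threshold and evidence of
#' BAP1 pathway involvement (BAP1 mutation or LOH3p) -> `transitional_class1`;
#' Class 2 with dscore below the threshold -> `transitional_class2`;
#' otherwise `stable_class1` / `established_class2`.  Each triggered rule is
#' recorded in `rationale` (including `subclonal_bap1` when the supplied
#' CCF is below 0.5).
#'
#' @param gep_class `"Class1"` or `"Class2"`.
#' @param dscore Discriminant score in [0, 1] (absolute distance to the
#'   boundary); `NA` is unclassifiable.
#' @param bap1_mutant Logical: a BAP1 mutation detected.
#' @param loh3p Logical: a usable LOH3p call of loss or isodisomy.
#' @param ccf_bap1 BAP1 cancer cell fraction, or `NA`.
#' @param threshold Transition threshold on the dscore scale (default 0.2).
#' @return List of class `evolution_state`: `transition_state`, `rationale`.
#' @examples
#' classify_transition("Class1", 0.9, FALSE, FALSE)$transition_state
#' classify_transition("Class2", 0.02, TRUE, TRUE, 0.9)$transition_state
#' @export
classify_transition <- function(gep_class, dscore, bap1_mutant = FALSE,
                                loh3p = FALSE, ccf_bap1 = NA_real_,
                                threshold = 0.2) {
  if (is.na(dscore)) stop("missing dscore: unclassifiable", call. = FALSE)
  stopifnot(gep_class %in% c("Class1", "Class2"),
            dscore >= 0, dscore <= 1)
  rationale <- character(0)
  low <- dscore < threshold
  if (low) rationale <- c(rationale,
                          sprintf("low_dscore(%.3g<%.3g)", dscore, threshold))
  bap1_path <- isTRUE(bap1_mutant) || isTRUE(loh3p)
  if (isTRUE(bap1_mutant)) rationale <- c(rationale, "bap1_mutation")
  if (isTRUE(loh3p)) rationale <- c(rationale, "loh3p")
  if (!is.na(ccf_bap1) && ccf_bap1 < 0.5)
    rationale <- c(rationale, sprintf("subclonal_bap1(ccf=%.2f)", ccf_bap1))
  state <- if (gep_class == "Class1") {
    if (low && bap1_path) "transitional_class1" else "stable_class1"
  } else {
    if (low) "transitional_class2" else "established_class2"
  }
  structure(list(transition_state = state, gep_class = gep_class,
                 dscore = dscore, threshold = threshold,
                 rationale = rationale),
            class = "evolution_state")
}

#' @export
print.evolution_state <- function(x, ...) {
  cat(sprintf("%s (dscore %.3g, threshold %.3g)\n", x$transition_state,
              x$dscore, x$threshold))
  if (length(x$rationale))
    cat("  rules fired:", paste(x$rationale, collapse = ", "), "\n")
  invisible(x)
}

#' Oncoprint table with mutual-exclusivity summary
#'
#' One row per sample with the seven driver-mutation flags, class, PRAME,
#' size and outcome columns, deterministically ordered by class, then BSE
#' mutation pattern, then decreasing discriminant score.  Counts of samples
#' carrying two Gq or two or more BSE mutations are emitted alongside.
#'
#' @param cohort Cohort data frame (as from [simulate_cohort()]).
#' @return List of class `oncoprint`: `table` (ordered data frame),
#'   `co_occurrence` (list with `multi_gq_samples`, `multi_bse_samples`).
#' @export
build_oncoprint <- function(cohort) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  mg <- paste0("mut_", GQ_GENES)
  mb <- paste0("mut_", BSE_GENES)
  n_gq <- rowSums(cohort[, mg, drop = FALSE])
  n_bse <- rowSums(cohort[, mb, drop = FALSE])
  bse_pattern <- apply(cohort[, mb, drop = FALSE], 1, function(r)
    paste(BSE_GENES[as.logical(r)], collapse = "+"))
  ord <- order(cohort$gep_class, bse_pattern, -cohort$dscore,
               cohort$sample_id)
  tab <- cohort[ord, c("sample_id", mg, mb, "gep_class", "prame",
                       "thickness_mm", "diameter_mm", "dscore",
                       intersect(c("mfs_months", "mfs_event", "os_months",
                                   "os_event"), names(cohort)))]
  tab$bse_pattern <- bse_pattern[ord]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 co_occurrence = list(
                   multi_gq_samples = cohort$sample_id[n_gq >= 2],
                   multi_bse_samples = cohort$sample_id[n_bse >= 2])),
            class = "oncoprint")
}

#' @export
print.oncoprint <- function(x, ...) {
  cat(sprintf("Oncoprint: %d samples (%d with 2 Gq mutations, %d with >=2 BSE)\n",
              nrow(x$table), length(x$co_occurrence$multi_gq_samples),
              length(x$co_occurrence$multi_bse_samples)))
  invisible(x)
}

#' Per-case evolution timeline
#'
#' Orders the inferred events for one tumor -- Gq founder mutation, BSE
#' mutations labelled near-clonal (CCF >= 0.5) or sub-clonal, LOH3p, class
#' and discriminant score, outcome -- into a structured summary suitable for
#' serialisation or plotting.  Samples without a Gq mutation are excluded
#' with an explicit reason (the cohort inclusion criterion).
#'
#' @param sample One-row cohort data frame (or list) with `sample_id`,
#'   `gep_class`, `dscore`, `diameter_mm` and outcome columns.
#' @param clonality Rows of [estimate_clonality()] for this sample.
#' @param loh_call One row of [call_loh3p_cohort()] for this sample, or
#'   `NULL`.
#' @return List of class `case_timeline`: `sample_id`, `events` (ordered
#'   character descriptions), `excluded`, `partial`.
#' @export
case_timeline <- function(sample, clonality, loh_call = NULL) {
  sid <- sample$sample_id
  events <- character(0)
  partial <- FALSE
  if (is.null(clonality) || nrow(clonality) == 0 ||
      !any(clonality$tp_estimable)) {
    return(structure(list(sample_id = sid, events = character(0),
                          excluded = TRUE,
                          reason = "no Gq founder mutation (inclusion criterion)",
                          partial = TRUE),
                     class = "case_timeline"))
  }
  events <- c(events, sprintf("Gq founder mutation (TP %.2f)",
                              clonality$tp[1]))
  bse <- clonality[!is.na(clonality$gene), , drop = FALSE]
  bse <- bse[order(-ifelse(is.na(bse$ccf), -1, bse$ccf)), , drop = FALSE]
  for (j in seq_len(nrow(bse))) {
    if (is.na(bse$ccf[j])) {
      events <- c(events, sprintf("%s mutation (CCF undefined)", bse$gene[j]))
      partial <- TRUE
    } else {
      lab <- if (bse$ccf[j] >= 0.5) "near-clonal" else "sub-clonal"
      events <- c(events, sprintf("%s %s mutation (CCF %.2f)", bse$gene[j],
                                  lab, bse$ccf[j]))
    }
  }
  if (!is.null(loh_call) && loh_call$status %in% c("loss", "isodisomy") &&
      loh_call$confidence >= 2)
    events <- c(events, sprintf("LOH3p (%s, confidence %d)",
                                loh_call$status, loh_call$confidence))
  events <- c(events, sprintf("15-GEP %s, discriminant score %.2f",
                              sample$gep_class, sample$dscore))
  if (!is.null(sample$mfs_event))
    events <- c(events, if (isTRUE(sample$mfs_event))
      sprintf("metastasis at %.1f months", sample$mfs_months)
      else sprintf("no metastasis at %.1f months follow-up",
                   sample$mfs_months))
  structure(list(sample_id = sid, events = events, excluded = FALSE,
                 partial = partial),
            class = "case_timeline")
}

#' @export
print.case_timeline <- function(x, ...) {
  cat(sprintf("Case %s%s\n", x$sample_id,
              if (x$excluded) paste0(" [excluded: ", x$reason, "]") else ""))
  for (e in x$events) cat("  ->", e, "\n")
  invisible(x)
}
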