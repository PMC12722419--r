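# Tumor purity and cancer cell fraction estimation.
#
# The founder Gq mutation is assumed clonal and heterozygous, hence present
# at 50% VAF in tumor cells: TP = min(2 x VAF_Gq, 1).  BSE VAFs are divided
# by TP and converted to CCF under gene-specific allelic models.

# deterministic tie-break order for the max-VAF Gq selection
GQ_TIEBREAK <- c("GNAQ", "GNA11", "PLCB4", "CYSLTR2")

#' Estimate tumor purity from the founder Gq mutation
#'
#' Among the sample's Gq-gene variants (GNAQ, GNA11, PLCB4, CYSLTR2) the one
#' with the highest VAF -- presumed the earliest initiating mutation -- is
#' selected, and purity is `min(2 * VAF, 1)`.  Samples without a Gq variant
#' get `estimable = FALSE` with an undefined purity (such samples are
#' excluded from purity-corrected analyses rather than erroring).
#'
#' @param variants Data frame of variant calls for one sample, with columns
#'   `gene`, `ref_count`, `alt_count` and optionally `pathogenic` (when
#'   present, only pathogenic Gq variants are considered).
#' @return List of class `purity_estimate`: `sample_id`, `tp`, `source_gene`,
#'   `source_vaf`, `capped`, `estimable`.
#' @examples
#' v <- data.frame(sample_id = "s1", gene = "GNAQ",
#'                 ref_count = 75, alt_count = 25)
#' estimate_purity(v)$tp  # 0.5
#' @export
estimate_purity <- function(variants) {
  sid <- if ("sample_id" %in% names(variants) && nrow(variants) > 0)
    variants$sample_id[1] else NA_character_
  if (length(unique(variants$sample_id)) > 1)
    stop("estimate_purity expects variants from a single sample",
         call. = FALSE)
  gq <- variants[variants$gene %in% GQ_GENES, , drop = FALSE]
  if ("pathogenic" %in% names(gq))
    gq <- gq[!is.na(gq$pathogenic) & gq$pathogenic, , drop = FALSE]
  if (nrow(gq) == 0) {
    return(structure(list(sample_id = sid, tp = NA_real_,
                          source_gene = NA_character_, source_vaf = NA_real_,
                          capped = NA, estimable = FALSE),
                     class = "purity_estimate"))
  }
  vaf <- gq$alt_count / (gq$alt_count + gq$ref_count)
  ord <- order(-vaf, match(gq$gene, GQ_TIEBREAK))
  best <- ord[1]
  structure(list(sample_id = sid,
                 tp = min(2 * vaf[best], 1),
                 source_gene = gq$gene[best],
                 source_vaf = vaf[best],
                 capped = 2 * vaf[best] > 1,
                 estimable = TRUE),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("Sample %s: purity not estimable (no Gq mutation)\n",
                x$sample_id))
  } else {
    cat(sprintf("Sample %s: TP = %.3f from %s (VAF %.3f)%s\n", x$sample_id,
                x$tp, x$source_gene, x$source_vaf,
                if (x$capped) " [capped at 1]" else ""))
  }
  invisible(x)
}

#' Purity-correct a BSE variant allele frequency
#'
#' `corrected VAF = VAF / TP`, left uncapped; values above 1 indicate a
#' purity/VAF inconsistency and are flagged downstream rather than silently
#' truncated.
#'
#' @param vaf_bse Raw VAF of the BSE mutation, in [0, 1].
#' @param tp Tumor purity in (0, 1], or `NA` when not estimable (returns
#'   `NA`: the sample cannot be corrected and is excluded from CCF
#'   analyses).
#' @return Corrected VAF (may exceed 1), or `NA_real_`.
#' @export
correct_vaf <- function(vaf_bse, tp) {
  if (is.na(tp)) return(NA_real_)
  if (tp <= 0 || tp > 1) stop("tp must be in (0, 1]", call. = FALSE)
  stopifnot(vaf_bse >= 0, vaf_bse <= 1)
  vaf_bse / tp
}

#' Cancer cell fraction of a BSE mutation under its allelic model
#'
#' Gene-specific models:
#' \itemize{
#'   \item SF3B1 (chromosome 2, copy-stable): heterozygous,
#'     `CCF = min(2 * corrected VAF, 1)`.
#'   \item EIF1AX (X chromosome): females heterozygous (`min(2cv, 1)`),
#'     males hemizygous (`min(cv, 1)`).
#'   \item BAP1 (3p21): with 3p retention, heterozygous (`min(2cv, 1)`);
#'     with a usable LOH3p call (loss or isodisomy, confidence >= 2),
#'     hemizygous (`min(cv, 1)`), LOH assumed at ~100% CCF; with no usable
#'     call the CCF is undefined and flagged.
#' }
#'
#' @param gene `"BAP1"`, `"SF3B1"` or `"EIF1AX"`.
#' @param corrected_vaf Purity-corrected VAF from [correct_vaf()] (>= 0,
#'   may exceed 1).
#' @param sex `"female"` or `"male"` (used for EIF1AX only).
#' @param loh3p A [call_loh3p()] result (or list with `status` and
#'   `confidence`/`usable`), or `NULL`; required for BAP1.
#' @return List of class `ccf_estimate`: `gene`, `corrected_vaf`, `ccf`,
#'   `allelic_model`, `inconsistent` (pre-cap value exceeded 1), `defined`.
#' @examples
#' estimate_ccf("SF3B1", 0.45)$ccf  # 0.9
#' estimate_ccf("EIF1AX", 0.8, sex = "male")$ccf  # 0.8
#' @export
estimate_ccf <- function(gene, corrected_vaf, sex = c("female", "male"),
                         loh3p = NULL) {
  if (!gene %in% BSE_GENES)
    stop("gene must be one of BAP1, SF3B1, EIF1AX", call. = FALSE)
  sex <- match.arg(sex)
  out <- list(gene = gene, corrected_vaf = corrected_vaf, ccf = NA_real_,
              allelic_model = NA_character_, inconsistent = FALSE,
              defined = FALSE)
  class(out) <- "ccf_estimate"
  if (is.na(corrected_vaf)) return(out)
  stopifnot(corrected_vaf >= 0)

  mult_model <- switch(gene,
    SF3B1 = list(2, "het_autosome"),
    EIF1AX = if (sex == "male") list(1, "x_male") else list(2, "x_female"),
    BAP1 = {
      usable <- !is.null(loh3p) &&
        (isTRUE(loh3p$usable) ||
           (!is.null(loh3p$confidence) && loh3p$confidence >= 2))
      if (!usable) NULL
      else if (loh3p$status %in% c("loss", "isodisomy")) list(1, "bap1_loh")
      else list(2, "bap1_retention")
    })
  if (is.null(mult_model)) return(out)   # BAP1 without a usable LOH3p call

  mult <- mult_model[[1]]
  out$allelic_model <- mult_model[[2]]
  out$inconsistent <- corrected_vaf * mult > 1
  out$ccf <- min(corrected_vaf * mult, 1)
  out$defined <- TRUE
  out
}

#' @export
print.ccf_estimate <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("%s: CCF undefined (corrected VAF %s)\n", x$gene,
                format(x$corrected_vaf)))
  } else {
    cat(sprintf("%s: CCF = %.3f (%s%s)\n", x$gene, x$ccf, x$allelic_model,
                if (x$inconsistent) ", flagged inconsistent" else ""))
  }
  invisible(x)
}

#' Per-sample clonality estimation across a cohort
#'
#' Runs [estimate_purity()], [correct_vaf()] and [estimate_ccf()] for every
#' sample: purity from the max-VAF Gq mutation, then corrected VAF and CCF
#' for each BSE mutation present, using the sample's sex (for EIF1AX) and
#' LOH3p call (for BAP1).
#'
#' @param variants Variant-call data frame (multiple samples) with `gene`,
#'   `ref_count`, `alt_count`, `sample_id`.
#' @param clinical Data frame with `sample_id` and `sex`.
#' @param loh_calls Optional data frame from [call_loh3p_cohort()] with
#'   `sample_id`, `status`, `confidence`.
#' @return Data frame, one row per (sample, BSE gene) plus purity columns:
#'   `sample_id`, `tp`, `tp_capped`, `tp_estimable`, `gene`, `raw_vaf`,
#'   `corrected_vaf`, `ccf`, `allelic_model`, `inconsistent`.  Samples with
#'   no BSE mutation contribute a single row with `gene = NA`.
#' @export
estimate_clonality <- function(variants, clinical, loh_calls = NULL) {
  ids <- unique(variants$sample_id)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sid <- ids[k]
    v <- variants[variants$sample_id == sid, , drop = FALSE]
    pe <- estimate_purity(v)
    sex <- clinical$sex[match(sid, clinical$sample_id)]
    loh <- NULL
    if (!is.null(loh_calls) && sid %in% loh_calls$sample_id) {
      lr <- loh_calls[loh_calls$sample_id == sid, , drop = FALSE][1, ]
      loh <- list(status = lr$status, confidence = lr$confidence)
    }
    bse <- v[v$gene %in% BSE_GENES, , drop = FALSE]
    mk <- function(gene, raw, cv, ce) {
      data.frame(sample_id = sid, tp = if (pe$estimable) pe$tp else NA_real_,
                 tp_capped = isTRUE(pe$capped), tp_estimable = pe$estimable,
                 gene = gene, raw_vaf = raw, corrected_vaf = cv,
                 ccf = ce$ccf, allelic_model = ce$allelic_model,
                 inconsistent = ce$inconsistent, stringsAsFactors = FALSE)
    }
    if (nrow(bse) == 0) {
      ce0 <- list(ccf = NA_real_, allelic_model = NA_character_,
                  inconsistent = FALSE)
      rows[[k]] <- mk(NA_character_, NA_real_, NA_real_, ce0)
    } else {
      sub <- vector("list", nrow(bse))
      for (j in seq_len(nrow(bse))) {
        raw <- bse$alt_count[j] / (bse$alt_count[j] + bse$ref_count[j])
        cv <- if (pe$estimable) correct_vaf(raw, pe$tp) else NA_real_
        ce <- estimate_ccf(bse$gene[j], cv,
                           sex = if (is.na(sex)) "female" else sex,
                           loh3p = loh)
        sub[[j]] <- mk(bse$gene[j], raw, cv, ce)
      }
      rows[[k]] <- do.call(rbind, sub)
    }
  }
  do.call(rbind, rows)
}
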