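# Variant-type taxonomy and pathogenicity rule engine over precomputed
# annotation scores (SpliceAI, SIFT, PolyPhen2, ClinVar).  The package never
# runs these predictors; their scores arrive as input fields.

VARIANT_TYPES <- c("nonsense", "stop_loss", "start_loss", "frameshift_indel",
                   "nonframeshift_indel", "block_substitution", "splice_site",
                   "missense")

SPLICE_EFFECTS <- c("acceptor_loss", "acceptor_gain", "donor_loss",
                    "donor_gain")

#' Classify a variant into the driver-panel taxonomy
#'
#' Exactly one of: nonsense (premature stop introduced), stop_loss,
#' start_loss, frameshift_indel (length change not a multiple of 3),
#' nonframeshift_indel, block_substitution (multiple sequential codons
#' altered), splice_site (within the canonical splice window), missense.
#' Splice-window membership takes precedence; indels are classified by
#' length arithmetic; substitutions need codon context (translated reference
#' and alternate amino acids) to separate nonsense/stop-loss/start-loss from
#' missense.
#'
#' @param ref_allele,alt_allele Nucleotide strings (non-empty).
#' @param codon_context List with `ref_aa` and `alt_aa` (single-letter amino
#'   acids, `"*"` for stop), optional `is_start_codon` flag, optional
#'   `codons_affected` (count, for multi-base substitutions), optional
#'   `splice_distance` (bp to the nearest exon/intron boundary).
#' @param splice_window Half-width of the canonical splice window in bp
#'   (default 2: the +/-2 donor/acceptor dinucleotides).
#' @return One of the eight variant-type strings.
#' @examples
#' classify_variant_type("C", "T", list(ref_aa = "Q", alt_aa = "*")) # nonsense
#' classify_variant_type("CAT", "C", list())   # frameshift_indel
#' @export
classify_variant_type <- function(ref_allele, alt_allele,
                                  codon_context = list(),
                                  splice_window = 2) {
  if (!nzchar(ref_allele) || !nzchar(alt_allele))
    stop("ref/alt alleles must be non-empty", call. = FALSE)
  sd <- codon_context$splice_distance
  if (!is.null(sd) && !is.na(sd) && abs(sd) <= splice_window)
    return("splice_site")

  len_diff <- nchar(alt_allele) - nchar(ref_allele)
  if (len_diff != 0L)
    return(if (len_diff %% 3L != 0L) "frameshift_indel"
           else "nonframeshift_indel")

  # same-length substitution
  n_codons <- codon_context$codons_affected
  if (nchar(ref_allele) > 1L) {
    if (is.null(n_codons)) n_codons <- ceiling(nchar(ref_allele) / 3)
    if (n_codons >= 2L) return("block_substitution")
  }
  ref_aa <- codon_context$ref_aa
  alt_aa <- codon_context$alt_aa
  if (is.null(ref_aa) || is.null(alt_aa))
    stop("codon context (ref_aa/alt_aa) required to classify a substitution",
         call. = FALSE)
  if (isTRUE(codon_context$is_start_codon) && ref_aa == "M" && alt_aa != "M")
    return("start_loss")
  if (alt_aa == "*" && ref_aa != "*") return("nonsense")
  if (ref_aa == "*" && alt_aa != "*") return("stop_loss")
  "missense"
}

#' Pathogenicity call from variant type and annotation scores
#'
#' The rules, applied in order:
#' \itemize{
#'   \item nonsense, stop-loss, start-loss, frameshift and non-frameshift
#'     indels, and block substitutions are pathogenic by type
#'     (`basis = "type_rule"`);
#'   \item splice-site alterations are pathogenic iff SpliceAI >= 0.5 with a
#'     predicted acceptor/donor loss or gain (`basis = "splice_ai"`);
#'   \item missense variants are pathogenic iff reported pathogenic in
#'     ClinVar, or SIFT <= 0.05, or PolyPhen2 >= 0.5 (evaluated in that
#'     order for basis attribution; all thresholds inclusive).
#' }
#' A missense variant with no annotation at all -- or a splice-site variant
#' with no SpliceAI score -- is *indeterminate* (`pathogenic = NA`), a state
#' distinct from not-pathogenic.
#'
#' @param variant_type One of the taxonomy strings from
#'   [classify_variant_type()].
#' @param splice_ai SpliceAI score in [0, 1] or `NA`.
#' @param splice_effect One of `"acceptor_loss"`, `"acceptor_gain"`,
#'   `"donor_loss"`, `"donor_gain"`, `"none"`, or `NA`.
#' @param clinvar_pathogenic Logical flag or `NA`.
#' @param sift SIFT score in [0, 1] or `NA` (low = deleterious).
#' @param polyphen2 PolyPhen2 score in [0, 1] or `NA` (high = damaging).
#' @return List: `pathogenic` (TRUE/FALSE/NA), `basis` (`"type_rule"`,
#'   `"splice_ai"`, `"clinvar"`, `"sift"`, `"polyphen2"` or `"none"`),
#'   `indeterminate`.
#' @examples
#' call_pathogenic("nonsense")                       # pathogenic, type_rule
#' call_pathogenic("splice_site", splice_ai = 0.4,
#'                 splice_effect = "donor_loss")     # not pathogenic
#' call_pathogenic("missense", sift = 0.05)          # pathogenic, sift
#' @export
call_pathogenic <- function(variant_type, splice_ai = NA_real_,
                            splice_effect = NA_character_,
                            clinvar_pathogenic = NA, sift = NA_real_,
                            polyphen2 = NA_real_) {
  variant_type <- match.arg(variant_type, VARIANT_TYPES)
  res <- function(p, b, ind = FALSE)
    list(pathogenic = p, basis = b, indeterminate = ind)

  if (variant_type %in% c("nonsense", "stop_loss", "start_loss",
                          "frameshift_indel", "nonframeshift_indel",
                          "block_substitution"))
    return(res(TRUE, "type_rule"))

  if (variant_type == "splice_site") {
    if (is.na(splice_ai)) return(res(NA, "none", ind = TRUE))
    hit <- splice_ai >= 0.5 && !is.na(splice_effect) &&
      splice_effect %in% SPLICE_EFFECTS
    return(if (hit) res(TRUE, "splice_ai") else res(FALSE, "none"))
  }

  # missense
  if (is.na(clinvar_pathogenic) && is.na(sift) && is.na(polyphen2))
    return(res(NA, "none", ind = TRUE))
  if (isTRUE(clinvar_pathogenic)) return(res(TRUE, "clinvar"))
  if (!is.na(sift) && sift <= 0.05) return(res(TRUE, "sift"))
  if (!is.na(polyphen2) && polyphen2 >= 0.5) return(res(TRUE, "polyphen2"))
  res(FALSE, "none")
}

#' Classify and call pathogenicity for a variant table
#'
#' Convenience wrapper over [call_pathogenic()] for a data frame of variant
#' calls whose `variant_type` is already known (e.g. simulated calls or an
#' annotated VCF import).
#'
#' @param variants Data frame with `variant_type` plus annotation columns
#'   `splice_ai`, `splice_effect`, `clinvar_pathogenic`, `sift`,
#'   `polyphen2` (missing columns treated as all-`NA`).
#' @return The input with `pathogenic`, `pathogenicity_basis` and
#'   `indeterminate` columns appended.
#' @export
annotate_pathogenicity <- function(variants) {
  get <- function(col, default) {
    if (col %in% names(variants)) variants[[col]]
    else rep(default, nrow(variants))
  }
  sai <- get("splice_ai", NA_real_)
  sef <- get("splice_effect", NA_character_)
  clv <- get("clinvar_pathogenic", NA)
  sift <- get("sift", NA_real_)
  pp2 <- get("polyphen2", NA_real_)
  out <- lapply(seq_len(nrow(variants)), function(i)
    call_pathogenic(variants$variant_type[i], sai[i], sef[i], clv[i],
                    sift[i], pp2[i]))
  variants$pathogenic <- vapply(out, `[[`, logical(1), "pathogenic")
  variants$pathogenicity_basis <- vapply(out, `[[`, character(1), "basis")
  variants$indeterminate <- vapply(out, `[[`, logical(1), "indeterminate")
  variants
}

#' Exclude complex BAP1 alterations
#'
#' Partitions BAP1 variants into those kept and those excluded because they
#' alter >= 5 nucleotides (complex alterations cannot be matched reliably to
#' the saturation-genome-editing table).  The nucleotide-change count is the
#' edit distance between reference and alternate alleles.
#'
#' @param variants Data frame of BAP1 variants with `ref_allele`,
#'   `alt_allele`.
#' @param max_changes Variants with at least this many changed nucleotides
#'   are excluded (default 5).
#' @return List with `kept` and `excluded` data frames (input order
#'   preserved; `kept` plus `excluded` is exactly the input).
#' @export
filter_complex_bap1 <- function(variants, max_changes = 5) {
  if (nrow(variants) == 0)
    return(list(kept = variants, excluded = variants))
  nch <- mapply(function(r, a) utils::adist(r, a)[1, 1],
                variants$ref_allele, variants$alt_allele)
  complex_ <- nch >= max_changes
  list(kept = variants[!complex_, , drop = FALSE],
       excluded = variants[complex_, , drop = FALSE])
}

#' Join variants to a saturation-genome-editing (SGE) functional table
#'
#' Matches on hg38 start position, reference allele(s) and mutant allele(s).
#' Variants still on hg19 are refused (silent cross-assembly joins produce
#' wrong matches); liftover is external to this package.
#'
#' @param variants Data frame with `pos`, `ref_allele`, `alt_allele` and an
#'   `assembly` column that must be `"hg38"` throughout.
#' @param sge_table Data frame with `pos`, `ref_allele`, `alt_allele`,
#'   `functional_class` (`"depleted"`/`"not_depleted"`), `functional_score`.
#' @return The variants with `functional_class`, `functional_score` and
#'   `unmapped` columns appended.
#' @export
join_sge <- function(variants, sge_table) {
  if (!"assembly" %in% names(variants) ||
      any(variants$assembly != "hg38"))
    stop("SGE join requires hg38 coordinates; refusing hg19/untagged input",
         call. = FALSE)
  key <- function(df) paste(df$pos, df$ref_allele, df$alt_allele, sep = ":")
  idx <- match(key(variants), key(sge_table))
  variants$functional_class <- sge_table$functional_class[idx]
  variants$functional_score <- sge_table$functional_score[idx]
  variants$unmapped <- is.na(idx)
  variants
}

#' Compare SGE functional classification and scores between GEP classes
#'
#' Two-tailed Fisher's exact test on the 2x2 depleted/not-depleted by
#' Class 1/Class 2 table, and a two-tailed rank-sum test on the functional
#' scores.
#'
#' @param annotated Output of [join_sge()] restricted to mapped variants,
#'   with `functional_class` and `functional_score`.
#' @param class_labels Character vector (`"Class1"`/`"Class2"`) aligned with
#'   `annotated` rows.
#' @return List with `fisher_p`, `wilcoxon_p` and the 2x2 `table`.
#' @export
compare_functional_by_class <- function(annotated, class_labels) {
  stopifnot(nrow(annotated) == length(class_labels))
  keep <- !annotated$unmapped
  annotated <- annotated[keep, , drop = FALSE]
  class_labels <- class_labels[keep]
  if (!all(c("Class1", "Class2") %in% class_labels))
    stop("each class needs at least one annotated variant", call. = FALSE)
  tab <- table(factor(annotated$functional_class,
                      levels = c("depleted", "not_depleted")),
               factor(class_labels, levels = c("Class1", "Class2")))
  fp <- stats::fisher.test(tab)$p.value
  wp <- stats::wilcox.test(functional_score ~ factor(class_labels),
                           data = annotated, exact = FALSE)$p.value
  list(fisher_p = fp, wilcoxon_p = wp, table = tab)
}
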