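# Plain-text I/O: TSV export of simulated cohorts and results, and VCF
# ingestion of variant calls with annotation scores in INFO keys.

#' Write a simulated cohort to TSV files
#'
#' Writes `cohort.tsv`, `variants.tsv`, `panel.tsv` and `truth.tsv` into a
#' directory.
#'
#' @param sim An `um_cohort` object from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "um_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("cohort", "variants", "panel", "truth")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(sim[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a variant table from TSV
#'
#' @param path TSV with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `assembly`, `ref_allele`, `alt_allele`, `ref_count`, `alt_count` and
#'   optional annotation columns.
#' @return Data frame of variant calls.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ref_count", "alt_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant TSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read variant calls from a VCF file
#'
#' Ingests a (multi-)sample VCF using the `vcfR` package: per-sample alt and
#' ref counts from the `AD` FORMAT field (or `DP` minus alt), and annotation
#' scores from INFO keys (names configurable).  One row per
#' variant-by-sample with non-missing genotype.
#'
#' @param path VCF file.
#' @param info_keys Named character vector mapping package annotation fields
#'   to INFO keys, default `c(splice_ai = "SPLICEAI", sift = "SIFT",
#'   polyphen2 = "POLYPHEN2", gene = "GENE")`.
#' @param assembly Assembly tag recorded on the imported rows.
#' @return Data frame in the package's variant-call layout.
#' @export
read_variants_vcf <- function(path,
                              info_keys = c(splice_ai = "SPLICEAI",
                                            sift = "SIFT",
                                            polyphen2 = "POLYPHEN2",
                                            gene = "GENE"),
                              assembly = "hg19") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  get_info <- function(key) {
    if (is.na(key)) return(rep(NA_character_, nrow(fix)))
    vcfR::extract.info(v, element = key)
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(ad)
  rows <- list()
  for (s in samples) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    ref_c <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 1) p[1] else NA_character_, character(1))))
    alt_c <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, character(1))))
    keep <- !is.na(ref_c) & !is.na(alt_c)
    if (!any(keep)) next
    rows[[s]] <- data.frame(
      sample_id = s,
      gene = get_info(info_keys[["gene"]])[keep],
      chrom = fix$CHROM[keep],
      pos = as.integer(fix$POS[keep]),
      assembly = assembly,
      ref_allele = fix$REF[keep], alt_allele = fix$ALT[keep],
      ref_count = ref_c[keep], alt_count = alt_c[keep],
      splice_ai = suppressWarnings(
        as.numeric(get_info(info_keys[["splice_ai"]])[keep])),
      sift = suppressWarnings(
        as.numeric(get_info(info_keys[["sift"]])[keep])),
      polyphen2 = suppressWarnings(
        as.numeric(get_info(info_keys[["polyphen2"]])[keep])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a 3p panel table from TSV
#'
#' @param path TSV with columns `sample_id`, `locus_id`, `chrom`, `pos`,
#'   `ref_count`, `alt_count`, `normals_depth` and optional `informative`.
#' @return Data frame sorted by sample and position.
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "locus_id", "ref_count", "alt_count",
            "normals_depth")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel TSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("pos" %in% names(df)) df <- df[order(df$sample_id, df$pos), ]
  df
}
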