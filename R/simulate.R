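# Synthetic cohort generator: read-level data with retained ground truth.

# Representative hg19 coordinates for the seven driver genes (hotspot region
# for Gq genes; a mid-gene coding position for BSE genes).
DRIVER_LOCI <- data.frame(
  gene  = c("GNAQ", "GNA11", "PLCB4", "CYSLTR2", "BAP1", "SF3B1", "EIF1AX"),
  chrom = c("chr9", "chr19", "chr20", "chr13", "chr3", "chr2", "chrX"),
  pos   = c(80409488L, 3118942L, 9389496L, 49281112L,
            52436624L, 198266834L, 20159906L),
  stringsAsFactors = FALSE
)

GQ_HOTSPOTS <- c(GNAQ = "Q209P", GNA11 = "Q209L",
                 PLCB4 = "D630N", CYSLTR2 = "S154N")

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Expected variant allele frequency under the two read models
#'
#' The `paper_consistent` model is the generative inverse of the CCF
#' estimator's arithmetic: expected VAF = purity*CCF/2 at heterozygous
#' autosomal (and female X) loci, purity*CCF at hemizygous loci (male X, or
#' BAP1 after 3p loss/isodisomy).  The `copy_aware` model mixes allele pools
#' explicitly: VAF = purity*CCF*copies_mut / (purity*copies_tumor +
#' (1-purity)*copies_normal), which at a copy-loss locus dilutes the mutant
#' fraction by the normal diploid DNA (p/(2-p) for a clonal mutation at
#' purity p) -- the bias the paper-consistent estimator cannot see.
#' Male X loci are hemizygous in both tumor and normal cells, so the two
#' models agree there.
#'
#' @param purity Tumor purity, fraction in (0, 1].
#' @param ccf Cancer cell fraction of the mutation, in [0, 1].
#' @param context One of `"het_autosome"` (also female X), `"loss"` (mutant
#'   on the single retained 3p homolog), `"isodisomy"` (mutant duplicated,
#'   copy-neutral), `"x_male"`.
#' @param read_model `"paper_consistent"` or `"copy_aware"`.
#' @return Expected VAF (fraction).
#' @examples
#' expected_vaf(1, 1, "het_autosome")               # 0.5
#' expected_vaf(0.8, 1, "loss", "copy_aware")       # 0.8/1.2 = 0.667
#' expected_vaf(0.8, 1, "loss", "paper_consistent") # 0.8
#' @export
expected_vaf <- function(purity, ccf,
                         context = c("het_autosome", "loss", "isodisomy",
                                     "x_male"),
                         read_model = c("paper_consistent", "copy_aware")) {
  context <- match.arg(context)
  read_model <- match.arg(read_model)
  stopifnot(purity >= 0, purity <= 1, ccf >= 0, ccf <= 1)
  if (read_model == "paper_consistent") {
    return(switch(context,
                  het_autosome = purity * ccf / 2,
                  loss = ,
                  isodisomy = ,
                  x_male = purity * ccf))
  }
  # copy_aware: allele-pool mixing
  cp <- switch(context,
               het_autosome = c(mut = 1, tumor = 2, normal = 2),
               loss         = c(mut = 1, tumor = 1, normal = 2),
               isodisomy    = c(mut = 2, tumor = 2, normal = 2),
               x_male       = c(mut = 1, tumor = 1, normal = 1))
  purity * ccf * cp[["mut"]] /
    (purity * cp[["tumor"]] + (1 - purity) * cp[["normal"]])
}

#' Simulate binomial read counts for one driver variant
#'
#' Draws a sequencing depth around `depth` with multiplicative log-normal
#' noise and an alt-read count Binomial(depth, expected VAF), using
#' [expected_vaf()] for the given allelic context and read model.  Uses the
#' current R random-number stream.
#'
#' @inheritParams expected_vaf
#' @param depth Mean total depth (> 0).
#' @param depth_noise_sdlog sdlog of the multiplicative depth noise.
#' @return List with `ref_count`, `alt_count`, `depth`, `expected_vaf`.
#' @export
simulate_variant_reads <- function(purity, ccf, context, depth,
                                   read_model = c("paper_consistent",
                                                  "copy_aware"),
                                   depth_noise_sdlog = 0.15) {
  if (!is.numeric(depth) || depth <= 0)
    stop("depth must be > 0", call. = FALSE)
  ev <- expected_vaf(purity, ccf, context, read_model)
  d <- max(1L, as.integer(round(depth * stats::rlnorm(1, 0, depth_noise_sdlog))))
  alt <- stats::rbinom(1, d, ev)
  list(ref_count = d - alt, alt_count = alt, depth = d, expected_vaf = ev)
}

#' Simulate the 74-locus chromosome-3p copy-number panel for one tumor
#'
#' Per informative (germline heterozygous) locus the expected B-allele
#' frequency follows allele-pool mixing for the tumor's true 3p state:
#' 0.5 under retention; mirrored 1/(2-purity) under copy loss (one homolog
#' retained, normal diploid DNA dilutes); mirrored (1+purity)/2 under
#' copy-neutral isodisomy (the duplicated homolog contributes two copies).
#' Which germline allele sits on the affected homolog is random per locus.
#' Total depth is scaled by (2-purity)/2 under loss and unscaled otherwise,
#' with multiplicative log-normal noise; uninformative loci are homozygous
#' with only sequencing-error alt reads.
#'
#' @param truth One row of the truth table from [simulate_cohort()], or any
#'   list with `sample_id`, `true_purity`, `true_3p_state`.
#' @param config A [sim_config()] object.
#' @return Data frame with one row per locus: `sample_id`, `locus_id`,
#'   `chrom`, `pos`, `ref_count`, `alt_count`, `normals_depth`,
#'   `informative`.
#' @export
simulate_cnv_panel <- function(truth, config) {
  n <- config$n_panel_loci
  state <- truth$true_3p_state
  p <- truth$true_purity
  pos <- sort(round(seq(1.2e6, 8.7e7, length.out = n)))
  informative <- stats::runif(n) > config$het_dropout
  normals_depth <- config$depth_panel * stats::rlnorm(n, 0, 0.03)
  ratio <- if (state == "loss") (2 - p) / 2 else 1
  depth <- pmax(1L, as.integer(round(
    normals_depth * ratio * stats::rlnorm(n, 0, config$depth_noise_sdlog))))

  q <- switch(state,
              retention = 0.5,
              loss = 1 / (2 - p),
              isodisomy = (1 + p) / 2)
  # random per-locus phase: affected homolog carries ref or alt allele
  exp_alt <- ifelse(stats::runif(n) < 0.5, q, 1 - q)
  err <- 0.003
  exp_alt[!informative] <- ifelse(stats::runif(sum(!informative)) < 0.5,
                                  err, 1 - err)
  alt <- stats::rbinom(n, depth, exp_alt)
  data.frame(sample_id = truth$sample_id,
             locus_id = sprintf("L%02d", seq_len(n)),
             chrom = "chr3", pos = pos,
             ref_count = depth - alt, alt_count = alt,
             normals_depth = normals_depth,
             informative = informative,
             stringsAsFactors = FALSE)
}

# Latent discriminant-score process.  dosage_deficit in [0,1] is the fraction
# of functional BAP1 alleles lost; months is time since the first BAP1 hit
# (NA when BAP1 is intact).  The latent score z sits on the Class 1 side when
# negative; noise is resampled (capped) so the sign matches the tumor's
# class, with a deterministic reflection fallback.
sim_dscore <- function(class2, dosage_deficit, months, dm) {
  sat <- if (is.na(months)) 0 else months / (months + dm$tau_months)
  z_det <- -1 + dm$slope * dosage_deficit * sat
  z <- z_det + stats::rnorm(1, 0, dm$noise_sd)
  tries <- 0L
  while (((z > 0) != class2) && tries < 50L) {
    z <- z_det + stats::rnorm(1, 0, dm$noise_sd)
    tries <- tries + 1L
  }
  if ((z > 0) != class2) {
    # deterministic-side state contradicts the class: place the tumor just
    # on its class side of the boundary (a transitional score)
    m <- abs(stats::rnorm(1, 0, dm$noise_sd)) + 1e-3
    z <- if (class2) m else -m
  }
  z
}

sample_variant_row <- function(sample_id, gene, protein_change, variant_type,
                               purity, ccf, context, config) {
  loc <- DRIVER_LOCI[DRIVER_LOCI$gene == gene, ]
  alleles <- switch(variant_type,
                    missense = c("C", "A"),
                    nonsense = c("C", "T"),
                    frameshift_indel = c("CA", "C"),
                    nonframeshift_indel = c("C", "CTTA"),
                    splice_site = c("G", "A"),
                    block_substitution = c("CTG", "AGA"),
                    c("C", "A"))
  reads <- simulate_variant_reads(purity, ccf, context, config$depth_variant,
                                  config$read_model,
                                  config$depth_noise_sdlog)
  # Annotation scores consistent with a pathogenic call of the drawn type
  splice_ai <- if (variant_type == "splice_site") stats::runif(1, 0.6, 1) else NA_real_
  splice_effect <- if (variant_type == "splice_site") "donor_loss" else NA_character_
  sift <- if (variant_type == "missense") stats::runif(1, 0, 0.05) else NA_real_
  polyphen2 <- if (variant_type == "missense") stats::runif(1, 0.5, 1) else NA_real_
  clinvar <- if (variant_type == "missense" && gene %in% GQ_GENES) TRUE else NA
  data.frame(sample_id = sample_id, gene = gene, chrom = loc$chrom,
             pos = loc$pos, assembly = "hg19",
             ref_allele = alleles[1], alt_allele = alleles[2],
             protein_change = protein_change,
             ref_count = reads$ref_count, alt_count = reads$alt_count,
             splice_ai = splice_ai, splice_effect = splice_effect,
             sift = sift, polyphen2 = polyphen2,
             clinvar_pathogenic = clinvar,
             stringsAsFactors = FALSE)
}

BSE_TYPE_PROBS <- c(nonsense = 0.25, frameshift_indel = 0.30,
                    splice_site = 0.15, missense = 0.20,
                    nonframeshift_indel = 0.05, block_substitution = 0.05)

#' Simulate a uveal melanoma cohort with retained ground truth
#'
#' Generates a complete synthetic cohort under a [sim_config()]: clinical
#' table (size, sex, class, PRAME, discriminant score, survival), per-sample
#' driver variant calls with binomial read counts, the 74-locus 3p panel,
#' and a truth table with the generative purity, per-gene CCFs, 3p state and
#' latent discriminant-score variables, for estimator-recovery testing.
#'
#' Every tumor carries at least one Gq founder mutation at CCF 1 (the cohort
#' inclusion criterion); a rare second Gq mutation and a rare second BSE
#' mutation reproduce the observed near mutual exclusivity.  Class labels
#' are Bernoulli(`class1_fraction`); BAP1 mutation and LOH3p are sampled
#' conditional on class so that biallelic BAP1 loss is concentrated in
#' Class 2, and the discriminant score follows the latent inversion process
#' (see [sim_config()]).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `um_cohort`: a list with data frames
#'   `cohort` (one row per sample), `variants`, `panel` and `truth`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 20, seed = 1))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be a sim_config object", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_patients
  empty <- function(df) df[0, , drop = FALSE]
  if (n == 0L) {
    out <- list(
      cohort = data.frame(sample_id = character()),
      variants = data.frame(sample_id = character()),
      panel = data.frame(sample_id = character()),
      truth = data.frame(sample_id = character()))
    class(out) <- "um_cohort"
    return(out)
  }

  sm <- config$size_model
  pm <- config$purity_model
  mp <- config$mutation_prevalences
  dm <- config$dscore_model
  lm_ <- config$loh_model

  sample_id <- sprintf("S%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.518, "male", "female")
  age <- rtrunc_norm(n, 63, 13, 18, 99)

  # tumor size stratum, then class conditional on it: small tumors are
  # enriched for Class 1 (odds ratio small_class1_odds_ratio), with the
  # large-tumor probability solved so the cohort-wide Class 1 fraction is
  # exactly class1_fraction
  small <- stats::runif(n) < sm$small_fraction
  c1 <- config$class1_fraction
  f <- sm$small_fraction
  p_small <- if (c1 %in% c(0, 1)) c1 else {
    odds <- c1 / (1 - c1) * config$small_class1_odds_ratio
    odds / (1 + odds)
  }
  p_large <- if (f < 1) min(1, max(0, (c1 - f * p_small) / (1 - f))) else c1
  # keep the mixture exact when the large-arm clamp bites
  if (f > 0 && f < 1) p_small <- (c1 - (1 - f) * p_large) / f
  class1 <- stats::runif(n) < ifelse(small, p_small, p_large)
  gep_class <- ifelse(class1, "Class1", "Class2")
  prame <- ifelse(stats::runif(n) < ifelse(class1, 0.18, 0.60),
                  "positive", "negative")
  thickness <- numeric(n); diameter <- numeric(n)
  ns <- sum(small)
  thickness[small] <- stats::runif(ns, sm$small_thick[1], sm$small_thick[2])
  diameter[small] <- stats::runif(ns, sm$small_diam[1], sm$small_diam[2])
  nl <- sum(!small)
  if (nl > 0) {
    lt <- rtrunc_norm(nl, sm$large_thick_mean, sm$large_thick_sd,
                      sm$thick_range[1], sm$thick_range[2])
    ld <- rtrunc_norm(nl, sm$large_diam_mean, sm$large_diam_sd,
                      sm$diam_range[1], sm$diam_range[2])
    # a "larger" tumor must exceed at least one small-tumor bound
    redo <- lt <= sm$small_thick[2] & ld <= sm$small_diam[2]
    while (any(redo)) {
      k <- sum(redo)
      lt[redo] <- rtrunc_norm(k, sm$large_thick_mean, sm$large_thick_sd,
                              sm$thick_range[1], sm$thick_range[2])
      ld[redo] <- rtrunc_norm(k, sm$large_diam_mean, sm$large_diam_sd,
                              sm$diam_range[1], sm$diam_range[2])
      redo <- lt <= sm$small_thick[2] & ld <= sm$small_diam[2]
    }
    thickness[!small] <- lt
    diameter[!small] <- ld
  }
  ciliary_body <- stats::runif(n) < ifelse(small, 0.05, 0.19)

  purity <- ifelse(small,
                   rtrunc_norm(n, pm$small_mean, pm$small_sd,
                               pm$bounds[1], pm$bounds[2]),
                   rtrunc_norm(n, pm$large_mean, pm$large_sd,
                               pm$bounds[1], pm$bounds[2]))

  # Gq founder mutations (CCF 1, heterozygous)
  gq_p <- mp$gq / sum(mp$gq)
  gq_primary <- sample(names(gq_p), n, replace = TRUE, prob = gq_p)
  has_second_gq <- stats::runif(n) < mp$second_gq

  # BSE mutation assignment, class-conditional, near mutually exclusive
  bse_gene <- character(n)
  for (i in seq_len(n)) {
    pr <- mp$bse[[gep_class[i]]]
    bse_gene[i] <- sample(names(pr), 1, prob = pr)
  }
  second_bse <- character(n)
  add2 <- bse_gene != "none" & stats::runif(n) < mp$second_bse
  for (i in which(add2))
    second_bse[i] <- sample(setdiff(BSE_GENES, bse_gene[i]), 1)

  has_bap1 <- bse_gene == "BAP1" | second_bse == "BAP1"

  # 3p state: loss predominantly with BAP1 inactivation / Class 2
  p_loh <- ifelse(!class1 & has_bap1, lm_$p_loh_class2_bap1,
           ifelse(!class1, lm_$p_loh_class2_wt,
           ifelse(has_bap1, lm_$p_loh_class1_bap1, 0)))
  loh <- stats::runif(n) < p_loh
  iso <- loh & stats::runif(n) < lm_$isodisomy_fraction
  true_3p <- ifelse(!loh, "retention", ifelse(iso, "isodisomy", "loss"))

  # BSE CCFs
  draw_ccf <- function(gene, cls) {
    if (gene == "BAP1") {
      if (cls == "Class2") stats::runif(1, 0.7, 1) else stats::runif(1, 0.2, 0.8)
    } else stats::rbeta(1, 5, 2)   # near-clonal-heavy
  }
  ccf_bap1 <- ccf_sf3b1 <- ccf_eif1ax <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (g in c(bse_gene[i], second_bse[i])) {
      if (g == "" || g == "none") next
      cc <- draw_ccf(g, gep_class[i])
      if (g == "BAP1") ccf_bap1[i] <- cc
      else if (g == "SF3B1") ccf_sf3b1[i] <- cc
      else ccf_eif1ax[i] <- cc
    }
  }

  # BAP1 dosage deficit and time since first hit, driving the d-score;
  # Class 2 tumors without a detectable mutation or LOH carry a cryptic hit
  bap1_inactivated <- has_bap1 | loh | !class1
  months_since_loss <- ifelse(bap1_inactivated,
                              pmax(0, stats::rnorm(n, 2.2 * diameter - 8, 5)),
                              NA_real_)
  # Class 2 tumors without a detectable BAP1 mutation carry a cryptic hit
  mut_dose <- ifelse(has_bap1, ccf_bap1, ifelse(!class1, 0.85, 0))
  deficit <- pmin(1, (mut_dose + as.numeric(loh)) / 2)
  z <- vapply(seq_len(n), function(i)
    sim_dscore(!class1[i], deficit[i], months_since_loss[i], dm), numeric(1))
  dscore <- pmin(abs(z), 1)

  # survival (exponential, administrative censoring)
  sv <- config$survival_model
  lin <- function(coef) coef[["class2"]] * as.numeric(!class1) +
    coef[["prame_pos"]] * as.numeric(prame == "positive") +
    coef[["diameter"]] * diameter
  mfs_rate <- sv$mfs_base_rate * exp(lin(sv$mfs_coef) -
                                       sv$mfs_coef[["diameter"]] * 12.6)
  os_rate <- sv$os_base_rate * exp(lin(sv$os_coef) -
                                     sv$os_coef[["diameter"]] * 12.6)
  t_mfs <- stats::rexp(n, mfs_rate)
  t_os <- stats::rexp(n, os_rate)
  hz <- config$censoring_months
  mfs_event <- t_mfs <= pmin(t_os, hz)
  mfs_months <- pmin(t_mfs, t_os, hz)
  os_event <- t_os <= hz
  os_months <- pmin(t_os, hz)

  cohort <- data.frame(
    sample_id = sample_id, sex = sex, age_at_entry = round(age, 1),
    thickness_mm = round(thickness, 2), diameter_mm = round(diameter, 2),
    ciliary_body = ciliary_body, gep_class = gep_class, prame = prame,
    dscore = dscore,
    mut_GNAQ = gq_primary == "GNAQ", mut_GNA11 = gq_primary == "GNA11",
    mut_PLCB4 = gq_primary == "PLCB4", mut_CYSLTR2 = gq_primary == "CYSLTR2",
    mut_BAP1 = has_bap1,
    mut_SF3B1 = bse_gene == "SF3B1" | second_bse == "SF3B1",
    mut_EIF1AX = bse_gene == "EIF1AX" | second_bse == "EIF1AX",
    mfs_months = mfs_months, mfs_event = mfs_event,
    os_months = os_months, os_event = os_event,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = sample_id, true_purity = purity,
    true_ccf_BAP1 = ccf_bap1, true_ccf_SF3B1 = ccf_sf3b1,
    true_ccf_EIF1AX = ccf_eif1ax,
    true_3p_state = true_3p, true_class = gep_class,
    true_dscore = dscore, months_since_bap1_loss = months_since_loss,
    stringsAsFactors = FALSE)

  # read-level variant calls
  variants <- vector("list", n)
  panel <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- list()
    hot <- GQ_HOTSPOTS[[gq_primary[i]]]
    rows[[1]] <- sample_variant_row(sample_id[i], gq_primary[i], hot,
                                    "missense", purity[i], 1,
                                    "het_autosome", config)
    if (has_second_gq[i]) {
      g2 <- sample(setdiff(GQ_GENES, gq_primary[i]), 1)
      rows[[length(rows) + 1]] <- sample_variant_row(
        sample_id[i], g2, "rare", "missense", purity[i],
        stats::runif(1, 0.3, 1), "het_autosome", config)
    }
    add_bse <- function(g, ccf) {
      vt <- sample(names(BSE_TYPE_PROBS), 1, prob = BSE_TYPE_PROBS)
      ctx <- if (g == "BAP1" && true_3p[i] != "retention") {
        if (true_3p[i] == "loss") "loss" else "isodisomy"
      } else if (g == "EIF1AX" && sex[i] == "male") "x_male"
      else "het_autosome"
      sample_variant_row(sample_id[i], g, NA_character_, vt,
                         purity[i], ccf, ctx, config)
    }
    if (!is.na(ccf_bap1[i]) && has_bap1[i])
      rows[[length(rows) + 1]] <- add_bse("BAP1", ccf_bap1[i])
    if (!is.na(ccf_sf3b1[i]))
      rows[[length(rows) + 1]] <- add_bse("SF3B1", ccf_sf3b1[i])
    if (!is.na(ccf_eif1ax[i]))
      rows[[length(rows) + 1]] <- add_bse("EIF1AX", ccf_eif1ax[i])
    variants[[i]] <- do.call(rbind, rows)
    panel[[i]] <- simulate_cnv_panel(truth[i, ], config)
  }

  out <- list(cohort = cohort,
              variants = do.call(rbind, variants),
              panel = do.call(rbind, panel),
              truth = truth)
  class(out) <- "um_cohort"
  out
}

#' @export
print.um_cohort <- function(x, ...) {
  n <- nrow(x$cohort)
  cat(sprintf("Synthetic UM cohort: %d samples, %d variant calls, %d panel loci\n",
              n, nrow(x$variants), nrow(x$panel)))
  if (n > 0) {
    cat(sprintf("  Class 1: %d (%.1f%%)   small tumors: %d\n",
                sum(x$cohort$gep_class == "Class1"),
                100 * mean(x$cohort$gep_class == "Class1"),
                sum(x$cohort$thickness_mm <= 2.5 & x$cohort$diameter_mm <= 12)))
  }
  invisible(x)
}
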