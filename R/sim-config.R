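#' Configuration for the synthetic uveal melanoma cohort generator
#'
#' Builds a validated configuration object for [simulate_cohort()].  Defaults
#' reproduce the statistical structure of a large multicenter UM cohort:
#' 62.8% Class 1 tumors, ~11.5% small tumors (thickness <= 2.5 mm and
#' diameter <= 12 mm), mean purity 58.6% in small and 81.9% in larger tumors,
#' Gq founder mutations in every sample with near-complete mutual
#' exclusivity, BSE mutations strongly class-linked (BAP1 with Class 2), and
#' 3p loss sampled predominantly in BAP1-inactivated tumors.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param class1_fraction Probability that a tumor is 15-GEP Class 1.
#' @param mutation_prevalences Named list with elements `gq` (probability of
#'   each Gq gene being the primary founder; normalised internally),
#'   `second_gq` (probability of a rare co-occurring second Gq mutation) and
#'   `bse` (list with `Class1`/`Class2` named probability vectors over
#'   `none`, `BAP1`, `SF3B1`, `EIF1AX`) plus `second_bse` (probability of a
#'   second, distinct BSE mutation).
#' @param size_model List: `small_fraction`, small-tumor uniform ranges
#'   (`small_thick`, `small_diam`) and larger-tumor normal parameters
#'   (`large_thick_mean/sd`, `large_diam_mean/sd`) in millimetres.
#' @param purity_model List with `small_mean`, `small_sd`, `large_mean`,
#'   `large_sd` and truncation `bounds` for tumor purity (fractions).
#' @param depth_variant Mean sequencing depth at driver variant loci.
#' @param depth_panel Mean depth at 3p panel loci.
#' @param n_panel_loci Number of 3p panel loci (>= 2; default 74).
#' @param het_dropout Probability that a panel locus is germline homozygous
#'   (uninformative for B-allele analysis).
#' @param read_model `"paper_consistent"` (expected VAF purity*CCF/2 at
#'   heterozygous loci and purity*CCF at hemizygous loci, the model the CCF
#'   estimator inverts exactly) or `"copy_aware"` (full allele-pool mixing,
#'   which dilutes LOH-locus VAFs by normal diploid DNA and exposes the
#'   estimator's bias).
#' @param dscore_model List controlling the discriminant-score process:
#'   `slope`, `tau_months` (saturation time constant), `noise_sd`.  The
#'   latent score is z = -1 + slope * dosage_deficit * m/(m+tau) + noise,
#'   with Class 2 on the z > 0 side and discriminant score min(|z|, 1).
#' @param survival_model List of baseline monthly hazards and log-hazard
#'   coefficients for the MFS and OS endpoints.
#' @param censoring_months Administrative censoring horizon in months.
#' @param small_class1_odds_ratio Odds ratio coupling small tumor size to
#'   Class 1 membership (small tumors are sampled earlier in their genetic
#'   evolution and are enriched for Class 1).  The large-tumor Class-1
#'   probability is solved so the cohort-wide Class-1 fraction equals
#'   `class1_fraction` exactly.
#' @param loh_model List of conditional LOH3p probabilities
#'   (`p_loh_class2_bap1`, `p_loh_class2_wt`, `p_loh_class1_bap1`) and
#'   `isodisomy_fraction` among LOH tumors.
#' @param depth_noise_sdlog Multiplicative (log-normal) depth noise, sdlog.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- sim_config(n_patients = 50, seed = 7)
#' cfg$class1_fraction
#' @export
sim_config <- function(n_patients = 1140,
                       seed = 1L,
                       class1_fraction = 0.628,
                       mutation_prevalences = list(
                         gq = c(GNAQ = 0.489, GNA11 = 0.465,
                                PLCB4 = 0.022, CYSLTR2 = 0.012),
                         second_gq = 6 / 1140,
                         bse = list(
                           Class1 = c(none = 0.32, BAP1 = 0.035,
                                      SF3B1 = 0.245, EIF1AX = 0.40),
                           Class2 = c(none = 0.12, BAP1 = 0.80,
                                      SF3B1 = 0.05, EIF1AX = 0.03)
                         ),
                         second_bse = 26 / 1140
                       ),
                       size_model = list(
                         small_fraction = 131 / 1140,
                         small_thick = c(1.0, 2.5),
                         small_diam = c(3.0, 12.0),
                         large_thick_mean = 6.0, large_thick_sd = 2.5,
                         large_diam_mean = 13.5, large_diam_sd = 3.5,
                         thick_range = c(1.0, 18.0),
                         diam_range = c(3.0, 28.9)
                       ),
                       purity_model = list(
                         small_mean = 0.586, small_sd = 0.15,
                         large_mean = 0.819, large_sd = 0.10,
                         bounds = c(0.05, 0.99)
                       ),
                       depth_variant = 1000,
                       depth_panel = 300,
                       n_panel_loci = 74L,
                       het_dropout = 0.2,
                       read_model = c("paper_consistent", "copy_aware"),
                       dscore_model = list(slope = 2.6, tau_months = 12,
                                           noise_sd = 0.15),
                       survival_model = list(
                         mfs_base_rate = -log(0.95) / 60,
                         mfs_coef = c(class2 = log(8), prame_pos = log(1.8),
                                      diameter = log(1.03)),
                         os_base_rate = -log(0.88) / 60,
                         os_coef = c(class2 = log(3), prame_pos = log(1.3),
                                     diameter = log(1.02))
                       ),
                       censoring_months = 120,
                       small_class1_odds_ratio = 3.7,
                       loh_model = list(p_loh_class2_bap1 = 0.85,
                                        p_loh_class2_wt = 0.60,
                                        p_loh_class1_bap1 = 0.50,
                                        isodisomy_fraction = 0.25),
                       depth_noise_sdlog = 0.15) {
  read_model <- match.arg(read_model)

  stop_cfg <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  chk_prob <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop_cfg(paste(what, "must be probabilities in [0, 1]"))
  }

  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0)
    stop_cfg("n_patients must be a non-negative count")
  chk_prob(class1_fraction, "class1_fraction")
  chk_prob(mutation_prevalences$gq, "Gq prevalences")
  chk_prob(mutation_prevalences$second_gq, "second_gq")
  chk_prob(mutation_prevalences$second_bse, "second_bse")
  for (cl in c("Class1", "Class2")) {
    p <- mutation_prevalences$bse[[cl]]
    chk_prob(p, paste(cl, "BSE prevalences"))
    if (abs(sum(p) - 1) > 1e-6)
      stop_cfg(paste(cl, "BSE prevalences must sum to 1"))
  }
  if (depth_variant <= 0 || depth_panel <= 0)
    stop_cfg("sequencing depths must be > 0")
  if (n_panel_loci < 2) stop_cfg("n_panel_loci must be >= 2")
  chk_prob(het_dropout, "het_dropout")
  chk_prob(purity_model$small_mean, "purity means")
  chk_prob(purity_model$large_mean, "purity means")
  if (censoring_months <= 0) stop_cfg("censoring_months must be > 0")
  if (small_class1_odds_ratio <= 0)
    stop_cfg("small_class1_odds_ratio must be > 0")
  chk_prob(unlist(loh_model[c("p_loh_class2_bap1", "p_loh_class2_wt",
                              "p_loh_class1_bap1", "isodisomy_fraction")]),
           "LOH probabilities")

  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         class1_fraction = class1_fraction,
         mutation_prevalences = mutation_prevalences,
         size_model = size_model, purity_model = purity_model,
         depth_variant = depth_variant, depth_panel = depth_panel,
         n_panel_loci = as.integer(n_panel_loci), het_dropout = het_dropout,
         read_model = read_model, dscore_model = dscore_model,
         survival_model = survival_model,
         censoring_months = censoring_months,
         small_class1_odds_ratio = small_class1_odds_ratio,
         loh_model = loh_model,
         depth_noise_sdlog = depth_noise_sdlog),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic UM cohort configuration\n")
  cat(sprintf("  patients: %d   seed: %d   Class 1 fraction: %.3f\n",
              x$n_patients, x$seed, x$class1_fraction))
  cat(sprintf("  read model: %s   variant depth: %g   panel: %d loci @ %gx\n",
              x$read_model, x$depth_variant, x$n_panel_loci, x$depth_panel))
  invisible(x)
}
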