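test_that("purity doubles the founder Gq VAF and caps at 1", {
  v <- data.frame(sample_id = "s1", gene = "GNAQ",
                  ref_count = 75, alt_count = 25)
  pe <- estimate_purity(v)
  expect_equal(pe$tp, 0.5)
  expect_equal(pe$source_gene, "GNAQ")
  expect_false(pe$capped)
  # VAF 0.6 -> capped at 1
  v2 <- data.frame(sample_id = "s1", gene = "GNA11",
                   ref_count = 40, alt_count = 60)
  pe2 <- estimate_purity(v2)
  expect_equal(pe2$tp, 1)
  expect_true(pe2$capped)
})

test_that("the max-VAF rule selects among multiple Gq mutations", {
  v <- data.frame(sample_id = "s1",
                  gene = c("GNAQ", "CYSLTR2", "BAP1"),
                  ref_count = c(70, 60, 80),
                  alt_count = c(30, 40, 20))
  pe <- estimate_purity(v)
  expect_equal(pe$source_gene, "CYSLTR2")
  expect_equal(pe$tp, 0.8)
  # exact VAF tie resolved by the fixed gene order
  vt <- data.frame(sample_id = "s1", gene = c("PLCB4", "GNA11"),
                   ref_count = c(60, 60), alt_count = c(40, 40))
  expect_equal(estimate_purity(vt)$source_gene, "GNA11")
  # only pathogenic Gq variants count when annotation is present
  vp <- transform(v, pathogenic = c(TRUE, FALSE, TRUE))
  expect_equal(estimate_purity(vp)$source_gene, "GNAQ")
})

test_that("samples without a Gq mutation are flagged, not errored", {
  v <- data.frame(sample_id = "s1", gene = "SF3B1",
                  ref_count = 80, alt_count = 20)
  pe <- estimate_purity(v)
  expect_false(pe$estimable)
  expect_true(is.na(pe$tp))
  expect_error(estimate_purity(data.frame(sample_id = c("a", "b"),
                                          gene = "GNAQ", ref_count = 50,
                                          alt_count = 50)), "single sample")
})

test_that("VAF correction divides by purity and stays uncapped", {
  expect_equal(correct_vaf(0.2, 0.5), 0.4)
  expect_equal(correct_vaf(0.48, 0.4), 1.2)   # inconsistency preserved
  expect_true(is.na(correct_vaf(0.2, NA)))
  expect_error(correct_vaf(0.2, 0), "tp")
  expect_error(correct_vaf(0.2, 1.1), "tp")
})

test_that("CCF follows the gene-specific allelic models", {
  expect_equal(estimate_ccf("SF3B1", 0.45)$ccf, 0.9)
  expect_equal(estimate_ccf("SF3B1", 0.45)$allelic_model, "het_autosome")
  expect_equal(estimate_ccf("SF3B1", 0.6)$ccf, 1)        # capped
  expect_true(estimate_ccf("SF3B1", 0.6)$inconsistent)
  expect_equal(estimate_ccf("EIF1AX", 0.4, sex = "female")$ccf, 0.8)
  expect_equal(estimate_ccf("EIF1AX", 0.8, sex = "male")$ccf, 0.8)
  expect_equal(estimate_ccf("EIF1AX", 0.8, sex = "male")$allelic_model,
               "x_male")
  loh <- list(status = "loss", confidence = 3L)
  expect_equal(estimate_ccf("BAP1", 0.95, loh3p = loh)$ccf, 0.95)
  expect_equal(estimate_ccf("BAP1", 0.95, loh3p = loh)$allelic_model,
               "bap1_loh")
  iso <- list(status = "isodisomy", confidence = 2L)
  expect_equal(estimate_ccf("BAP1", 0.6, loh3p = iso)$ccf, 0.6)
  ret <- list(status = "retention", confidence = 3L)
  expect_equal(estimate_ccf("BAP1", 0.3, loh3p = ret)$ccf, 0.6)
  expect_equal(estimate_ccf("BAP1", 0.3, loh3p = ret)$allelic_model,
               "bap1_retention")
  expect_error(estimate_ccf("GNAQ", 0.5), "BAP1")
})

test_that("BAP1 CCF is undefined without a usable LOH3p call", {
  e1 <- estimate_ccf("BAP1", 0.5, loh3p = NULL)
  expect_false(e1$defined)
  expect_true(is.na(e1$ccf))
  lowconf <- list(status = "loss", confidence = 1L)
  expect_false(estimate_ccf("BAP1", 0.5, loh3p = lowconf)$defined)
  # NA corrected VAF propagates to an undefined estimate for any gene
  expect_false(estimate_ccf("SF3B1", NA_real_)$defined)
})

test_that("CCF is monotone in corrected VAF under each model", {
  cv <- seq(0, 1.2, by = 0.05)
  configs <- list(list("SF3B1", "female", NULL),
                  list("EIF1AX", "female", NULL),
                  list("EIF1AX", "male", NULL),
                  list("BAP1", "female", list(status = "loss",
                                              confidence = 3L)),
                  list("BAP1", "female", list(status = "retention",
                                              confidence = 3L)))
  for (cf in configs) {
    ccfs <- vapply(cv, function(x)
      estimate_ccf(cf[[1]], x, sex = cf[[2]], loh3p = cf[[3]])$ccf,
      numeric(1))
    expect_true(all(diff(ccfs) >= 0))
    expect_true(all(ccfs <= 1))
  }
})

test_that("cohort clonality table reproduces the per-sample pipeline", {
  variants <- data.frame(
    sample_id = c("a", "a", "b", "b", "c"),
    gene = c("GNAQ", "SF3B1", "GNA11", "EIF1AX", "GNAQ"),
    ref_count = c(700, 820, 750, 600, 400),
    alt_count = c(300, 180, 250, 400, 600),
    stringsAsFactors = FALSE)
  clinical <- data.frame(sample_id = c("a", "b", "c"),
                         sex = c("female", "male", "female"),
                         stringsAsFactors = FALSE)
  cl <- estimate_clonality(variants, clinical)
  a <- cl[cl$sample_id == "a", ]
  expect_equal(a$tp, 0.6)
  expect_equal(a$raw_vaf, 0.18)
  expect_equal(a$corrected_vaf, 0.3)
  expect_equal(a$ccf, 0.6)
  b <- cl[cl$sample_id == "b", ]
  expect_equal(b$tp, 0.5)
  expect_equal(b$ccf, min(0.4 / 0.5, 1))   # male X hemizygous
  expect_equal(b$allelic_model, "x_male")
  # no BSE mutation: one NA-gene row, purity still reported (capped)
  c_ <- cl[cl$sample_id == "c", ]
  expect_equal(nrow(c_), 1)
  expect_true(is.na(c_$gene))
  expect_equal(c_$tp, 1)
  expect_true(c_$tp_capped)
})

test_that("noise-free round trip recovers the simulated truth exactly", {
  # deterministic reads at the expected VAFs: the estimator chain must
  # invert the generative arithmetic exactly
  depth <- 10000
  purity <- 0.72
  ccf_true <- 0.65
  vaf_gq <- purity / 2
  vaf_sf <- purity * ccf_true / 2
  v <- data.frame(
    sample_id = "t", gene = c("GNAQ", "SF3B1"),
    ref_count = round(depth * (1 - c(vaf_gq, vaf_sf))),
    alt_count = round(depth * c(vaf_gq, vaf_sf)))
  cl <- estimate_clonality(v, data.frame(sample_id = "t", sex = "female"))
  expect_equal(cl$tp, purity, tolerance = 1e-3)
  expect_equal(cl$ccf, ccf_true, tolerance = 1e-3)
})

test_that("copy-aware reads bias the hemizygous estimator to 1/(2-p) under loss", {
  # under true 3p loss the copy-aware VAF is p/(2-p); the hemizygous
  # estimator (divide by p) then reports CCF 1/(2-p) instead of 1
  purity <- 0.8
  vaf <- expected_vaf(purity, 1, "loss", "copy_aware")
  cv <- correct_vaf(vaf, purity)
  est <- estimate_ccf("BAP1", cv,
                      loh3p = list(status = "loss", confidence = 3L))
  expect_equal(est$ccf, min(1 / (2 - purity), 1), tolerance = 1e-12)
})
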