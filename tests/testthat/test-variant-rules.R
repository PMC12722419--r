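test_that("variant-type taxonomy follows the length and codon rules", {
  # premature stop codon
  expect_equal(classify_variant_type("C", "T", list(ref_aa = "Q", alt_aa = "*")),
               "nonsense")
  expect_equal(classify_variant_type("T", "C", list(ref_aa = "*", alt_aa = "R")),
               "stop_loss")
  expect_equal(classify_variant_type("A", "G",
                                     list(ref_aa = "M", alt_aa = "V",
                                          is_start_codon = TRUE)),
               "start_loss")
  # 2-nt deletion: 2 mod 3 != 0
  expect_equal(classify_variant_type("CAT", "C", list()), "frameshift_indel")
  # in-frame 3-nt insertion
  expect_equal(classify_variant_type("C", "CTTA", list()),
               "nonframeshift_indel")
  # multi-codon substitution
  expect_equal(classify_variant_type("CTGAAA", "AGACCC",
                                     list(codons_affected = 2)),
               "block_substitution")
  # canonical splice window takes precedence
  expect_equal(classify_variant_type("G", "A", list(splice_distance = 2)),
               "splice_site")
  expect_equal(classify_variant_type("G", "A",
                                     list(splice_distance = 3,
                                          ref_aa = "G", alt_aa = "D")),
               "missense")
  # SNV without codon context cannot be classified
  expect_error(classify_variant_type("C", "T", list()), "codon context")
  expect_error(classify_variant_type("", "T", list()), "non-empty")
})

test_that("pathogenicity rule engine matches a brute-force truth table", {
  eps <- 1e-9
  sai_grid <- c(NA, 0, 0.4, 0.5 - eps, 0.5, 0.5 + eps, 1)
  sift_grid <- c(NA, 0, 0.05 - eps, 0.05, 0.05 + eps, 0.3, 1)
  pp2_grid <- c(NA, 0, 0.5 - eps, 0.5, 0.5 + eps, 1)
  clv_grid <- c(NA, TRUE, FALSE)
  eff_grid <- c(NA, "donor_loss", "acceptor_gain", "none")
  types <- c("nonsense", "stop_loss", "start_loss", "frameshift_indel",
             "nonframeshift_indel", "block_substitution", "splice_site",
             "missense")
  n_checked <- 0
  for (ty in types) {
    for (sai in sai_grid) for (eff in eff_grid) {
      for (sift in sift_grid) for (pp2 in pp2_grid) for (clv in clv_grid) {
        got <- call_pathogenic(ty, sai, eff, clv, sift, pp2)
        want <- oracle_pathogenic(ty, sai, eff, clv, sift, pp2)
        expect_identical(got$pathogenic, want)
        n_checked <- n_checked + 1
      }
      # the non-score rules do not depend on sift/pp2/clinvar: skip the
      # inner grid after one pass for those types
      if (ty != "missense") break
    }
    if (ty != "missense" && ty != "splice_site") next
  }
  expect_gt(n_checked, 500)
})

test_that("pathogenicity basis attribution follows the stated precedence", {
  expect_equal(call_pathogenic("nonsense")$basis, "type_rule")
  expect_equal(call_pathogenic("missense", clinvar_pathogenic = TRUE,
                               sift = 0.01)$basis, "clinvar")
  expect_equal(call_pathogenic("missense", sift = 0.05,
                               polyphen2 = 0.1)$basis, "sift")
  expect_equal(call_pathogenic("missense", sift = 0.2,
                               polyphen2 = 0.5)$basis, "polyphen2")
  # unannotated missense is indeterminate, not benign
  r <- call_pathogenic("missense")
  expect_true(r$indeterminate)
  expect_true(is.na(r$pathogenic))
  # splice site below threshold is a definite negative
  r2 <- call_pathogenic("splice_site", splice_ai = 0.4,
                        splice_effect = "donor_loss")
  expect_false(r2$pathogenic)
  expect_false(r2$indeterminate)
})

test_that("complex BAP1 filter partitions by nucleotide-change count", {
  v <- data.frame(
    sample_id = paste0("s", 1:4), gene = "BAP1",
    ref_allele = c("C", "AAAAAA", "CAAAA", "ACGTACGT"),
    alt_allele = c("A", "GGGGGG", "C", "A"),
    stringsAsFactors = FALSE)
  # edit distances: 1 (SNV), 6 (block), 4 (deletion), 7 (deletion)
  fc <- filter_complex_bap1(v)
  expect_equal(fc$kept$sample_id, c("s1", "s3"))
  expect_equal(fc$excluded$sample_id, c("s2", "s4"))
  # exact partition, order preserved
  expect_equal(nrow(fc$kept) + nrow(fc$excluded), nrow(v))
  expect_identical(rbind(fc$kept, fc$excluded)[order(c(which(!v$sample_id %in%
    fc$excluded$sample_id), which(v$sample_id %in% fc$excluded$sample_id))), ],
    rbind(fc$kept, fc$excluded)[order(match(rbind(fc$kept,
      fc$excluded)$sample_id, v$sample_id)), ])
})

test_that("SGE join matches on hg38 position and alleles only", {
  set.seed(42)
  n <- 300
  vars <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    pos = 52400000 + seq_len(n) * 3,
    ref_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    alt_allele = "X",  # placeholder, fixed below
    assembly = "hg38", stringsAsFactors = FALSE)
  vars$alt_allele <- vapply(vars$ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  in_table <- sample(n, 250)
  sge <- data.frame(pos = vars$pos[in_table],
                    ref_allele = vars$ref_allele[in_table],
                    alt_allele = vars$alt_allele[in_table],
                    functional_class = sample(c("depleted", "not_depleted"),
                                              250, TRUE, prob = c(0.9, 0.1)),
                    functional_score = rnorm(250),
                    stringsAsFactors = FALSE)
  j <- join_sge(vars, sge)
  expect_equal(sum(!j$unmapped), 250)
  expect_equal(sum(j$unmapped), 50)
  expect_equal(j$functional_score[in_table[1]], sge$functional_score[1])
  # refuse cross-assembly joins
  vars19 <- transform(vars, assembly = "hg19")
  expect_error(join_sge(vars19, sge), "hg38")
})

test_that("functional comparison by class uses two-tailed exact tests", {
  # 2x2 [[8,2],[1,9]]: frozen from the hypergeometric enumeration oracle
  tab <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  expect_equal(oracle_fisher_p(tab), 0.005477495, tolerance = 1e-6)
  ann <- data.frame(
    functional_class = rep(c("depleted", "not_depleted"), c(9, 11)),
    functional_score = c(rnorm(9, -2), rnorm(11, 0)),
    unmapped = FALSE, stringsAsFactors = FALSE)
  cls <- c(rep("Class1", 8), "Class2", rep("Class1", 2), rep("Class2", 9))
  res <- compare_functional_by_class(ann, cls)
  expect_equal(res$fisher_p, oracle_fisher_p(tab), tolerance = 1e-9)

  # identical score distributions: rank-sum p ~ 1
  sc <- rep(seq(0, 1, length.out = 10), 2)
  ann2 <- data.frame(functional_class = "depleted", functional_score = sc,
                     unmapped = FALSE)
  res2 <- compare_functional_by_class(ann2, rep(c("Class1", "Class2"),
                                                each = 10))
  expect_gt(res2$wilcoxon_p, 0.9)
  # degenerate margin: all depleted in both classes
  expect_equal(res2$fisher_p, 1)
  # a class with no annotated variants is an error
  expect_error(compare_functional_by_class(ann2, rep("Class1", 20)),
               "at least one")
})
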