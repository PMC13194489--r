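# Minimal hand-built CT table: two strains, one target gene, one replicate,
# with ddCt fully controlled.
ct_table <- function(test_target_ct, ref_target_ct = 24, hk_ct = 18,
                     replicates = 1) {
  tidyr::expand_grid(
    strain = c("test", "ref"), replicate = seq_len(replicates)
  ) %>%
    dplyr::reframe(
      gene = c("tgt", "recA"),
      ct = c(ifelse(strain == "test", test_target_ct, ref_target_ct), hk_ct),
      .by = c("strain", "replicate")
    )
}

test_that("fold changes follow the 2^-ddCt definition", {
  # identical CTs -> fold 1
  r <- delta_delta_ct(ct_table(24), "recA", "ref")
  expect_equal(r$fold[r$strain == "test"], 1)
  # ddCt = -1 (target one cycle earlier) -> fold 2
  r <- delta_delta_ct(ct_table(23), "recA", "ref")
  expect_equal(r$fold[r$strain == "test"], 2)
  # ddCt = +2 -> fold 0.25
  r <- delta_delta_ct(ct_table(26), "recA", "ref")
  expect_equal(r$fold[r$strain == "test"], 0.25)
})

test_that("the reference strain's mean fold is exactly 1", {
  set.seed(301)
  folds <- tibble::tibble(strain = "evolved", gene = c("pilA", "omcZ"),
                          fold = c(5, 0.3))
  ct <- generate_ct_table(folds, reference_strain = "parent", noise_sd = 0.4,
                          replicates = 4, seed = 31)
  r <- delta_delta_ct(ct, "recA", "parent")
  ref_folds <- r$fold[r$strain == "parent"]
  expect_equal(ref_folds, rep(1, length(ref_folds)), tolerance = 1e-12)
})

test_that("adding a constant to every CT of a sample leaves folds unchanged", {
  folds <- tibble::tibble(strain = "evolved", gene = "pilA", fold = 3)
  ct <- generate_ct_table(folds, reference_strain = "parent", noise_sd = 0.2,
                          replicates = 3, seed = 32)
  r1 <- delta_delta_ct(ct, "recA", "parent")
  shifted <- ct %>%
    dplyr::mutate(ct = ct + ifelse(strain == "evolved" & replicate == 2, 4.7, 0))
  r2 <- delta_delta_ct(shifted, "recA", "parent")
  expect_equal(r2$fold, r1$fold, tolerance = 1e-12)
})

test_that("missing housekeeping or reference strain raise errors", {
  tb <- ct_table(24)
  expect_error(delta_delta_ct(tb[tb$gene != "recA", ], "recA", "ref"),
               "Housekeeping")
  expect_error(delta_delta_ct(tb, "recA", "nope"), "absent")
  bad <- tb[!(tb$strain == "ref" & tb$gene == "tgt"), ]
  expect_error(delta_delta_ct(bad, "recA", "ref"), "Reference strain lacks")
})

test_that("noiseless generator encodes folds as CT shifts", {
  folds <- tibble::tibble(strain = "evolved", gene = "pilA", fold = 4)
  ct <- generate_ct_table(folds, reference_strain = "parent", noise_sd = 0,
                          replicates = 1, seed = 33)
  t_ev <- ct$ct[ct$strain == "evolved" & ct$gene == "pilA"]
  t_ref <- ct$ct[ct$strain == "parent" & ct$gene == "pilA"]
  expect_equal(t_ref - t_ev, 2)  # 4-fold = 2 cycles earlier
  r <- delta_delta_ct(ct, "recA", "parent")
  expect_equal(r$fold[r$strain == "evolved"], 4)
  expect_error(generate_ct_table(dplyr::mutate(folds, fold = -1), "parent"),
               "positive")
})

test_that("a planted 10-fold change is recovered within 20% on average", {
  folds <- tibble::tibble(strain = "evolved", gene = "pilA", fold = 10)
  rec <- vapply(1:30, function(i) {
    ct <- generate_ct_table(folds, reference_strain = "parent", noise_sd = 0.3,
                            replicates = 3, seed = 300 + i)
    r <- delta_delta_ct(ct, "recA", "parent")
    r$fold[r$strain == "evolved"]
  }, numeric(1))
  expect_lt(abs(mean(rec) - 10) / 10, 0.2)
})

test_that("expression contrasts behave like t-tests on log2 folds", {
  folds <- tibble::tibble(strain = c("lt1", "lt2"), gene = "pilA",
                          fold = c(4, 4))
  ct <- generate_ct_table(folds, reference_strain = "kn", noise_sd = 0.2,
                          replicates = 3, seed = 34)
  r <- delta_delta_ct(ct, "recA", "kn")
  # identical groups: difference 0, p = 1
  same <- expression_contrast(r, "pilA", list(a = "lt1", b = "lt1"))
  expect_equal(same$log2_difference, 0)
  expect_equal(same$p_value, 1)
  # symmetry under group swap
  ab <- expression_contrast(r, "pilA", list(a = "lt1", b = "kn"))
  ba <- expression_contrast(r, "pilA", list(a = "kn", b = "lt1"))
  expect_equal(ab$log2_difference, -ba$log2_difference)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("a planted 4-fold separation is detected with high power", {
  folds <- tibble::tibble(strain = "evolved", gene = "pilA", fold = 4)
  reject <- vapply(1:50, function(i) {
    ct <- generate_ct_table(folds, reference_strain = "parent", noise_sd = 0.2,
                            replicates = 3, seed = 400 + i)
    r <- delta_delta_ct(ct, "recA", "parent")
    ec <- expression_contrast(r, "pilA", list(a = "evolved", b = "parent"))
    isTRUE(ec$p_value < 0.05)
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})

test_that("single-replicate contrasts return point estimates without a test", {
  tb <- ct_table(22)
  r <- delta_delta_ct(tb, "recA", "ref")
  ec <- expression_contrast(r, "tgt", list(a = "test", b = "ref"))
  expect_true(is.na(ec$p_value))
  expect_match(ec$method, "single replicate")
  expect_equal(ec$fold_a, 4)
})
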