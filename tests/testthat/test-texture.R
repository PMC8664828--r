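test_that("resampling is exact on identity, constants and linear ramps", {
  # identity: already at target spacing
  v <- volume_grid(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(4, 4, 2))
  out <- resample_pet(v, c(4, 4, 2))
  expect_equal(out$data, v$data)
  expect_equal(out$spacing, c(4, 4, 2))

  # constant field stays constant
  cv <- volume_grid(array(3.7, c(16, 16, 16)), c(2, 2, 2))
  expect_true(all(abs(resample_pet(cv, c(4, 4, 2))$data - 3.7) < 1e-12))

  # linear ramp along x reproduces the ramp at the new centres
  nx <- 16
  ramp <- array(rep((0:(nx - 1)) * 2 * 0.5 + 1, 16 * 16), c(nx, 16, 16))
  rv <- volume_grid(ramp, c(2, 2, 2))
  out <- resample_pet(rv, c(4, 4, 4))
  centres_x <- -1 + (seq_len(dim(out$data)[1]) - 0.5) * 4
  expected <- centres_x * 0.5 + 1
  expect_lt(max(abs(sweep(out$data, 1, expected))), 1e-6)
  expect_error(resample_pet(rv, c(0, 4, 4)), "positive")
})

test_that("resampling preserves the physical extent within one voxel", {
  v <- volume_grid(array(0, c(64, 64, 160)), c(2, 2, 2))
  out <- resample_pet(v, c(4, 4, 2))
  expect_equal(dim(out$data), c(32, 32, 160))
  expect_equal(dim(out$data) * out$spacing, dim(v$data) * v$spacing)
})

test_that("absolute SUV discretization follows the 64-bin 0-30 mapping", {
  spec <- discretization_spec()
  expect_equal(spec$bin_width, 0.46875)
  suv <- c(0, 0.5, 15, 30, 31)
  vol <- volume_grid(array(suv, c(5, 1, 1)), c(1, 1, 1))
  voi <- skeleton_voi(array(TRUE, c(5, 1, 1)), c(1, 1, 1))
  d <- discretize(vol, voi, spec)
  expect_identical(as.integer(d$levels), c(1L, 2L, 33L, 64L, 64L))
  empty <- skeleton_voi(array(FALSE, c(5, 1, 1)), c(1, 1, 1))
  expect_error(discretize(vol, empty, spec), "empty")
})

test_that("conventional features on a uniform block are exact", {
  vol <- volume_grid(array(2, c(10, 10, 10)), c(2, 4, 4))
  voi <- skeleton_voi(array(TRUE, c(10, 10, 10)), c(2, 4, 4))
  cf <- conventional_features(vol, voi)
  expect_equal(unname(cf$values["SUVmax"]), 2)
  expect_equal(unname(cf$values["SUVpeak"]), 2)
  expect_equal(unname(cf$values["TLG_mL"]), 64)
  # uniform input: skewness/kurtosis undefined, flagged
  expect_true(is.na(cf$values["SUVskewness"]))
  expect_match(cf$flags, "zero-variance", all = FALSE)
})

test_that("skewness is zero on symmetric data; kurtosis identity holds", {
  vol <- volume_grid(array(c(1, 2, 3), c(3, 1, 1)), c(1, 1, 1))
  voi <- skeleton_voi(array(TRUE, c(3, 1, 1)), c(1, 1, 1))
  cf <- conventional_features(vol, voi)
  expect_equal(unname(cf$values["SUVskewness"]), 0)
  expect_equal(unname(cf$values["SUVkurtosis"] - cf$values["SUVexcess_kurtosis"]), 3)
  # identity also on skewed data
  vol2 <- volume_grid(array(c(1, 1, 1, 9, 2, 3, 1, 5), c(8, 1, 1)), c(1, 1, 1))
  voi2 <- skeleton_voi(array(TRUE, c(8, 1, 1)), c(1, 1, 1))
  cf2 <- conventional_features(vol2, voi2)
  expect_equal(unname(cf2$values["SUVkurtosis"] - cf2$values["SUVexcess_kurtosis"]), 3)
})

test_that("SUVpeak averages the 1 mL sphere at the hottest voxel", {
  a <- array(1, c(9, 9, 9)); a[5, 5, 5] <- 10
  vol <- volume_grid(a, c(4, 4, 4))
  voi <- skeleton_voi(array(TRUE, c(9, 9, 9)), c(4, 4, 4))
  cf <- conventional_features(vol, voi)
  # 6.2 mm radius at 4 mm voxels: hot centre + 6 face + 12 edge neighbours
  expect_equal(unname(cf$values["SUVpeak"]), (10 + 18) / 19)
})

test_that("a single-level VOI collapses the GLCM to one cell", {
  d <- make_dvoi(array(5L, c(3, 3, 3)), n_bins = 8)
  g <- glcm_features(d)
  expect_equal(unname(g$values["angular_second_moment_GLCM"]), 1)
  expect_equal(unname(g$values["inverse_difference_GLCM"]), 1)
  expect_equal(unname(g$values["dissimilarity_GLCM"]), 0)
  expect_equal(unname(g$values["joint_entropy_GLCM"]), 0)
  expect_equal(unname(g$values["variance_GLCM"]), 0)
  expect_true(is.na(g$values["correlation_GLCM"]))
  expect_match(g$flags, "degenerate", all = FALSE)
})

test_that("GLCM features equal pair-enumeration on the 2x2 example block", {
  L <- array(NA_integer_, c(2, 2, 1))
  L[, , 1] <- matrix(c(1L, 1L, 2L, 2L), 2, 2)   # columns [1,2],[1,2]
  d <- make_dvoi(L, n_bins = 2)
  o <- oracle_glcm(L)
  g <- glcm_features(d)$values
  expect_feature_equal(g["inverse_difference_GLCM"], o$inverse_difference)
  expect_feature_equal(g["angular_second_moment_GLCM"], o$asm)
  expect_feature_equal(g["variance_GLCM"], o$variance)
  expect_feature_equal(g["correlation_GLCM"], o$correlation)
  expect_feature_equal(g["joint_entropy_GLCM"], o$joint_entropy)
  expect_feature_equal(g["dissimilarity_GLCM"], o$dissimilarity)
})

test_that("the pooled GLCM is symmetric, normalized and entropy-bounded", {
  set.seed(42)
  for (rep in 1:5) {
    L <- array(sample(1:6, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
    L[sample(length(L), 10)] <- NA
    d <- make_dvoi(L, n_bins = 64)
    P <- skelrad:::glcm_matrix(d)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
    expect_lte(glcm_features(d)$values[["joint_entropy_GLCM"]], log2(64))
  }
})

test_that("a flat VOI reports the documented NGLDM degeneracies", {
  d <- make_dvoi(array(3L, c(3, 3, 3)), n_bins = 8)
  ng <- ngldm_features(d)
  expect_equal(unname(ng$values["coarseness_NGLDM"]), 1e6)
  expect_equal(unname(ng$values["contrast_NGLDM"]), 0)
  expect_true(is.na(ng$values["busyness_NGLDM"]))
})

test_that("NGLDM features equal the neighbour-mean enumeration oracle", {
  L <- array(NA_integer_, c(3, 3, 1))
  L[, , 1] <- matrix(c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L), 3, 3)
  d <- make_dvoi(L, n_bins = 4)
  o <- oracle_ngldm(L)
  ng <- ngldm_features(d)$values
  expect_feature_equal(ng["coarseness_NGLDM"], o$coarseness)
  expect_feature_equal(ng["contrast_NGLDM"], o$contrast)
  expect_feature_equal(ng["busyness_NGLDM"], o$busyness)
})

test_that("interleaved levels are busier than the same levels in blocks", {
  checker <- array(NA_integer_, c(4, 4, 1))
  checker[, , 1] <- (outer(1:4, 1:4, `+`) %% 2) + 1L
  blocks <- array(NA_integer_, c(4, 4, 1))
  blocks[, , 1] <- rbind(matrix(1L, 2, 4), matrix(2L, 2, 4))
  b_checker <- ngldm_features(make_dvoi(checker, 2))$values["busyness_NGLDM"]
  b_blocks <- ngldm_features(make_dvoi(blocks, 2))$values["busyness_NGLDM"]
  expect_gt(b_checker, b_blocks)
  # and the oracle agrees with both
  expect_feature_equal(b_checker, oracle_ngldm(checker)$busyness)
  expect_feature_equal(b_blocks, oracle_ngldm(blocks)$busyness)
})

test_that("single-zone and all-singleton VOIs match GLZLM closed forms", {
  uni <- make_dvoi(array(4L, c(3, 3, 2)), n_bins = 8)
  zf <- glzlm_features(uni)$values
  n_v <- 18
  expect_feature_equal(zf["ZP_GLZLM"], 1 / n_v)
  expect_feature_equal(zf["SZE_GLZLM"], 1 / n_v^2)
  expect_feature_equal(zf["LZE_GLZLM"], n_v^2)

  strip <- make_dvoi(array(rep(1:3, 2), c(6, 1, 1)), n_bins = 4)
  zs <- glzlm_features(strip)$values
  expect_feature_equal(zs["ZP_GLZLM"], 1)
  expect_feature_equal(zs["SZE_GLZLM"], 1)
})

test_that("GLZLM features equal the flood-fill connected-component oracle", {
  skip_if_not_installed("igraph")
  L <- array(NA_integer_, c(4, 4, 1))
  L[, , 1] <- matrix(c(1L, 1L, 2L, 2L,
                       1L, 3L, 2L, 2L,
                       3L, 3L, 1L, 2L,
                       3L, 1L, 1L, 2L), 4, 4, byrow = TRUE)
  o <- oracle_glzlm(L)
  z <- glzlm_features(make_dvoi(L, 4))$values
  nm <- c(SZE = "SZE_GLZLM", LZE = "LZE_GLZLM", LGZE = "LGZE_GLZLM",
          HGZE = "HGZE_GLZLM", SZLGE = "SZLGE_GLZLM", SZHGE = "SZHGE_GLZLM",
          LZLGE = "LZLGE_GLZLM", LZHGE = "LZHGE_GLZLM", GLNU = "GLNU_GLZLM",
          ZLNU = "ZLNU_GLZLM", ZP = "ZP_GLZLM")
  for (k in names(nm)) expect_feature_equal(z[nm[[k]]], o[[k]])
})

test_that("matrix features are translation- and axis-order-invariant", {
  set.seed(7)
  core <- array(sample(1:4, 3 * 3 * 2, replace = TRUE), c(3, 3, 2))
  embed <- function(at) {
    L <- array(NA_integer_, c(10, 10, 8))
    L[at[1]:(at[1] + 2), at[2]:(at[2] + 2), at[3]:(at[3] + 1)] <- core
    L
  }
  f1 <- c(glcm_features(make_dvoi(embed(c(1, 1, 1)), 4))$values,
          ngldm_features(make_dvoi(embed(c(1, 1, 1)), 4))$values,
          glzlm_features(make_dvoi(embed(c(1, 1, 1)), 4))$values)
  f2 <- c(glcm_features(make_dvoi(embed(c(6, 5, 4)), 4))$values,
          ngldm_features(make_dvoi(embed(c(6, 5, 4)), 4))$values,
          glzlm_features(make_dvoi(embed(c(6, 5, 4)), 4))$values)
  expect_equal(f1, f2)
  perm <- array(NA_integer_, c(8, 10, 10))
  perm[1:2, 1:3, 1:3] <- aperm(core, c(3, 1, 2))
  f3 <- c(glcm_features(make_dvoi(perm, 4))$values,
          ngldm_features(make_dvoi(perm, 4))$values,
          glzlm_features(make_dvoi(perm, 4))$values)
  expect_equal(f1, f3)
})

test_that("sub-bin-width SUV shifts leave matrix features unchanged", {
  spec <- discretization_spec()
  set.seed(11)
  # SUVs at bin centres so a +0.2*bin_width shift cannot cross a bin edge
  lv <- sample(2:10, 4 * 4 * 4, replace = TRUE)
  suv <- (lv - 0.5) * spec$bin_width
  vol1 <- volume_grid(array(suv, c(4, 4, 4)), c(2, 2, 2))
  vol2 <- volume_grid(array(suv + 0.2 * spec$bin_width, c(4, 4, 4)), c(2, 2, 2))
  voi <- skeleton_voi(array(TRUE, c(4, 4, 4)), c(2, 2, 2))
  d1 <- discretize(vol1, voi, spec); d2 <- discretize(vol2, voi, spec)
  expect_identical(d1$levels, d2$levels)
  expect_equal(glcm_features(d1)$values, glcm_features(d2)$values)
  expect_equal(glzlm_features(d1)$values, glzlm_features(d2)$values)
})

test_that("cohort extraction is deterministic and orders its 26 columns", {
  p <- small_phantom(grid_shape = c(24, 24, 48))
  tr <- generate_truth_table(3, prevalence = 1 / 3, seed = 5)
  f1 <- extract_features_cohort(tr, p, seed = 5)
  f2 <- extract_features_cohort(tr, p, seed = 5)
  expect_identical(f1, f2)
  expect_identical(colnames(f1), c("subject_id", radiomic_feature_names()))
})

test_that("stage errors name the failing stage", {
  soft_ct <- volume_grid(array(40, c(16, 16, 16)), c(2, 2, 2))
  pet <- volume_grid(array(1, c(16, 16, 16)), c(2, 2, 2))
  expect_error(suppressWarnings(extract_features(soft_ct, pet)),
               "transfer_to_pet|discretize")
})
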