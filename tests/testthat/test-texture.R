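test_that("GLCM matches the worked 2-voxel example", {
  v <- pet_volume(array(c(1, 3, rep(1, 6)), c(2, 2, 2)))
  m <- array(c(TRUE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  g <- glcm_features(discretize(v, m, "fbn", 3))
  # only pair (1,3)/(3,1): contrast = (1-3)^2 = 4
  expect_equal(g$glcm_contrast, 4)
  expect_equal(g$glcm_dissimilarity, 2)
  expect_equal(g$glcm_joint_energy, 0.5)
})

test_that("constant ROI gives zero contrast and joint maximum 1", {
  v <- pet_volume(array(5, c(3, 3, 3)))
  d <- discretize(v, array(TRUE, c(3, 3, 3)), "fbn", 6)
  g <- glcm_features(d)
  expect_equal(g$glcm_contrast, 0)
  expect_equal(g$glcm_joint_maximum, 1)
  expect_equal(g$glcm_joint_entropy, 0)
})

test_that("single-voxel ROI warns and degrades gracefully", {
  v <- pet_volume(array(1:8 / 8, c(2, 2, 2)))
  m <- array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2))
  expect_warning(g <- glcm_features(discretize(v, m, "fbn", 4)),
                 "single-voxel")
  expect_equal(g$glcm_contrast, 0)
})

test_that("GLCM counts equal brute-force enumeration on random ROIs", {
  for (s in 1:12) {
    roi <- random_roi(s)
    d <- make_droi(roi$values, roi$mask, roi$n_levels)
    ng <- max(d$levels, na.rm = TRUE)
    oracle <- oracle_glcm_counts(d$levels, roi$mask, ng)
    if (sum(oracle) == 0) next
    p_oracle <- oracle / sum(oracle)
    got <- glcm_features(d)
    i <- matrix(seq_len(ng), ng, ng); j <- t(i)
    expect_equal(got$glcm_contrast, sum(p_oracle * (i - j)^2),
                 tolerance = 1e-12)
    expect_equal(got$glcm_joint_energy, sum(p_oracle^2),
                 tolerance = 1e-12)
  }
})

test_that("distance map matches brute force on random masks", {
  for (s in 1:8) {
    roi <- random_roi(s + 100)
    got <- pcrpet:::distance_map_cheb(roi$mask)
    want <- oracle_distance_map(roi$mask)
    expect_equal(got[roi$mask], want[roi$mask])
  }
})

test_that("GLDZM matrix matches brute force on random ROIs", {
  for (s in 1:10) {
    roi <- random_roi(s + 200)
    d <- make_droi(roi$values, roi$mask, roi$n_levels)
    ng <- max(d$levels, na.rm = TRUE)
    got <- pcrpet:::gldzm_matrix(d)
    want <- oracle_gldzm(d$levels, roi$mask, ng)
    expect_equal(dim(got), dim(want))
    expect_equal(got, want)
  }
})

test_that("GLDZM on a fully interior solid block", {
  # 5x5x5 all-mask constant ROI: one zone at distance 3 (center depth)
  v <- pet_volume(array(1, c(5, 5, 5)))
  d <- discretize(v, array(TRUE, c(5, 5, 5)), "fbn", 4)
  m <- pcrpet:::gldzm_matrix(d)
  expect_equal(sum(m), 1)  # a single zone
  expect_equal(unname(which(m == 1, arr.ind = TRUE)[1, 2]), 1)  # touches border
  f <- gldzm_features(d)
  expect_equal(f$gldzm_zone_percentage, 1 / 125)
})

test_that("NGLDM matrix matches brute force on random ROIs", {
  for (s in 1:10) {
    roi <- random_roi(s + 300)
    d <- make_droi(roi$values, roi$mask, roi$n_levels)
    ng <- max(d$levels, na.rm = TRUE)
    got <- pcrpet:::ngldm_matrix(d)
    want <- oracle_ngldm(d$levels, roi$mask, ng)
    expect_equal(dim(got), dim(want))
    expect_equal(got, want)
  }
})

test_that("NGLDM of a constant all-mask cube: full dependence", {
  v <- pet_volume(array(1, c(3, 3, 3)))
  d <- discretize(v, array(TRUE, c(3, 3, 3)), "fbn", 2)
  m <- pcrpet:::ngldm_matrix(d)
  # center voxel has k = 27, corners k = 8, etc.; all level 1
  expect_equal(nrow(m), 1)
  expect_equal(sum(m), 27)
  expect_equal(m[1, 27], 1)  # the center voxel
  f <- ngldm_features(d)
  expect_equal(f$ngldm_low_gray_level_count_emphasis, 1)
})

test_that("emphasis features follow their defining sums", {
  roi <- random_roi(999)
  d <- make_droi(roi$values, roi$mask, roi$n_levels)
  ng <- max(d$levels, na.rm = TRUE)
  mz <- oracle_gldzm(d$levels, roi$mask, ng)
  nz <- sum(mz)
  want <- 0
  for (i in 1:nrow(mz)) for (dd in 1:ncol(mz))
    want <- want + mz[i, dd] * dd^2 / i^2
  expect_equal(gldzm_features(d)$gldzm_large_distance_low_gray_level_emphasis,
               want / nz, tolerance = 1e-12)
  ms <- oracle_ngldm(d$levels, roi$mask, ng)
  nv <- sum(ms)
  want2 <- 0
  for (i in 1:nrow(ms)) for (k in 1:ncol(ms))
    want2 <- want2 + ms[i, k] / (i^2 * k^2)
  expect_equal(ngldm_features(d)$ngldm_low_dependence_low_gray_level_emphasis,
               want2 / nv, tolerance = 1e-12)
})
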