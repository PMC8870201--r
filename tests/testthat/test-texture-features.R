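test_that("constant ROI collapses to the single-level closed forms", {
  lev <- array(1L, c(4, 4, 2))
  f <- texture_features(build_texture_matrices(lev, 8L))
  expect_equal(unname(f["GLRLM_HGLRE"]), 1)   # all runs at level 1
  expect_equal(unname(f["GLCM_joint_entropy"]), 0)
  expect_equal(unname(f["GLCM_angular_second_moment"]), 1)
  expect_equal(unname(f["GLCM_joint_maximum"]), 1)
  expect_equal(unname(f["GLSZM_HGLZE"]), 1)
  expect_equal(unname(f["GLSZM_zone_entropy"]), 0)
  expect_equal(unname(f["NGTDM_contrast"]), 0)
  expect_equal(unname(f["GLCM_information_correlation_1"]), 0) # HX = HY = 0
  expect_length(f, 62L)
})

test_that("run emphasis follows the direct formula on a hand-built matrix", {
  # runs: level 1 length 2 (x1), level 2 length 1 (x2)
  M <- matrix(0, 2, 2); M[1, 2] <- 1; M[2, 1] <- 2
  f <- radiopcr:::.glrlm_features(M, nvox = 4, ndir = 1)
  expect_equal(unname(f["HGLRE"]), (1 * 1^2 + 2 * 2^2) / 3)  # 3.0
  expect_equal(unname(f["SRE"]), (1 / 4 + 2) / 3)
  expect_equal(unname(f["LRE"]), (1 * 4 + 2) / 3)
  expect_equal(unname(f["GLNU"]), (1^2 + 2^2) / 3)
  expect_equal(unname(f["run_percentage"]), 3 / 4)
})

test_that("feature values match an independent naive implementation", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_level_grid(max_dim = 6L)
    tm <- build_texture_matrices(g$levels, g$nb)
    f <- texture_features(tm)
    # GLCM oracle: explicit double loops over the enumeration-built matrix
    M <- oracle_glcm(g$levels, g$nb)
    if (sum(M) > 0) {
      p <- M / sum(M)
      contrast <- ent <- asm <- auto <- 0
      for (a in seq_len(g$nb)) for (b in seq_len(g$nb)) {
        contrast <- contrast + (a - b)^2 * p[a, b]
        asm <- asm + p[a, b]^2
        auto <- auto + a * b * p[a, b]
        if (p[a, b] > 0) ent <- ent - p[a, b] * log2(p[a, b])
      }
      expect_equal(unname(f["GLCM_contrast"]), contrast, tolerance = 1e-10)
      expect_equal(unname(f["GLCM_joint_entropy"]), ent, tolerance = 1e-10)
      expect_equal(unname(f["GLCM_angular_second_moment"]), asm, tolerance = 1e-10)
      expect_equal(unname(f["GLCM_autocorrelation"]), auto, tolerance = 1e-10)
    }
    # GLRLM oracle
    R <- oracle_glrlm(g$levels, g$nb)
    pr <- R / sum(R)
    hglre <- 0
    for (a in seq_len(nrow(R))) for (l in seq_len(ncol(R)))
      hglre <- hglre + a^2 * pr[a, l]
    expect_equal(unname(f["GLRLM_HGLRE"]), hglre, tolerance = 1e-10)
    # GLSZM oracle
    S <- oracle_glszm(g$levels, g$nb)
    ps <- S / sum(S)
    hglze <- 0
    for (a in seq_len(nrow(S))) for (s in seq_len(ncol(S)))
      hglze <- hglze + a^2 * ps[a, s]
    expect_equal(unname(f["GLSZM_HGLZE"]), hglze, tolerance = 1e-10)
    # NGTDM coarseness from the enumeration-built table
    Nm <- oracle_ngtdm(g$levels, g$nb)
    nvc <- sum(Nm[, 1])
    if (nvc > 0) {
      den <- sum(Nm[, 1] / nvc * Nm[, 2])
      coarse <- if (den > 0) 1 / den else 1e6
      expect_equal(unname(f["NGTDM_coarseness"]), coarse, tolerance = 1e-8)
    }
    expect_true(all(is.finite(f)))
  }
})

test_that("intensity and entropy bounds hold for texture probability inputs", {
  set.seed(78)
  for (i in 1:10) {
    g <- random_level_grid()
    f <- texture_features(build_texture_matrices(g$levels, g$nb))
    expect_lte(unname(f["GLCM_joint_entropy"]), 2 * log2(g$nb) + 1e-9)
    expect_gte(unname(f["GLCM_angular_second_moment"]), 0)
    expect_gte(unname(f["GLRLM_run_percentage"]), 0)
    expect_lte(unname(f["GLRLM_run_percentage"]), 1 + 1e-12)
    expect_lte(unname(f["GLSZM_zone_percentage"]), 1 + 1e-12)
    expect_gte(unname(f["GLCM_information_correlation_2"]), 0)
    expect_lte(unname(f["GLCM_information_correlation_2"]), 1)
  }
})
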