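test_that("feature vector has the frozen 354-name panel and is deterministic", {
  nm <- radiomics_feature_names()
  expect_length(nm, 354L)
  expect_false(any(duplicated(nm)))
  s <- generate_phantom("benign", phantom_config(image_size = 64L, seed = 2L),
                        1L)
  f1 <- extract_features(s)
  f2 <- extract_features(s)
  expect_identical(f1, f2)
  expect_length(f1, 354L)
  expect_true(all(is.finite(f1)))
  expect_identical(names(f1), nm)
  expect_error(extract_features(s$image, matrix(0L, 64, 64)), "empty")
})

test_that("GLCM matches exhaustive pair-enumeration on toy rasters", {
  q <- matrix(c(1, 2, 5, 2,
                3, 5, 1, 3,
                5, 5, 5, 1,
                1, 2, 1, 3), 4, 4, byrow = TRUE)
  for (off in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    got <- glcm_matrix(q, off, n_levels = 5L)
    want <- oracle_glcm(q, off[1], off[2], 5L)
    expect_equal(unclass(got), unclass(want), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(got), 1)
  }
  # contrast from the oracle matrix, horizontal offset
  P <- oracle_glcm(q, 0, 1, 5)
  want_contrast <- sum((row(P) - col(P))^2 * P)
  got_contrast <- dualrad:::glcm_features_one(unclass(glcm_matrix(q, c(0L, 1L), 5L)))
  expect_equal(unname(got_contrast["Contrast"]), want_contrast,
               tolerance = 1e-12)

  # checkerboard of two levels: every horizontal pair differs by one
  cb <- (outer(1:6, 1:6, "+") %% 2) + 1
  f <- dualrad:::glcm_features_one(unclass(glcm_matrix(cb, c(0L, 1L), 2L)))
  expect_equal(unname(f["Contrast"]), 1)

  # constant ROI: one nonzero cell, no transitions
  con <- matrix(1, 5, 5)
  M <- glcm_matrix(con, c(0L, 1L), 1L)
  expect_equal(sum(M > 0), 1L, ignore_attr = TRUE)
  expect_equal(unname(dualrad:::glcm_features_one(unclass(M))["Contrast"]), 0)
})

test_that("first-order features hit closed forms on a constant ROI", {
  img <- matrix(0.37, 12, 12)
  msk <- matrix(0L, 12, 12); msk[3:9, 4:10] <- 1L
  f <- extract_features(img, msk)
  expect_equal(unname(f["original_firstorder_Mean"]), 0.37)
  expect_equal(unname(f["original_firstorder_Variance"]), 0)
  expect_equal(unname(f["original_firstorder_Entropy"]), 0)
  expect_equal(unname(f["original_firstorder_Uniformity"]), 1)
  expect_true(all(is.finite(f)))
})

test_that("shape features match geometry on squares and disks", {
  sq <- matrix(0L, 16, 16); sq[4:13, 4:13] <- 1L
  sf <- shape_features_2d(sq)
  expect_equal(unname(sf["PixelSurface"]), 100)
  n <- 64; xs <- (1:n) - 32.5
  disk <- (outer(xs^2, xs^2, "+") <= 400) * 1L
  df <- shape_features_2d(disk)
  ratio <- unname(df["Perimeter"]^2 / df["MeshSurface"])
  expect_lt(abs(ratio - 4 * pi) / (4 * pi), 0.15)
  expect_equal(unname(df["Elongation"]), 1, tolerance = 0.02)
  expect_equal(unname(df["MaximumDiameter"]), 40, tolerance = 0.05 * 40)
  rot <- shape_features_2d(t(disk)[n:1, ])
  expect_equal(sf_r <- unname(rot), unname(df), tolerance = 1e-9)
  expect_error(shape_features_2d(matrix(0L, 4, 4)), "empty")
})

test_that("derived images: 14 rasters, zero LoG on constants, exact impulse", {
  d <- derive_images(matrix(runif(64 * 64), 64, 64))
  expect_length(d, 14L)
  expect_true(all(vapply(d, function(m) all(dim(m) == c(64, 64)), TRUE)))

  dc <- derive_images(matrix(0.8, 48, 48))
  expect_lt(max(abs(dc$log_sigma_1_0)), 1e-10)
  expect_lt(max(abs(dc$log_sigma_3_0)), 1e-10)

  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  k <- dualrad:::log_kernel(1)
  r <- (nrow(k) - 1) / 2
  got <- derive_images(imp, radiomics_config(log_sigmas = 1,
                                             wavelet_levels = 1))$log_sigma_1_0
  expect_lt(max(abs(got[17 + (-r:r), 17 + (-r:r)] - k)), 1e-6)
})

test_that("discretised texture families are affine-intensity invariant", {
  s <- generate_phantom("malignant", phantom_config(image_size = 64L,
                                                    seed = 4L), 2L)
  f1 <- extract_features(s)
  s2 <- s; s2$image <- 0.5 * s$image + 0.1
  f2 <- extract_features(s2)
  tex <- grepl("original_(glcm|gldm|glrlm|glszm|ngtdm)", names(f1)) |
    grepl("original_firstorder_(Entropy|Uniformity)", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-10)
})

test_that("GLCM texture separates benign from malignant phantom classes", {
  af <- accept_features()
  keep <- c(which(af$y == 0)[1:30], which(af$y == 1)[1:30])
  glcm_cols <- grep("original_glcm_", colnames(af$X))
  w <- suppressWarnings(
    per_feature_wilcoxon(af$X[keep, glcm_cols], af$y[keep]))
  expect_lt(min(w$p), 0.05)
})
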