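test_that("write/load round-trip preserves labels and mask supports", {
  coh <- generate_cohort(phantom_config(image_size = 64L, n_benign = 4L,
                                        n_malignant = 3L, n_normal = 3L,
                                        seed = 5L))
  root <- withr::local_tempdir()
  write_cohort(coh, root)
  loaded <- load_dataset(root, target_size = 64L)
  expect_length(loaded, 10L)
  expect_true(all(vapply(loaded, function(s) all(s$mask %in% c(0L, 1L)), TRUE)))
  orig <- coh$samples[order(vapply(coh$samples, `[[`, "", "id"))]
  got <- loaded[order(vapply(loaded, `[[`, "", "id"))]
  for (k in seq_along(orig)) {
    expect_equal(got[[k]]$label, orig[[k]]$label)
    expect_identical(unname(got[[k]]$mask), unname(orig[[k]]$mask))
  }
})

test_that("missing abnormal mask is an error naming the case", {
  coh <- generate_cohort(phantom_config(image_size = 64L, n_benign = 2L,
                                        n_malignant = 0L, n_normal = 0L,
                                        seed = 2L))
  root <- withr::local_tempdir()
  write_cohort(coh, root)
  victim <- coh$samples[[1]]$id
  unlink(file.path(root, "benign", paste0(victim, "_mask.png")))
  expect_error(load_dataset(root, 64L), victim)
})

test_that("mask resize preserves binarity and connectivity", {
  coh <- generate_cohort(phantom_config(image_size = 32L, n_benign = 5L,
                                        n_malignant = 0L, n_normal = 0L,
                                        seed = 9L))
  root <- withr::local_tempdir()
  write_cohort(coh, root)
  big <- load_dataset(root, target_size = 64L)
  for (k in seq_along(big)) {
    expect_true(all(big[[k]]$mask %in% c(0L, 1L)))
    before <- oracle_n_components(coh$samples[[k]]$mask)
    after <- oracle_n_components(big[[k]]$mask)
    expect_equal(after, before)
  }
})

test_that("splits have requested sizes, are disjoint and deterministic", {
  stub <- function(i, lab) structure(list(id = paste0(lab, i), label = lab),
                                     class = "ultrasound_sample")
  samples <- c(lapply(1:437, stub, "benign"), lapply(1:210, stub, "malignant"),
               lapply(1:133, stub, "normal"))
  sp <- split_dataset(samples, 635L, 145L, seed = 4L)
  expect_length(sp$train, 635L)
  expect_length(sp$test, 145L)
  ids <- function(l) vapply(l, `[[`, "", "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  sp2 <- split_dataset(samples, 635L, 145L, seed = 4L)
  expect_identical(ids(sp$train), ids(sp2$train))

  e <- split_dataset(samples, 0L, 10L, seed = 1L)
  expect_length(e$train, 0L)
  expect_length(e$test, 10L)
  expect_error(split_dataset(samples, 700L, 145L, seed = 1L), "exceed")
})

test_that("stratified splits preserve class ratios within one case", {
  stub <- function(i, lab) structure(list(id = paste0(lab, i), label = lab),
                                     class = "ultrasound_sample")
  samples <- c(lapply(1:40, stub, "benign"), lapply(1:20, stub, "malignant"))
  sp <- split_dataset(samples, 30L, 30L, seed = 8L, stratify = TRUE)
  for (part in sp) {
    tab <- table(vapply(part, `[[`, "", "label"))
    expect_equal(unname(tab["benign"]), 20, tolerance = 0, ignore_attr = TRUE)
    expect_true(abs(tab[["benign"]] - 2 * tab[["malignant"]]) <= 2)
  }
})
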