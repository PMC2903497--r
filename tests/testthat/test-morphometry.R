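test_that("green channel projection ignores red and blue", {
  expect_equal(green_channel_grey(flat_rgb(4, 5, 255, 0, 0)),
               matrix(0, 4, 5))
  expect_equal(green_channel_grey(flat_rgb(4, 5, 0, 255, 0)),
               matrix(255, 4, 5))
  set.seed(11)
  arr <- array(sample(0:255, 6 * 7 * 3, replace = TRUE), dim = c(6, 7, 3))
  expect_equal(green_channel_grey(rgb_image(arr)), arr[, , 2] + 0)
})

test_that("mean blur matches the brute-force windowed mean", {
  m <- matrix(0, 3, 3); m[2, 2] <- 9
  expect_equal(mean_blur(m, 3)[2, 2], 1)
  expect_equal(mean_blur(m, 1), m)                  # window 1 is identity
  const <- matrix(42, 8, 9)
  expect_equal(mean_blur(const, 5), const)
  set.seed(21)
  r <- matrix(runif(12 * 10, 0, 255), 12, 10)
  for (k in c(3L, 5L)) {
    expect_equal(mean_blur(r, k), box_mean_brute(r, k), tolerance = 1e-12)
  }
  expect_error(mean_blur(r, 4), class = "fibromat_bad_config")
  expect_error(mean_blur(r, -1), class = "fibromat_bad_config")
})

test_that("shading correction flattens a known multiplicative field", {
  const <- matrix(77, 40, 40)
  expect_equal(correct_shading(const, 15), const)
  expect_equal(correct_shading(const, 15, method = "median"), const)

  # flat tissue level times a smooth illumination field; the oracle is the
  # exact pixelwise division by the known field
  n <- 160
  u <- matrix(seq(0, 1, length.out = n), n, n)
  f <- 1 + 0.3 * cos(pi * u) * cos(pi * t(u))      # within [0.7, 1.3]
  img <- 150 * f
  for (meth in c("mean", "median")) {
    corr <- correct_shading(img, 41, method = meth)
    interior <- corr[40:(n - 40), 40:(n - 40)]
    expect_lt(mean(abs(interior - 150)), 2)
  }

  # an impulse only perturbs the output near itself: the illumination
  # estimate is smooth
  imp <- matrix(100, 60, 60); imp[30, 30] <- 255
  corr <- correct_shading(imp, 21)
  far <- abs(corr - imp); far[15:45, 15:45] <- 0
  expect_lt(max(far), 0.5)

  expect_error(correct_shading(matrix(1, 10, 10), 21),
               class = "fibromat_bad_config")    # window exceeds image
  expect_error(correct_shading(const, 14), class = "fibromat_bad_config")
})

test_that("background mask is a brightness cutoff", {
  white <- matrix(255, 6, 6)
  expect_true(all(background_mask(white, 240)))
  expect_false(any(background_mask(matrix(128, 6, 6), 240)))
  # exactly-at-cutoff pixels are background
  expect_true(all(background_mask(matrix(240, 2, 2), 240)))
})

test_that("background mask recovers a planted lumen disc", {
  fld <- synthesize_field(synthetic_spec(0.01, width = 640, height = 512,
                                         lumen_count = 1, seed = 33))
  grey <- correct_shading(green_channel_grey(fld$image), 127,
                          method = "median")
  bg <- background_mask(grey, 240)
  truth <- fld$lumen_truth
  iou <- sum(bg & truth) / sum(bg | truth)
  expect_gte(iou, 0.95)
})

test_that("histogram threshold maximizes between-class variance over tissue", {
  # two-valued tissue: 30% at 50, 70% at 200
  v <- c(rep(50, 300), rep(200, 700))
  grey <- matrix(v, 25, 40)
  tissue <- matrix(TRUE, 25, 40)
  thr <- histogram_threshold(grey, tissue)
  expect_gt(thr, 50)
  expect_lt(thr, 200)
  expect_equal(thr, otsu_brute(v))
  # additive offset contract
  expect_equal(histogram_threshold(grey, tissue, threshold_offset = 10),
               thr + 10)
  # the midpoint refinement lands between the class means
  mid <- histogram_threshold(grey, tissue, refine = "midpoint")
  expect_equal(mid, (50 + 200) / 2)
  # degenerate single-valued tissue
  expect_error(histogram_threshold(matrix(128, 5, 5), matrix(TRUE, 5, 5)),
               class = "fibromat_degenerate_histogram")
  expect_error(histogram_threshold(grey, matrix(FALSE, 25, 40)),
               class = "fibromat_no_tissue")
})

test_that("binarize_dark selects dark tissue pixels only", {
  grey <- matrix(c(50, 200, 50, 200), 2, 2)
  tissue <- matrix(TRUE, 2, 2)
  expect_equal(binarize_dark(grey, 120, tissue), grey <= 120)
  expect_true(all(binarize_dark(grey, 255, tissue)))
  expect_false(any(binarize_dark(grey, 10, tissue)))
  # background pixels never positive
  tissue[1, 1] <- FALSE
  expect_false(binarize_dark(grey, 255, tissue)[1, 1])
})

test_that("object labelling honours connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE                 # diagonal touch
  lab8 <- label_objects(m, 8)
  lab4 <- label_objects(m, 4)
  expect_equal(nrow(lab8$records), 1L)
  expect_equal(lab8$records$area, 2L)
  expect_equal(nrow(lab4$records), 2L)
  expect_equal(lab4$records$area, c(1L, 1L))

  empty <- label_objects(matrix(FALSE, 5, 5), 8)
  expect_equal(nrow(empty$records), 0L)

  # three disjoint rectangles of known areas
  m2 <- matrix(FALSE, 20, 20)
  m2[1:2, 1:2] <- TRUE; m2[5:7, 5:7] <- TRUE; m2[10:14, 10:14] <- TRUE
  lab <- label_objects(m2, 8)
  expect_setequal(lab$records$area, c(4L, 9L, 25L))
  expect_equal(sum(lab$records$area), sum(m2))
  # bounding boxes contain their objects
  for (i in seq_len(nrow(lab$records))) {
    r <- lab$records[i, ]
    px <- which(lab$labels == r$label, arr.ind = TRUE)
    expect_true(all(px[, 1] >= r$row_min & px[, 1] <= r$row_max))
    expect_true(all(px[, 2] >= r$col_min & px[, 2] <= r$col_max))
  }
})

test_that("small-object filtering removes nuclei-sized objects", {
  m <- matrix(FALSE, 30, 40)
  m[2:6, 2:6] <- TRUE                               # 25 px
  m[10:25, 10:25] <- TRUE                           # 256 px
  lab <- label_objects(m, 8)
  kept <- filter_small_objects(lab$labels, lab$records, 200)
  expect_equal(sum(kept), 256)
  expect_equal(filter_small_objects(lab$labels, lab$records, 0), m)
  expect_false(any(filter_small_objects(lab$labels, lab$records, 1e6)))
})

test_that("exclusions remove objects from numerator and denominator", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE; m[7:9, 7:9] <- TRUE
  lab <- label_objects(m, 8)
  tissue <- matrix(TRUE, 10, 10)

  none <- apply_exclusions(m, lab$labels, integer(), NULL, tissue)
  expect_equal(none$fibres, m)
  expect_equal(none$excluded_area, 0L)

  all_out <- apply_exclusions(m, lab$labels, lab$records$label, NULL, tissue)
  expect_false(any(all_out$fibres))
  expect_equal(all_out$excluded_area, sum(m))

  expect_error(apply_exclusions(m, lab$labels, 99L, NULL, tissue),
               class = "fibromat_unknown_object")
  expect_match(tryCatch(apply_exclusions(m, lab$labels, 99L),
                        error = conditionMessage), "99")
})

test_that("fibrosis index is the fibre share of parenchyma", {
  expect_equal(fibrosis_index(0, 100000), 0)
  expect_equal(fibrosis_index(100000, 100000), 1)
  expect_equal(fibrosis_index(4750, 100000), 0.0475)
  expect_error(fibrosis_index(10, 0), class = "fibromat_no_tissue")
  expect_error(fibrosis_index(11, 10), class = "fibromat_bad_config")
})

test_that("overlay partitions the field into the three display colours", {
  tissue <- matrix(FALSE, 8, 8); tissue[2:7, 2:7] <- TRUE
  fibres <- matrix(FALSE, 8, 8); fibres[3:4, 3:5] <- TRUE
  ov <- render_overlay(tissue, fibres)
  px <- matrix(paste(ov[, , 1], ov[, , 2], ov[, , 3]), 8, 8)
  counts <- table(px)
  expect_equal(unname(counts[["255 0 0"]]), sum(fibres))
  expect_equal(unname(counts[["144 238 144"]]), sum(tissue) - sum(fibres))
  expect_equal(unname(counts[["0 0 0"]]), sum(!tissue))
  expect_equal(sum(counts), 64)

  black <- render_overlay(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_true(all(black == 0))
  expect_error(render_overlay(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3)),
               class = "fibromat_bad_image")
})

test_that("analyze_field recovers a planted fraction and is deterministic", {
  fld <- synthesize_field(synthetic_spec(0.02, width = 640, height = 512,
                                         seed = 91))
  r1 <- analyze_field(fld$image)
  expect_lt(abs(r1$fibrosis_index - 0.02), 0.005)
  r2 <- analyze_field(fld$image)
  expect_identical(unclass(r1), unclass(r2))

  expect_error(analyze_field(flat_rgb(64, 64, 255, 255, 255)),
               class = "fibromat_no_tissue")
  expect_error(analyze_field(flat_rgb(64, 64, 128, 128, 128)),
               class = "fibromat_degenerate_histogram")
})

test_that("excluding a fibre object matches direct recomputation", {
  fld <- small_field(0.03, seed = 55)
  base <- analyze_field(fld$image, keep_masks = TRUE)
  fibre_labels <- sort(unique(base$masks$labels[base$masks$fibres]))
  expect_gt(length(fibre_labels), 0)
  drop <- fibre_labels[1]
  obj_px <- sum(base$masks$labels == drop & base$masks$fibres)
  excl <- analyze_field(fld$image, exclude_ids = drop)
  expect_equal(excl$fibre_area, base$fibre_area - obj_px)
  expect_equal(excl$parenchyma_area, base$parenchyma_area - obj_px)
  expect_equal(excl$fibrosis_index,
               (base$fibre_area - obj_px) / (base$parenchyma_area - obj_px))
  expect_lte(excl$fibrosis_index, base$fibrosis_index)
})
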