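test_that("nucleus detection finds planted nuclei and is scale-free", {
  # blank DAPI -> zero cells with a warning
  blank <- list(channels = list(DAPI = matrix(100, 64, 64)))
  class(blank) <- "field_image"
  expect_warning(nuc0 <- detect_nuclei(blank), "flat")
  expect_equal(nuc0$n, 0)

  # noiseless field: every planted nucleus found within 2 px
  f <- generate_field(tiny_spec(background_sd = 0, seed = 6))
  nuc <- detect_nuclei(f)
  tc <- f$truth$cells
  expect_equal(nuc$n, nrow(tc))
  d <- vapply(seq_len(nrow(tc)), function(i) {
    min(sqrt((nuc$centroids$x - tc$x[i])^2 + (nuc$centroids$y - tc$y[i])^2))
  }, numeric(1))
  expect_lt(max(d), 2)
  # masks disjoint
  expect_false(any(duplicated(unlist(nuc$masks))))

  # detection count invariant to uniform intensity rescaling
  f2 <- f
  f2$channels$DAPI <- f$channels$DAPI * 2
  expect_equal(detect_nuclei(f2)$n, nuc$n)
})

test_that("dense cloud matches truth and excludes isolated stromal cells", {
  # saturated case: a field that is entirely tumour
  full <- generate_field(field_spec(width_px = 256, height_px = 256,
                                    n_tumour_cells = 85, n_stroma_cells = 0,
                                    front_position = 0.99,
                                    front_amplitude_px = 1, seed = 2))
  # no stroma means no background class for the automatic cutoff, so a
  # saturated field uses the explicit grey-level override
  m_full <- build_dense_cloud(full,
                              dense_cloud_params(intensity_cutoff = 500))
  truth <- full$truth$tumour_mask
  expect_gt(sum(m_full & truth) / sum(truth), 0.95)

  # boundary field: Jaccard overlap with ground truth
  f <- generate_field(tiny_spec(planted_triple_positive_density = 40,
                                seed = 4))
  m <- build_dense_cloud(f)
  jac <- sum(m & f$truth$tumour_mask) / sum(m | f$truth$tumour_mask)
  expect_gte(jac, 0.8)

  # planted stromal cells far from the front stay outside the mask
  tp <- f$truth$cells[f$truth$cells$class == "triple_pos", ]
  if (nrow(tp) > 0) {
    px <- cbind(floor(tp$y) + 1, floor(tp$x) + 1)
    expect_false(any(m[px]))
  }

  # cutoff above the channel maximum -> empty mask with warning
  expect_warning(
    m0 <- build_dense_cloud(f, dense_cloud_params(intensity_cutoff = 1e9)),
    "cutoff")
  expect_false(any(m0))
})

test_that("region assignment partitions cells and matches ground truth", {
  cells <- data.frame(x = c(1, 10, 30), y = c(1, 10, 30))
  empty <- matrix(FALSE, 40, 40); full <- matrix(TRUE, 40, 40)
  expect_true(all(assign_regions(cells, empty)$region == "stroma"))
  expect_true(all(assign_regions(cells, full)$region == "tumour"))

  f <- generate_field(tiny_spec(background_sd = 0, seed = 12))
  q_mask <- build_dense_cloud(f)
  nuc <- detect_nuclei(f)
  cells <- assign_regions(extract_intensities(f, nuc), q_mask)
  expect_equal(nrow(cells), nrow(f$truth$cells))
  # every cell labelled exactly once
  expect_true(all(cells$region %in% c("tumour", "stroma")))
  # cells far from the front match generator truth
  tc <- f$truth$cells
  i <- vapply(seq_len(nrow(cells)), function(j)
    which.min((tc$x - cells$x[j])^2 + (tc$y - cells$y[j])^2), integer(1))
  phases <- local({set.seed(12); runif(3, 0, 2 * pi)})
  dist_front <- abs(tc$x[i] - emtseek:::front_curve(f$spec, phases, tc$y[i]))
  far <- dist_front > 3 * dense_cloud_params()$dilation_radius_px + 20
  expect_true(all(cells$region[far] == tc$region[i][far]))
})

test_that("intensity extraction equals a brute-force pixel loop", {
  # uniform channel: every cell measures exactly the channel value
  f <- generate_field(tiny_spec(background_sd = 0, seed = 3))
  u <- f
  u$channels$FITC <- matrix(123, 352, 352)
  nuc <- detect_nuclei(u)
  cells <- extract_intensities(u, nuc)
  expect_true(all(cells$grey_FITC == 123))

  # single synthetic cell on zero background measured through hand-made mask
  chan <- matrix(0, 64, 64)
  idx <- emtseek:::disc_pixels(30, 30, 7, 64, 64)
  chan[idx] <- 500
  sf <- structure(list(channels = list(DAPI = chan, FITC = chan,
                                       CY3 = chan, CY5 = chan)),
                  class = "field_image")
  hand <- list(masks = list(emtseek:::disc_pixels(30, 30, 7, 64, 64)),
               centroids = data.frame(x = 30, y = 30))
  got <- extract_intensities(sf, hand, dilate_px = 0)
  expect_equal(got$grey_CY3, 500)

  # random field: means equal an explicit pixel-loop recomputation
  f <- generate_field(tiny_spec(seed = 31, n_tumour_cells = 8,
                                n_stroma_cells = 8))
  hand_masks <- lapply(seq_len(nrow(f$truth$cells)), function(i)
    emtseek:::disc_pixels(f$truth$cells$x[i], f$truth$cells$y[i], 7,
                          352, 352))
  nuc <- list(masks = hand_masks,
              centroids = f$truth$cells[, c("x", "y")])
  got <- extract_intensities(f, nuc, dilate_px = 0)
  bf <- bf_cell_means(f, as.matrix(f$truth$cells[, c("x", "y")]), 7)
  expect_equal(unname(as.matrix(got[, c("grey_FITC", "grey_CY3",
                                        "grey_CY5")])),
               unname(bf))

  # out-of-bounds mask is clipped with a warning
  oob <- list(masks = list(c(-5L, 1L, 2L)),
              centroids = data.frame(x = 0, y = 0))
  expect_warning(extract_intensities(sf, oob, dilate_px = 0), "clipped")
})

test_that("thresholds are exactly multiplier x pooled per-cell median", {
  ctrl_cells <- data.frame(grey_FITC = c(90, 100, 110),
                           grey_CY3 = c(70, 80, 90),
                           grey_CY5 = c(50, 60, 70))
  ts <- compute_thresholds(ctrl_cells)
  expect_equal(unname(ts$thresholds), c(150, 120, 90))
  ts1 <- compute_thresholds(ctrl_cells, multiplier = 1)
  expect_equal(unname(ts1$thresholds), c(100, 80, 60))

  # pooling across control fields equals the median of concatenated values
  ctrls <- lapply(1:3, function(s)
    generate_negative_control(tiny_spec(seed = s, background_sd = 30)))
  pooled <- compute_thresholds(ctrls)
  vals <- do.call(rbind, lapply(ctrls, function(f)
    extract_intensities(f, detect_nuclei(f))))
  for (ch in c("FITC", "CY3", "CY5")) {
    v <- sort(vals[[paste0("grey_", ch)]])
    n <- length(v)
    bf_med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(unname(pooled$thresholds[ch]), 1.5 * bf_med)
  }
  expect_error(compute_thresholds(ctrl_cells[0, ]), "no cells")
})

test_that("positivity calls use strict inequality and are scale-equivariant", {
  thr <- c(FITC = 150, CY3 = 120, CY5 = 90)
  cells <- data.frame(grey_FITC = c(151, 150), grey_CY3 = c(121, 200),
                      grey_CY5 = c(91, 200))
  got <- classify_cells(cells, thr)
  expect_equal(got$triple_positive, c(1L, 0L))
  expect_equal(got$double_positive, c(0L, 1L))  # FITC tie is negative
  # triple and double are mutually exclusive
  expect_true(all(got$triple_positive + got$double_positive <= 1))

  # 1000 random cells: calls equal brute-force re-evaluation and are
  # invariant to multiplying greys and thresholds by a constant
  rc <- random_cells(1000, seed = 2)
  got <- classify_cells(rc, thr)
  bf_triple <- as.integer(rc$grey_FITC > 150 & rc$grey_CY3 > 120 &
                            rc$grey_CY5 > 90)
  bf_double <- as.integer(rc$grey_FITC <= 150 & rc$grey_CY3 > 120 &
                            rc$grey_CY5 > 90)
  expect_identical(got$triple_positive, bf_triple)
  expect_identical(got$double_positive, bf_double)
  rc2 <- rc
  for (col in c("grey_FITC", "grey_CY3", "grey_CY5"))
    rc2[[col]] <- rc2[[col]] * 7
  got2 <- classify_cells(rc2, thr * 7)
  expect_identical(got2$triple_positive, got$triple_positive)
  expect_identical(got2$double_positive, got$double_positive)

  expect_error(classify_cells(rc[, -3], thr), "missing")
})

test_that("raising the multiplier never increases positive calls", {
  ctrls <- generate_negative_control(tiny_spec(seed = 20, background_sd = 40))
  f <- generate_field(tiny_spec(planted_triple_positive_density = 80,
                                seed = 21))
  cells <- extract_intensities(f, detect_nuclei(f))
  prev <- Inf
  for (mult in c(1, 1.5, 2, 5)) {
    thr <- compute_thresholds(ctrls, multiplier = mult)
    n_pos <- sum(classify_cells(cells, thr)$triple_positive)
    expect_lte(n_pos, prev)
    prev <- n_pos
  }
})

test_that("field QC implements the fraction-of-median rule", {
  sums <- data.frame(field_id = c("a", "b", "c"),
                     n_cells = c(100, 90, 15))
  kept <- qc_filter_fields(sums, 0.2)
  expect_setequal(kept$field_id, c("a", "b"))  # median 90, cutoff 18
  expect_equal(nrow(qc_filter_fields(sums, 0)), 3)

  # 200 random counts match a brute-force filter; retention monotone in
  # min_fraction
  set.seed(5)
  sums <- data.frame(field_id = sprintf("f%03d", 1:200),
                     n_cells = rpois(200, 60))
  prev <- Inf
  for (mf in c(0.1, 0.2, 0.5, 0.9)) {
    kept <- qc_filter_fields(sums, mf)
    bf <- sums$field_id[sums$n_cells >= mf * median(sums$n_cells)]
    expect_setequal(kept$field_id, bf)
    expect_lte(nrow(kept), prev)
    prev <- nrow(kept)
  }

  # exclusion blacklist and the all-excluded error
  kept <- qc_filter_fields(sums, 0.2, exclude = "f001")
  expect_false("f001" %in% kept$field_id)
  expect_error(qc_filter_fields(data.frame(field_id = "x", n_cells = 10),
                                exclude = "x"), "all fields excluded")
})

test_that("field summaries report proportions per region, NA when empty", {
  cells <- data.frame(region = rep("stroma", 10),
                      triple_positive = c(1, rep(0, 9)),
                      double_positive = 0)
  s <- summarize_field(cells)
  expect_equal(s$prop_stroma_triple, 0.1)
  expect_true(is.na(s$prop_tumour_triple))  # no tumour cells: missing
  expect_equal(s$n_cells, s$n_tumour + s$n_stroma)

  # noiseless synthetic field: summary equals generator ground truth
  f <- generate_field(tiny_spec(background_sd = 0,
                                planted_triple_positive_density = 60,
                                planted_double_positive_density = 40,
                                seed = 14))
  ctrl <- generate_negative_control(tiny_spec(background_sd = 0, seed = 15))
  q <- quantify_field(f, compute_thresholds(ctrl))
  tc <- f$truth$cells
  expect_equal(q$summary$stroma_triple, sum(tc$class == "triple_pos"))
  expect_equal(q$summary$stroma_double, sum(tc$class == "double_pos"))
  expect_equal(q$summary$tumour_triple + q$summary$tumour_double, 0)
  expect_equal(q$summary$n_cells, nrow(tc))
})

test_that("field TIFF round-trips through disk with channel metadata", {
  f <- generate_field(tiny_spec(seed = 17))
  path <- file.path(tempdir(), "field.tif")
  write_field_tiff(f, path)
  g <- read_field_tiff(path)
  for (ch in c("DAPI", "FITC", "CY3", "CY5"))
    expect_equal(g$channels[[ch]], unname(f$channels[[ch]]))
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json"),
           file.path(tempdir(), "field_truth_mask.tif")))
})
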