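test_that("max_project equals the per-pixel maximum over z", {
  set.seed(1)
  vox <- array(sample(0:255, 1 * 26 * 9 * 7, replace = TRUE),
               dim = c(1, 26, 9, 7))
  f <- image_field(vox, "telomere", bit_depth = 8)
  p <- max_project(f, "telomere")
  # explicit triple loop
  ref <- matrix(0, 9, 7)
  for (y in 1:9) for (x in 1:7) {
    mx <- -Inf
    for (z in 1:26) mx <- max(mx, vox[1, z, y, x])
    ref[y, x] <- mx
  }
  expect_equal(unclass(p)[, ], ref, ignore_attr = TRUE)
  # constant stack projects to the constant
  fc <- image_field(array(9, dim = c(1, 3, 4, 4)), "pml", bit_depth = 8)
  expect_true(all(max_project(fc, "pml") == 9))
  expect_error(max_project(f, "edu"), "not present")
})

test_that("tophat matches the brute-force opening on random images", {
  set.seed(2)
  for (r in c(1, 2, 4)) {
    for (rep in 1:3) {
      m <- matrix(runif(32 * 32, 0, 100), 32, 32)
      expect_equal(as_mat(tophat_subtract(m, r)), brute_tophat(m, r),
                   tolerance = 1e-10)
    }
  }
})

test_that("tophat removes flat structure and keeps point sources", {
  # constant image -> all zeros
  expect_true(all(tophat_subtract(matrix(5, 20, 20), 3) == 0))
  # single bright pixel survives intact
  m <- matrix(0, 21, 21); m[11, 11] <- 42
  th <- tophat_subtract(m, 2)
  expect_equal(th[11, 11], 42)
  # interior of a wide plateau maps to 0
  m2 <- matrix(0, 30, 30); m2[8:24, 8:24] <- 10
  th2 <- tophat_subtract(m2, 3)
  expect_true(all(th2[12:20, 12:20] == 0))
  expect_error(tophat_subtract(m, 0), ">= 1")
})

test_that("find_maxima matches the exhaustive prominence-flood oracle", {
  set.seed(3)
  for (rep in 1:8) {
    m <- random_smooth_image(24, 24)
    for (prom in c(0.2, 0.5, 1)) {
      got <- find_maxima(m, prom)
      ref <- brute_maxima_with_prominence(m, prom)
      expect_equal(unname(got), unname(ref))
    }
  }
})

test_that("find_maxima handles flat images, single peaks and twin peaks", {
  expect_identical(nrow(find_maxima(matrix(7, 15, 15), 1)), 0L)
  # one Gaussian spot -> exactly its center
  m <- 100 * exp(-(outer((1:41 - 20)^2, (1:61 - 30)^2, "+")) / (2 * 4))
  pk <- find_maxima(m, 10)
  expect_equal(unname(pk), matrix(c(20L, 30L), 1))
  # two equal peaks with a saddle between them: prominence gates the count
  m2 <- 100 * exp(-(outer((1:20 - 10)^2, (1:40 - 16)^2, "+")) / (2 * 9)) +
    100 * exp(-(outer((1:20 - 10)^2, (1:40 - 24)^2, "+")) / (2 * 9))
  valley <- m2[10, 20]
  peak <- m2[10, 16]
  expect_identical(nrow(find_maxima(m2, peak - valley + 1)), 1L)
  expect_identical(nrow(find_maxima(m2, peak - valley - 1)), 2L)
  expect_error(find_maxima(m2, 0), "positive")
})

test_that("a plateau of equal maxima collapses to its centroid pixel", {
  m <- matrix(0, 15, 15)
  m[6:8, 4:8] <- 5    # 3 x 5 plateau centered at (7, 6)
  pk <- find_maxima(m, 1)
  expect_equal(unname(pk), matrix(c(7L, 6L), 1))
})

test_that("maxima are shift-invariant and transpose-equivariant", {
  set.seed(4)
  for (rep in 1:5) {
    m <- random_smooth_image(28, 20)
    pk <- find_maxima(m, 0.3)
    expect_equal(find_maxima(m + 17.3, 0.3), pk)
    pt <- find_maxima(t(m), 0.3)
    flipped <- pt[, c(2, 1), drop = FALSE]
    expect_equal(flipped[order(flipped[, 1], flipped[, 2]), , drop = FALSE],
                 unname(pk), ignore_attr = TRUE)
  }
})

test_that("raising prominence never increases the number of maxima", {
  set.seed(5)
  for (rep in 1:5) {
    m <- random_smooth_image(32, 32, n_bumps = 6)
    n <- vapply(c(0.05, 0.2, 0.5, 1, 2),
                function(p) nrow(find_maxima(m, p)), integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("segment_foci: single-spot area matches the threshold oracle", {
  m <- 80 * exp(-(outer((1:41 - 21)^2, (1:41 - 21)^2, "+")) / (2 * 6.25))
  pk <- find_maxima(m, 10)
  fs <- segment_foci(m, pk, detection_params(peak_fraction = 0.5,
                                             min_focus_area_px = 1))
  expect_identical(nrow(fs$objects), 1L)
  expect_identical(fs$objects$area_px, sum(m >= 0.5 * max(m)))
  expect_equal(fs$objects$y, 21, tolerance = 0.01)
})

test_that("segment_foci separates spots and filters small objects", {
  m <- 60 * exp(-(outer((1:30 - 10)^2, (1:50 - 12)^2, "+")) / 8) +
    90 * exp(-(outer((1:30 - 20)^2, (1:50 - 38)^2, "+")) / 8)
  pk <- find_maxima(m, 10)
  fs <- segment_foci(m, pk, detection_params(min_focus_area_px = 2))
  expect_identical(nrow(fs$objects), 2L)
  # each mask is nonempty and contains its own peak
  expect_true(all(tabulate(fs$labels[fs$labels > 0], 2) ==
                    fs$objects$area_px))
  for (i in 1:2)
    expect_identical(fs$labels[fs$objects$peak_y[i], fs$objects$peak_x[i]],
                     fs$objects$label[i])
  # a min area larger than any object empties the set
  fs2 <- segment_foci(m, pk, detection_params(min_focus_area_px = 10000))
  expect_identical(nrow(fs2$objects), 0L)
  # peaks must be genuine local maxima
  expect_error(segment_foci(m, matrix(c(1L, 1L), 1), detection_params()),
               "local maximum")
})

test_that("contested pixels between twin peaks are split by watershed", {
  m <- 50 * exp(-(outer((1:21 - 11)^2, (1:40 - 15)^2, "+")) / (2 * 9)) +
    50 * exp(-(outer((1:21 - 11)^2, (1:40 - 25)^2, "+")) / (2 * 9))
  pk <- find_maxima(m, 3)
  expect_identical(nrow(pk), 2L)
  fs <- segment_foci(m, pk, detection_params(peak_fraction = 0.8))
  expect_identical(nrow(fs$objects), 2L)
  # split is symmetric about the midline x = 20
  left <- fs$labels[, 1:19]; right <- fs$labels[, 21:40]
  expect_identical(sum(left == 1), sum(right == 2))
})

test_that("segment_nuclei finds ellipses and applies the border rule", {
  m <- matrix(0, 120, 120)
  yy <- matrix(1:120, 120, 120); xx <- t(yy)
  m[((yy - 35)^2 / 15^2 + (xx - 35)^2 / 11^2) <= 1] <- 200
  m[((yy - 85)^2 / 13^2 + (xx - 85)^2 / 16^2) <= 1] <- 220
  nm <- segment_nuclei(m, min_area_px = 100)
  expect_identical(nrow(nm$table), 2L)
  expect_identical(nm$excluded_border_count, 0L)
  # one ellipse crossing the border: excluded but counted
  m2 <- matrix(0, 120, 120)
  m2[((yy - 3)^2 / 15^2 + (xx - 60)^2 / 12^2) <= 1] <- 200
  nm2 <- segment_nuclei(m2, min_area_px = 100)
  expect_identical(nrow(nm2$table), 0L)
  expect_identical(nm2$excluded_border_count, 1L)
  # all-zero image: empty map, not an error
  nm3 <- segment_nuclei(matrix(0, 50, 50))
  expect_identical(nrow(nm3$table), 0L)
})

test_that("simulated nuclei are recovered one-for-one at default SNR", {
  cfg <- test_config(channels = c("dapi", "telomere"))
  sim <- simulate_field(cfg, "nuc", seed = 77)
  nm <- segment_nuclei(max_project(sim$field, "dapi"))
  expect_identical(nrow(nm$table), nrow(sim$truth$cells))
  # every detected nucleus centroid sits near a distinct true center
  d <- outer(nm$table$cy, sim$truth$cells$center_y, "-")^2 +
    outer(nm$table$cx, sim$truth$cells$center_x, "-")^2
  nearest <- apply(sqrt(d), 1, which.min)
  expect_identical(sort(nearest), seq_len(nrow(sim$truth$cells)))
  expect_true(all(apply(sqrt(d), 1, min) < 4))
})

test_that("assign_foci maps centroids to nuclei and drops background foci", {
  lab <- matrix(0L, 30, 30)
  lab[5:12, 5:12] <- 1L; lab[18:26, 15:25] <- 2L
  nm <- nucleus_map(lab, data.frame(label = 1:2, area_px = c(64, 99),
                                    cy = c(8.5, 22), cx = c(8.5, 20),
                                    y0 = c(5, 18), x0 = c(5, 15),
                                    y1 = c(12, 26), x1 = c(12, 25)))
  flab <- matrix(0L, 30, 30)
  flab[8, 8] <- 1L; flab[20, 20] <- 2L; flab[2, 28] <- 3L
  fs <- foci_from_labels(flab, "telomere")
  asg <- assign_foci(fs, nm)
  expect_identical(asg$assignment, c(1L, 2L, 0L))
  expect_identical(asg$dropped, 1L)
  bad <- nucleus_map(matrix(0L, 10, 10), nm$table)
  expect_error(assign_foci(fs, bad), "geometries")
})

test_that("per-cell assignment agrees with simulator truth", {
  cfg <- test_config(apb_prob = 0.2)
  sim <- simulate_field(cfg, "asg", seed = 13)
  nm <- segment_nuclei(max_project(sim$field, "dapi"))
  tel <- detect_foci(sim$field, "telomere")
  asg <- assign_foci(tel, nm)
  # map detected nuclei to true cells by centroid
  d <- outer(nm$table$cy, sim$truth$cells$center_y, "-")^2 +
    outer(nm$table$cx, sim$truth$cells$center_x, "-")^2
  nuc_to_cell <- apply(d, 1, which.min)
  tru <- sim$truth$foci[sim$truth$foci$channel_role == "telomere", ]
  ok <- 0; tot <- 0
  for (i in seq_len(nrow(tel$objects))) {
    if (asg$assignment[i] == 0) next
    dd <- (tru$y - tel$objects$y[i])^2 + (tru$x - tel$objects$x[i])^2
    j <- which.min(dd)
    if (dd[j] < 4) {
      tot <- tot + 1
      if (tru$cell_id[j] == nuc_to_cell[asg$assignment[i]]) ok <- ok + 1
    }
  }
  expect_gt(tot, 50)
  expect_gte(ok / tot, 0.99)
})

test_that("detect_foci auto-threshold scales with robust image noise", {
  cfg <- test_config(telomere_count_mean = 10)
  sim <- simulate_field(cfg, "auto", seed = 19)
  fs <- detect_foci(sim$field, "telomere", detection_params(k = 7))
  th <- tophat_subtract(max_project(sim$field, "telomere"), 5)
  expect_equal(attr(fs, "prominence"), 7 * mad(as.numeric(th)))
})
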