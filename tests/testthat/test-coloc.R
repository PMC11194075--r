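test_that("colocalize matches the all-pairs intersection oracle", {
  set.seed(6)
  for (rep in 1:30) {
    a <- foci_from_labels(random_label_image(n_obj = sample(1:20, 1)), "telomere")
    b <- foci_from_labels(random_label_image(n_obj = sample(1:20, 1)), "pml")
    got <- colocalize(a, b)
    ref <- brute_coloc(a, b)
    expect_equal(got$channel_a_label, ref$channel_a_label)
    expect_equal(got$channel_b_label, ref$channel_b_label)
    expect_equal(got$overlap_area_px, ref$overlap_area_px)
  }
})

test_that("colocalize basics: disjoint, identical and spanning objects", {
  la <- matrix(0L, 10, 10); la[2:3, 2:3] <- 1L
  lb <- matrix(0L, 10, 10); lb[7:8, 7:8] <- 1L
  a <- foci_from_labels(la); b <- foci_from_labels(lb)
  expect_identical(nrow(colocalize(a, b)), 0L)
  # identical masks: one pair, full overlap, zero distance
  same <- colocalize(a, foci_from_labels(la))
  expect_identical(nrow(same), 1L)
  expect_identical(same$overlap_area_px, 4L)
  expect_equal(same$centroid_distance_px, 0)
  # one b-object spanning two a-objects: exactly two pairs
  la2 <- matrix(0L, 10, 10); la2[5, 2:3] <- 1L; la2[5, 7:8] <- 2L
  lb2 <- matrix(0L, 10, 10); lb2[5, 2:8] <- 1L
  sp <- colocalize(foci_from_labels(la2), foci_from_labels(lb2))
  expect_identical(nrow(sp), 2L)
  expect_identical(sp$channel_a_label, c(1L, 2L))
  bad <- foci_from_labels(matrix(0L, 5, 5))
  expect_error(colocalize(a, bad), "geometries")
})

test_that("swapping channels transposes the pair list", {
  set.seed(7)
  for (rep in 1:5) {
    a <- foci_from_labels(random_label_image(n_obj = 10), "telomere")
    b <- foci_from_labels(random_label_image(n_obj = 10), "pml")
    ab <- colocalize(a, b)
    ba <- colocalize(b, a)
    swapped <- data.frame(channel_a_label = ba$channel_b_label,
                          channel_b_label = ba$channel_a_label,
                          overlap_area_px = ba$overlap_area_px)
    swapped <- swapped[order(swapped$channel_a_label,
                             swapped$channel_b_label), ]
    expect_equal(ab$channel_a_label, swapped$channel_a_label)
    expect_equal(ab$channel_b_label, swapped$channel_b_label)
    expect_equal(ab$overlap_area_px, swapped$overlap_area_px)
  }
})

test_that("centroid-distance criterion gates pairs by distance", {
  la <- matrix(0L, 20, 20); la[5, 5] <- 1L
  lb <- matrix(0L, 20, 20); lb[5, 8] <- 1L   # 3 px apart, no mask overlap
  a <- foci_from_labels(la); b <- foci_from_labels(lb)
  pp_near <- phenotype_params(coloc_criterion = "centroid_distance",
                              max_centroid_distance_px = 4)
  pp_far <- phenotype_params(coloc_criterion = "centroid_distance",
                             max_centroid_distance_px = 2)
  expect_identical(nrow(colocalize(a, b, pp_near)), 1L)
  expect_identical(nrow(colocalize(a, b, pp_far)), 0L)
  expect_identical(nrow(colocalize(a, b)), 0L)  # mask overlap: none
})

test_that("count_apb uses distinct telomere anchoring", {
  # 3 telomeres crossing one PML stripe -> 3 APBs
  la <- matrix(0L, 12, 12)
  la[3, 2:4] <- 1L; la[6, 2:4] <- 2L; la[9, 2:4] <- 3L
  lb <- matrix(0L, 12, 12); lb[1:12, 3] <- 1L
  tel <- foci_from_labels(la, "telomere"); pml <- foci_from_labels(lb, "pml")
  expect_identical(count_apb(tel, pml), 3L)
  # 1 telomere under 2 PML bodies -> 1 (distinctness)
  la2 <- matrix(0L, 12, 12); la2[6, 4:9] <- 1L
  lb2 <- matrix(0L, 12, 12); lb2[6, 4] <- 1L; lb2[6, 9] <- 2L
  expect_identical(count_apb(foci_from_labels(la2, "telomere"),
                             foci_from_labels(lb2, "pml")), 1L)
  # pair-counting mode sees both overlaps
  expect_identical(count_apb(foci_from_labels(la2, "telomere"),
                             foci_from_labels(lb2, "pml"),
                             phenotype_params(apb_count_mode = "pairs")), 2L)
  # no PML objects -> 0
  expect_identical(count_apb(tel, foci_from_labels(matrix(0L, 12, 12))), 0L)
})

test_that("count_apb is invariant to object relabeling", {
  set.seed(8)
  la <- random_label_image(n_obj = 12)
  lb <- random_label_image(n_obj = 12)
  tel <- foci_from_labels(la, "telomere"); pml <- foci_from_labels(lb, "pml")
  base <- count_apb(tel, pml)
  # permute telomere labels
  perm <- sample(max(la))
  la2 <- la; la2[la > 0] <- perm[la[la > 0]]
  tel2 <- foci_from_labels(la2, "telomere")
  tel2$objects <- tel2$objects[sample(nrow(tel2$objects)), ]
  expect_identical(count_apb(tel2, pml), base)
})

test_that("EdU and triple colocalization follow the same anchoring rules", {
  la <- matrix(0L, 15, 15); la[4, 4:5] <- 1L; la[10, 9:10] <- 2L
  lp <- matrix(0L, 15, 15); lp[4, 5] <- 1L
  le <- matrix(0L, 15, 15); le[4, 4] <- 1L; le[10, 10] <- 2L
  tel <- foci_from_labels(la, "telomere")
  pml <- foci_from_labels(lp, "pml")
  edu <- foci_from_labels(le, "edu")
  expect_identical(count_edu_telomere(tel, edu), 2L)
  expect_identical(count_edu_telomere(tel, foci_from_labels(matrix(0L, 15, 15))), 0L)
  # telomere 1 has PML and EdU; telomere 2 only EdU
  expect_identical(count_triple(tel, pml, edu), 1L)
  # PML-only overlap is not a triple
  expect_identical(count_triple(tel, pml,
                                foci_from_labels(matrix(0L, 15, 15))), 0L)
  # exhaustive triple loop on a random mixed field
  set.seed(9)
  for (rep in 1:10) {
    a <- foci_from_labels(random_label_image(n_obj = 10), "telomere")
    p <- foci_from_labels(random_label_image(n_obj = 8), "pml")
    e <- foci_from_labels(random_label_image(n_obj = 8), "edu")
    ref <- 0L
    for (l in a$objects$label) {
      hasp <- any(a$labels == l & p$labels > 0)
      hase <- any(a$labels == l & e$labels > 0)
      if (hasp && hase) ref <- ref + 1L
    }
    expect_identical(count_triple(a, p, e), ref)
  }
})

test_that("the APB-positive rule is strictly 'more than threshold'", {
  expect_true(classify_apb_positive(6))
  expect_false(classify_apb_positive(5))
  expect_false(classify_apb_positive(0))
  expect_true(classify_apb_positive(3, threshold = 2))
  expect_error(classify_apb_positive(-1), "nonnegative")
})

test_that("build_phenotypes fills per-cell metrics and flags absences", {
  cfg <- test_config(apb_prob = 0.5, edu_at_apb_prob = 0.8)
  sim <- simulate_field(cfg, "bp", seed = 23)
  nm <- segment_nuclei(max_project(sim$field, "dapi"))
  foci <- list(telomere = detect_foci(sim$field, "telomere"),
               pml = detect_foci(sim$field, "pml"),
               edu = detect_foci(sim$field, "edu"))
  ph <- build_phenotypes(foci, nm, field_id = "bp")
  expect_identical(nrow(ph), nrow(nm$table))
  expect_true(all(ph$apb_count <= ph$telomere_count))
  expect_true(all(ph$triple_count <= pmin(ph$apb_count,
                                          ph$edu_telomere_count)))
  expect_identical(ph$apb_positive, ph$apb_count > 5)
  # telomere+PML only: EdU-dependent metrics are NA, others populated
  ph2 <- build_phenotypes(foci[c("telomere", "pml")], nm, field_id = "bp")
  expect_true(all(is.na(ph2$edu_telomere_count)))
  expect_true(all(is.na(ph2$triple_count)))
  expect_identical(ph2$apb_count, ph$apb_count)
})

test_that("cells in an empty field report zero counts, not absence", {
  cfg <- test_config(telomere_count_mean = 0, free_pml_mean = 0,
                     apb_prob = 0)
  sim <- simulate_field(cfg, "z", seed = 29)
  nm <- segment_nuclei(max_project(sim$field, "dapi"))
  foci <- list(telomere = detect_foci(sim$field, "telomere"),
               pml = detect_foci(sim$field, "pml"))
  ph <- build_phenotypes(foci, nm, field_id = "z")
  expect_identical(nrow(ph), nrow(sim$truth$cells))
  expect_true(all(ph$telomere_count == 0))
  expect_true(all(ph$apb_count == 0))
  expect_true(all(!ph$apb_positive))
})

test_that("detection metrics: exact, missed and optimal matching cases", {
  tr <- ground_truth_table(
    data.frame(field_id = "f", cell_id = 1L, channel_role = "telomere",
               focus_id = 1:3, y = c(5, 15, 25), x = c(5, 15, 25),
               true_radius_px = 1, linked_focus_ids = "",
               stringsAsFactors = FALSE),
    data.frame(field_id = "f", cell_id = 1L, center_y = 15, center_x = 15,
               radius_y = 20, radius_x = 20, true_telomere_count = 3L,
               true_apb_count = 0L, true_edu_telomere_count = 0L))
  mk_det <- function(ys, xs) {
    lab <- matrix(0L, 30, 30)
    for (i in seq_along(ys)) lab[ys[i], xs[i]] <- i
    foci_from_labels(lab, "telomere")
  }
  # perfect detection
  m <- detection_metrics(mk_det(c(5, 15, 25), c(5, 15, 25)), tr)
  expect_equal(m$precision, 1); expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  # no detections: recall 0, precision reported 0 with flag
  m0 <- detection_metrics(mk_det(integer(0), integer(0)), tr)
  expect_equal(m0$recall, 0); expect_equal(m0$precision, 0)
  expect_true(m0$undefined)
  # 2 detections within radius of distinct truths
  m2 <- detection_metrics(mk_det(c(6, 16), c(5, 15)), tr)
  expect_equal(m2$precision, 1); expect_equal(m2$recall, 2 / 3)
  # one-to-one: two detections near one truth can only match once
  m3 <- detection_metrics(mk_det(c(5, 6, 15, 25), c(5, 5, 15, 25)), tr)
  expect_identical(m3$n_matched, 3L)
  expect_equal(m3$precision, 3 / 4)
})

test_that("optimal assignment beats greedy matching on a crossing pair", {
  # truth at 0 and 3; detections at 1.9 and 4 (radius 2): greedy nearest
  # match of detection 1.9 -> truth 3 would orphan truth 0
  tr <- ground_truth_table(
    data.frame(field_id = "f", cell_id = 1L, channel_role = "telomere",
               focus_id = 1:2, y = c(10, 10), x = c(10, 13),
               true_radius_px = 1, linked_focus_ids = "",
               stringsAsFactors = FALSE),
    data.frame(field_id = "f", cell_id = 1L, center_y = 10, center_x = 11,
               radius_y = 20, radius_x = 20, true_telomere_count = 2L,
               true_apb_count = 0L, true_edu_telomere_count = 0L))
  lab <- matrix(0L, 20, 20); lab[10, 12] <- 1L; lab[10, 14] <- 2L
  det <- foci_from_labels(lab, "telomere")
  m <- detection_metrics(det, tr, match_radius_px = 2)
  expect_identical(m$n_matched, 2L)
})
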