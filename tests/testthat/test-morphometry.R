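test_that("a straight bar gives two endpoints, no branch nodes, one edge", {
  m <- capsule_mask(120, 20, 60, 100, 60, 5)
  g <- skeleton_graph(m, pixel_size_um = 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2L)
  expect_equal(sum(g$nodes$kind == "branch_node"), 0L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_um, 80, tolerance = 0.12)
  expect_equal(g$edges$mean_radius_um, 5, tolerance = 0.25)
})

test_that("a Y-shape gives three endpoints, one branch node, three edges", {
  m <- capsule_mask(160, 80, 20, 80, 80, 5) |
    capsule_mask(160, 80, 80, 40, 130, 5) |
    capsule_mask(160, 80, 80, 120, 130, 5)
  g <- skeleton_graph(m, pixel_size_um = 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3L)
  expect_equal(sum(g$nodes$kind == "branch_node"), 1L)
  expect_equal(nrow(g$edges), 3L)
})

test_that("a perfect disk measures its diameter with a circular core", {
  m <- disk_mask(140, 70, 70, 50)
  sm <- as_seg_mask(m, ps = 1)
  g <- skeleton_graph(sm)
  rec <- measure(sm, g)
  expect_equal(rec$major_axis_um, 100, tolerance = 0.02)
  expect_equal(rec$n_nodes, 0L)
  expect_equal(rec$n_endpoints, 0L)
  expect_gte(rec$core_circularity, 0.95)
  expect_equal(rec$core_thickness_um, 100, tolerance = 0.05)
})

test_that("micrometre quantities scale exactly with the pixel size", {
  m <- capsule_mask(120, 20, 60, 100, 60, 6)
  r1 <- measure(as_seg_mask(m, 1), skeleton_graph(m, pixel_size_um = 1))
  r2 <- measure(as_seg_mask(m, 2), skeleton_graph(m, pixel_size_um = 2))
  for (f in c("major_axis_um", "core_thickness_um", "skeleton_length_um"))
    expect_equal(r2[[f]], 2 * r1[[f]], tolerance = 1e-8)
  expect_equal(r2$mask_area_um2, 4 * r1$mask_area_um2)
  expect_equal(r2$n_endpoints, r1$n_endpoints)
})

test_that("dilating a mask never decreases the major axis", {
  m <- capsule_mask(120, 30, 40, 90, 80, 5)
  d <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(m * 1), EBImage::makeBrush(3, "box"))) > 0.5
  f1 <- measure(as_seg_mask(m, 1), skeleton_graph(m, pixel_size_um = 1))
  f2 <- measure(as_seg_mask(d, 1), skeleton_graph(d, pixel_size_um = 1))
  expect_gte(f2$major_axis_um, f1$major_axis_um)
})

test_that("blank images segment to an empty, flagged mask", {
  img <- matrix(0.8, 64, 64)
  sm <- segment(img, 1.29)
  expect_true(sm$blank)
  expect_equal(sm$n_components, 0L)
  g <- skeleton_graph(sm)
  expect_equal(nrow(g$nodes), 0L)
  rec <- measure(sm, g)
  expect_equal(rec$n_endpoints, 0L)
  expect_equal(rec$mask_area_um2, 0)
})

test_that("segmentation recovers disk area and scattered components", {
  g <- generate_organoid_image(
    phenotype_archetype("clump", core_radius_um = 50),
    pixel_size_um = 1, noise_level = 0, seed = 5)
  sm <- segment(g$image, 1)
  expect_lt(abs(sum(sm$mask) - pi * 2500) / (pi * 2500), 0.02)

  sc <- generate_organoid_image(
    phenotype_archetype("scattered", n_blobs = 12L), seed = 6,
    noise_level = 0)
  sm2 <- segment(sc$image, 1.29, keep_largest = FALSE)
  expect_equal(sm2$n_components, 12L)
  expect_equal(sum(EBImage::bwlabel(sm2$mask) > 0) > 0, TRUE)
})

test_that("skeleton graphs satisfy the tree Euler property when acyclic", {
  for (ph in c("TEBBO", "tree_like", "star_like", "thick_branched")) {
    g <- generate_organoid_image(ph, seed = 31, noise_level = 0)
    sm <- segment(g$image, 1.29)
    gr <- skeleton_graph(sm)
    if (nrow(gr$cycles) == 0) {
      expect_equal(nrow(gr$edges), nrow(gr$nodes) - 1L,
                   info = paste("family", ph))
    }
  }
})

test_that("morphometry recovers generator ground truth on a mixed cohort", {
  co <- cohort_small()
  prof <- profile_small()
  man <- co$manifest
  expect_equal(prof$n_nodes, man$n_nodes)
  expect_equal(prof$n_endpoints, man$n_endpoints)
  expect_true(all(abs(prof$major_axis_um - man$major_axis_um) /
                  man$major_axis_um < 0.02))
  lum <- man$n_lumens > 0
  expect_true(any(lum))
  expect_equal(prof$n_lumens[lum], man$n_lumens[lum])
  expect_true(all(abs(prof$total_lumen_area_um2[lum] -
                      man$total_lumen_area_um2[lum]) /
                  man$total_lumen_area_um2[lum] < 0.05))
})

test_that("the rule-based classifier labels the mixed cohort correctly", {
  co <- cohort_small()
  prof <- profile_small()
  expect_gte(mean(prof$label == co$manifest$phenotype), 0.9)
})

test_that("classifier rules fire on their discriminating features", {
  rec <- measure(as_seg_mask(matrix(FALSE, 8, 8)),
                 skeleton_graph(matrix(FALSE, 8, 8), pixel_size_um = 1))
  rec$n_components <- 7L
  rec$mask_area_um2 <- 100
  cl <- classify_rule_based(rec)
  expect_equal(cl$label, "scattered")
  expect_equal(cl$rule, "n_components")

  rec2 <- rec
  rec2$n_components <- 1L
  rec2$core_circularity <- 0.95
  rec2$core_thickness_um <- 150
  rec2$core_area_um2 <- 80
  rec2$n_endpoints <- 6L
  rec2$n_nodes <- 1L
  cl2 <- classify_rule_based(rec2)
  expect_equal(cl2$label, "star_like")
  expect_gt(cl2$margin, 0)
})
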