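test_that("a plain clump renders as a disk with exact ground truth", {
  g <- generate_organoid_image(
    phenotype_archetype("clump", core_radius_um = 50, granularity_sigma = 0),
    canvas_px = c(256L, 256L), pixel_size_um = 1, noise_level = 0, seed = 3)
  tr <- g$truth
  expect_equal(tr$n_main_branches, 0L)
  expect_equal(tr$n_nodes, 0L)
  expect_equal(tr$n_endpoints, 0L)
  expect_equal(tr$major_axis_um, 100)
  expect_equal(tr$core_area_um2, pi * 50^2)
  # rendered mask area matches the analytic disk closely
  expect_lt(abs(sum(g$mask) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("TEBBO ground truth records the requested terminal end buds", {
  g <- generate_organoid_image(
    phenotype_archetype("TEBBO", n_terminal_end_buds = 5L), seed = 8,
    noise_level = 0)
  expect_equal(g$truth$n_terminal_end_buds, 5L)
  expect_equal(g$truth$phenotype, "TEBBO")
  expect_gte(g$truth$major_axis_um, g$truth$core_thickness_um)
})

test_that("image generation is bit-identical for a fixed seed", {
  a <- generate_organoid_image("star_like", seed = 77)
  b <- generate_organoid_image("star_like", seed = 77)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- generate_organoid_image("star_like", seed = 78)
  expect_false(identical(a$image, c$image))
})

test_that("geometry larger than the canvas raises an explicit error", {
  expect_error(
    generate_organoid_image(
      phenotype_archetype("clump", core_radius_um = 400),
      canvas_px = c(256L, 256L), seed = 1),
    "canvas")
})

test_that("cohort generation shuffles deterministically and keeps labels", {
  spec <- c(clump = 4, star_like = 3, TEBBO = 2)
  a <- generate_cohort(spec, jitter = 0.15, seed = 9, noise_level = 0)
  b <- generate_cohort(spec, jitter = 0.15, seed = 9, noise_level = 0)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$images, b$images)
  expect_equal(sort(as.vector(table(a$manifest$phenotype))), c(2, 3, 4))
  expect_error(generate_cohort(c()), "archetype")
  expect_error(generate_cohort(c(nonsense = 2)), "unknown")
})

test_that("zero jitter yields identical geometry parameters across a spec", {
  co <- generate_cohort(c(clump = 3), jitter = 0, seed = 4, noise_level = 0)
  expect_equal(length(unique(co$manifest$core_area_um2)), 1L)
  expect_equal(length(unique(co$manifest$seed)), 3L)
})

test_that("limiting-dilution wells saturate at frequency 1 and follow the binomial", {
  tab <- generate_limiting_dilution(1, doses = 20L, wells_per_dose = 50L,
                                    seed = 2)
  expect_equal(tab$n_responding, tab$n_wells)  # 1 - exp(-20) ~ 1

  # marginal response rate at dose 1, f = 0.5, within 3 binomial sd
  n <- 20000L
  tab2 <- generate_limiting_dilution(0.5, doses = 1L, wells_per_dose = n,
                                     seed = 6)
  p <- 1 - exp(-0.5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(tab2$n_responding / n - p), 3 * se)

  # the bench design: 20/10/3/1 cells per gel, 8 gels each
  tab3 <- generate_limiting_dilution(1 / 3, seed = 11)
  expect_equal(tab3$dose_cells, c(20L, 10L, 3L, 1L))
  expect_true(all(tab3$n_responding <= tab3$n_wells))
  expect_error(generate_limiting_dilution(0), "0, 1")
  expect_error(generate_limiting_dilution(2), "0, 1")
})

test_that("count matrices plant disjoint markers and respect the NB model", {
  ct <- generate_count_matrix(1500, rep(c("A", "B", "C"), each = 3), 40,
                              log2fc = 3, dispersion = 0.1, seed = 21)
  expect_equal(dim(ct$counts), c(1500L, 9L))
  expect_length(intersect(ct$planted_genes$A, ct$planted_genes$B), 0)
  expect_length(intersect(ct$planted_genes$A, ct$planted_genes$C), 0)

  # log2fc = 0: no systematic group difference in normalized means
  null <- generate_count_matrix(1500, rep(c("A", "B"), each = 4), 40,
                                log2fc = 0, dispersion = 0.1, seed = 22,
                                depth_range = c(1, 1))
  mA <- rowMeans(null$counts[, 1:4]); mB <- rowMeans(null$counts[, 5:8])
  lfc <- log2((mA + 1) / (mB + 1))
  expect_lt(abs(median(lfc)), 0.05)

  # near-zero dispersion: Poisson limit, variance ~ mean
  pois <- generate_count_matrix(2000, rep(c("A", "B"), each = 6), 10,
                                log2fc = 0, dispersion = 1e-5, seed = 23,
                                depth_range = c(1, 1))
  mu <- rowMeans(pois$counts)
  v <- apply(pois$counts, 1, var)
  keep <- mu > 10
  expect_lt(abs(median(v[keep] / mu[keep]) - 1), 0.1)
})

test_that("dose-response curves follow the Hill closed form", {
  concs <- 10 / 3^(6:0)
  gi50 <- concs[4]
  cv <- generate_dose_response(gi50, hill = 1, floor_viability = 0,
                               noise_sd = 0, concentrations = concs)
  expect_equal(cv$viability, 1 / (1 + concs / gi50))
  expect_equal(cv$viability[4], 0.5)  # midpoint at c = GI50
  low <- generate_dose_response(1e6, noise_sd = 0)$viability
  expect_true(all(low > 0.99))  # c << GI50: viability -> 1
  expect_error(generate_dose_response(1, floor_viability = 1.2), "floor")
})
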