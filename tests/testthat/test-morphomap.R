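test_that("classical features are z-scored, named and flag zero variance", {
  prof <- profile_small()
  fm <- suppressWarnings(extract_features_classical(prof,
                                                    cohort_small()$manifest))
  expect_equal(ncol(fm), length(attr(fm, "feature_names")))
  keep <- !colnames(fm) %in% attr(fm, "zero_variance")
  expect_true(all(abs(colMeans(fm)) < 1e-8))
  expect_true(all(abs(apply(fm[, keep], 2, sd) - 1) < 1e-8))

  # identical records -> every feature flagged, all-zero matrix
  same <- prof[rep(1, 5), ]
  expect_warning(f0 <- extract_features_classical(same), "zero-variance")
  expect_true(all(f0 == 0))
})

test_that("family structure is recovered in classical feature space", {
  fm <- suppressWarnings(extract_features_classical(profile_small()))
  sil <- mean_silhouette(unclass(fm), cohort_small()$manifest$phenotype)
  expect_gt(sil, 0.2)
})

test_that("t-SNE embedding is deterministic and keeps duplicates together", {
  fm <- suppressWarnings(extract_features_classical(profile_small()))
  e1 <- embed(fm, pca_dims = 5, perplexity = 5, seed = 3)
  e2 <- embed(fm, pca_dims = 5, perplexity = 5, seed = 3)
  expect_identical(unclass(e1), unclass(e2))

  # duplicated rows land (nearly) on top of each other
  x <- rbind(unclass(fm), unclass(fm)[1, , drop = FALSE])
  e3 <- embed(x, pca_dims = 5, perplexity = 5, seed = 4)
  dup <- sqrt(sum((e3[nrow(x), ] - e3[1, ])^2))
  diam <- max(dist(e3))
  expect_lt(dup, 0.01 * diam)

  expect_error(embed(unclass(fm)[1:10, ], perplexity = 30), "perplexity")
})

test_that("elbow rule finds three separated blobs and no knee in one", {
  mk_blobs <- function(centers, n, sd, seed) {
    withr::with_seed(seed, do.call(rbind, lapply(seq_len(nrow(centers)),
      function(i) cbind(rnorm(n, centers[i, 1], sd),
                        rnorm(n, centers[i, 2], sd)))))
  }
  b3 <- mk_blobs(rbind(c(0, 0), c(12, 0), c(6, 10)), 40, 0.5, 1)
  k3 <- choose_k_elbow(b3, k_max = 12, seed = 2)
  expect_equal(as.integer(k3), 3L)

  b1 <- mk_blobs(rbind(c(0, 0)), 120, 1, 3)
  k1 <- choose_k_elbow(b1, k_max = 12, seed = 2)
  expect_lte(as.integer(k1), 2L)
  expect_true(attr(k1, "no_knee"))
})

test_that("k-means assignment handles degenerate and labelled cases", {
  x <- rbind(matrix(0, 10, 2), matrix(5, 12, 2))
  cl <- cluster_assign(x, 2, seed = 1)
  expect_equal(attr(cl, "inertia"), 0)
  expect_equal(length(unique(as.integer(cl))), 2L)
  expect_setequal(unique(as.integer(cl)), c(0L, 1L))

  one <- cluster_assign(x, 1, seed = 1)
  expect_equal(attr(one, "inertia"), sum(scale(x, scale = FALSE)^2))

  fm <- suppressWarnings(extract_features_classical(profile_small()))
  cl8 <- cluster_assign(fm, 8, seed = 5)
  ari <- adjusted_rand_index(cl8, cohort_small()$manifest$phenotype)
  expect_gte(ari, 0.8)
})

test_that("density overlays integrate to one on a shared grid", {
  fm <- suppressWarnings(extract_features_classical(profile_small()))
  emb <- embed(fm, pca_dims = 5, perplexity = 5, seed = 7)
  line <- archetype_line(cohort_small()$manifest$phenotype)
  maps <- density_overlay(emb, line)
  for (m in maps) expect_equal(density_integral(m), 1, tolerance = 1e-6)

  # two disjoint groups put their modes in different places
  xy <- rbind(cbind(rnorm(20, 0, .2), rnorm(20, 0, .2)),
              cbind(rnorm(20, 10, .2), rnorm(20, 10, .2)))
  g <- rep(c("a", "b"), each = 20)
  m2 <- density_overlay(xy, g, bandwidth = 1)
  am <- function(m) {
    i <- which(m$z == max(m$z), arr.ind = TRUE)[1, ]
    c(m$x[i[1]], m$y[i[2]])
  }
  expect_gt(sqrt(sum((am(m2$a) - am(m2$b))^2)), 5)

  # a tight group concentrates its mass within 3 bandwidths
  ctr <- colMeans(xy[1:20, ])
  d <- sqrt(outer((m2$a$x - ctr[1])^2, (m2$a$y - ctr[2])^2, "+"))
  cell <- diff(m2$a$x[1:2]) * diff(m2$a$y[1:2])
  expect_gte(sum(m2$a$z[d <= 3 * m2$a$bandwidth]) * cell, 0.95)

  expect_error(density_overlay(xy, c("a", rep("b", 39))), ">= 2 points")
})

test_that("composition shifts report percentages, JSD and chi-square", {
  lab <- rep(c("A", "B"), times = c(50, 50))
  same <- occupancy_shift(c(lab, lab), rep(c("ctrl", "trt"), each = 100),
                          control = "ctrl")
  expect_equal(unname(same$jsd["trt"]), 0)
  expect_true(all(abs(rowSums(same$proportions) - 100) < 1e-9))

  # hand-computed JSD: {50,50} control vs {100,0} treated
  shift <- occupancy_shift(c(lab, rep("A", 100)),
                           rep(c("ctrl", "trt"), each = 100),
                           control = "ctrl")
  m <- c(0.75, 0.25)
  jsd_hand <- (0.5 * (1 * log2(1 / 0.75)) +
               0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)))
  expect_equal(unname(shift$jsd["trt"]), jsd_hand, tolerance = 1e-12)
  expect_lt(shift$chisq_p, 1e-6)

  # removing a phenotype strictly increases divergence from control
  lab3 <- rep(c("A", "B", "C"), times = c(30, 30, 40))
  base <- occupancy_shift(c(lab3, lab3),
                          rep(c("ctrl", "trt"), each = 100))$jsd["trt"]
  dropped <- occupancy_shift(c(lab3, rep(c("A", "B"), times = c(50, 50))),
                             rep(c("ctrl", "trt"), each = 100))$jsd["trt"]
  expect_gt(dropped, base)
})

test_that("drug response summaries match hand computations", {
  concs <- 10 / 3^(6:0)
  flat <- list(concentrations = concs, viability = rep(1, 7))
  gi <- concs[4]
  sig <- generate_dose_response(gi, hill = 1, floor_viability = 0,
                                noise_sd = 0, concentrations = concs)
  s <- drug_response_summary(list(drug1 = list(flat = flat, sig = sig)))
  expect_equal(unname(s$auc["drug1", "flat"]), 1)
  expect_equal(unname(s$gi50_censored["drug1", "flat"]), 1)  # censored high
  expect_lt(abs(s$gi50["drug1", "sig"] - gi) / gi, 0.1)
  # population-sd convention: two clones give -1 / +1
  expect_equal(sort(unname(s$zscore["drug1", ])), c(-1, 1))
  # curves with fewer than two finite points are skipped and reported
  bad <- list(concentrations = concs, viability = c(1, rep(NA, 6)))
  s2 <- drug_response_summary(list(d = list(ok = sig, bad = bad)))
  expect_true("d/bad" %in% s2$skipped)
})

test_that("the cnn backend trains deterministically on a surrogate task", {
  co <- fixture("cohort_cnn", function()
    generate_cohort(c(clump = 12, tree_like = 12), jitter = 0.1, seed = 19,
                    noise_level = 0.02))
  labs <- co$manifest$phenotype
  tr <- seq_along(labs) %% 2 == 0
  ex1 <- train_feature_extractor(co$images[tr], labs[tr], epochs = 40,
                                 seed = 5)
  ex2 <- train_feature_extractor(co$images[tr], labs[tr], epochs = 40,
                                 seed = 5)
  expect_identical(ex1$head, ex2$head)  # reproducible weights
  acc <- mean(predict_extractor(ex1, co$images[!tr]) == labs[!tr])
  expect_gt(acc, 0.9)

  # zero epochs: untrained but deterministic features
  e0a <- train_feature_extractor(co$images[tr], labs[tr], epochs = 0,
                                 seed = 7)
  e0b <- train_feature_extractor(co$images[tr], labs[tr], epochs = 0,
                                 seed = 7)
  f0a <- extract_features_cnn(e0a, co$images[1:4])
  f0b <- extract_features_cnn(e0b, co$images[1:4])
  expect_identical(unclass(f0a), unclass(f0b))
  expect_length(e0a$training_loss, 0)

  expect_error(train_feature_extractor(co$images[1:4], rep("x", 4)),
               "2 label classes")
  expect_error(train_feature_extractor(co$images[1:4], labs[1:4],
                                       architecture = "resnet50"),
               "runtime")
})
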