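test_that("median-of-ratios size factors behave on simple structures", {
  m <- matrix(withr::with_seed(3, rpois(600, 50)) + 1, 100, 6)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))

  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  zero <- m; zero[, 2] <- 0L
  expect_error(size_factors(zero), "all-zero")
})

test_that("generator depth factors are recovered within 5%", {
  ct <- generate_count_matrix(2500, rep(c("A", "B", "C"), each = 3), 30,
                              log2fc = 3, dispersion = 0.05,
                              depth_range = c(0.5, 2), seed = 13)
  sf <- size_factors(ct$counts)
  truth <- ct$library_size_factors
  # both rescaled to geometric mean one
  sf <- sf / exp(mean(log(sf)))
  truth <- truth / exp(mean(log(truth)))
  expect_true(all(abs(sf - truth) / truth < 0.05))
})

test_that("BH adjustment matches the step-up definition", {
  bh_ref <- function(p) {  # direct step-up reference
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  for (s in 1:5) {
    p <- withr::with_seed(s, runif(200)^2)
    expect_equal(p.adjust(p, "BH"), bh_ref(p), tolerance = 1e-12)
  }
})

test_that("swapping target and rest negates the fold changes", {
  ct <- generate_count_matrix(150, rep(c("A", "B"), each = 3), 10,
                              log2fc = 2, dispersion = 0.1, seed = 17)
  deA <- phenotype_de(ct$counts, ct$phenotype_labels, "A")
  deB <- phenotype_de(ct$counts, ct$phenotype_labels, "B")
  expect_equal(deA$log2_fold_change, -deB$log2_fold_change,
               tolerance = 1e-6)
  expect_equal(attr(deA, "contrast"), "A_vs_rest")
})

test_that("signature derivation applies thresholds and the uniqueness filter", {
  fake <- function(genes, padj, lfc) {
    structure(data.frame(gene = genes, base_mean = 10,
                         log2_fold_change = lfc, wald_statistic = 1,
                         p_value = padj, p_adjusted = padj,
                         dispersion = 0.1),
              class = c("de_result", "data.frame"))
  }
  g <- sprintf("g%02d", 1:6)
  # g1 passes in both phenotypes -> removed from both final lists
  deX <- fake(g, c(0.001, 0.001, 0.5, 0.5, 0.5, 0.5),
              c(3, 3, 3, 1, 1, 1))
  deY <- fake(g, c(0.001, 0.5, 0.5, 0.001, 0.5, 0.5),
              c(3, 3, 3, 3, 1, 1))
  sig <- derive_signatures(list(X = deX, Y = deY))
  expect_false("g01" %in% sig$X)
  expect_false("g01" %in% sig$Y)
  expect_equal(sig$X, "g02")
  expect_equal(sig$Y, "g04")
  expect_equal(attr(sig, "removed_shared"), "g01")

  # nothing passes -> empty but structurally valid signatures
  none <- fake(g, rep(0.9, 6), rep(0.1, 6))
  expect_warning(s0 <- derive_signatures(list(X = none, Y = none)),
                 "empty signature")
  expect_length(s0$X, 0)
})

test_that("recovery-curve AUC hits its degenerate bounds and rank invariance", {
  G <- 200
  genes <- sprintf("g%03d", 1:G)
  sig <- genes[1:10]
  top <- matrix(rev(seq_len(G)), G, 1, dimnames = list(genes, "s1"))
  expect_equal(unname(score_auc(top, sig, 0.1)), 1)

  bottom <- matrix(seq_len(G), G, 1, dimnames = list(genes, "s1"))
  expect_equal(unname(score_auc(bottom, sig, 0.1)), 0)

  x <- matrix(withr::with_seed(5, rnorm(G * 3)), G, 3,
              dimnames = list(genes, paste0("s", 1:3)))
  s1 <- score_auc(x, sig, 0.1)
  s2 <- score_auc(exp(3 * x), sig, 0.1)  # monotone transform
  expect_equal(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))

  expect_error(score_auc(x, "absent_gene", 0.1), "universe")
  expect_error(score_auc(x, sig, 1.5), "top_fraction")
})

test_that("random-expression scores match the brute-force expectation", {
  G <- 400; S <- 20; tf <- 0.05
  genes <- sprintf("g%03d", 1:G)
  sig <- genes[1:S]
  Tn <- ceiling(tf * G)
  maxarea <- sum(pmin(seq_len(Tn), S))
  # independent oracle: exhaustive expectation over random permutations by
  # direct Monte Carlo on permutations (not via score_auc)
  oracle <- withr::with_seed(99, replicate(4000, {
    ord <- sample.int(G)
    hits <- cumsum(ord[seq_len(Tn)] <= S)
    sum(hits) / maxarea
  }))
  x <- matrix(withr::with_seed(7, rnorm(G * 500)), G,
              dimnames = list(genes, NULL))
  sc <- score_auc(x, sig, tf)
  se <- sd(oracle) / sqrt(length(sc))
  expect_lt(abs(mean(sc) - mean(oracle)), 3 * se * sqrt(2))
})

test_that("the planted-marker loop recovers signatures end to end", {
  ct <- generate_count_matrix(800, rep(c("A", "B", "C"), each = 3), 25,
                              log2fc = 3, dispersion = 0.1, seed = 29)
  de <- lapply(c(A = "A", B = "B", C = "C"), function(ph)
    phenotype_de(ct$counts, ct$phenotype_labels, ph))
  sig <- derive_signatures(de)
  for (ph in names(sig)) {
    jac <- length(intersect(sig[[ph]], ct$planted_genes[[ph]])) /
      length(union(sig[[ph]], ct$planted_genes[[ph]]))
    expect_gte(jac, 0.8)
  }
  norm <- sweep(ct$counts, 2, size_factors(ct$counts), "/")
  scores <- score_signature_set(norm, sig, top_fraction = 0.05)
  for (ph in names(sig)) {
    own <- ct$phenotype_labels == ph
    expect_gt(mean(scores[own, ph]), mean(scores[!own, ph]))
  }
})
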