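#' Embed an image-feature matrix with PCA followed by t-SNE
#'
#' @param features numeric matrix (organoids x features), e.g. a
#'   `feature_matrix`.
#' @param pca_dims number of principal components fed to t-SNE (capped at
#'   the feature count and at n - 1).
#' @param perplexity t-SNE perplexity; requires `n - 1 >= 3 * perplexity`.
#' @param seed integer seed; fixed seed gives identical coordinates.
#' @param max_iter t-SNE iterations.
#' @return an `embedding`: n x 2 coordinate matrix with parameter
#'   attributes.
#' @export
embed <- function(features, pca_dims = 50, perplexity = 30, seed = 1L,
                  max_iter = 1000) {
  x <- unclass(as.matrix(features))
  n <- nrow(x)
  if (n - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " needs at least ",
         ceiling(3 * perplexity + 1), " observations (have ", n, ")")
  # identical observations must land on identical coordinates; embed the
  # unique rows and propagate (floating-point noise downstream of PCA would
  # otherwise break the symmetry)
  key <- apply(x, 1, paste, collapse = "\r")
  ux <- x[!duplicated(key), , drop = FALSE]
  umap <- match(key, key[!duplicated(key)])
  pca_dims <- min(pca_dims, ncol(ux), nrow(ux) - 1)
  pc <- prcomp(ux, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(pca_dims), drop = FALSE]
  # PCA initialization: duplicates start (and, having identical gradients,
  # stay) coincident, and runs are reproducible beyond the seed alone
  y0 <- scores[, 1:2, drop = FALSE]
  if (ncol(y0) < 2) y0 <- cbind(y0, 0)
  y0 <- y0 / max(sd(y0[, 1]), 1e-9) * 1e-4
  # exact gradients below 2000 points: Barnes-Hut approximation breaks the
  # symmetry of coincident observations
  theta <- if (n <= 2000) 0 else 0.3
  ts <- with_seed(seed,
    Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity, theta = theta,
                 pca = FALSE, max_iter = max_iter, check_duplicates = FALSE,
                 Y_init = y0, verbose = FALSE))
  coords <- ts$Y[umap, , drop = FALSE]
  colnames(coords) <- c("tsne1", "tsne2")
  rownames(coords) <- rownames(x)
  structure(coords, pca_dims = pca_dims, perplexity = perplexity,
            seed = as.integer(seed),
            class = c("embedding", "matrix", "array"))
}

#' Choose the number of k-means clusters by the elbow (Kneedle) rule
#'
#' Runs k-means for k = 1..`k_max`, records the inertia (total
#' within-cluster sum of squares) and returns the k whose point on the
#' axis-normalized inertia curve lies farthest from the chord joining
#' (1, inertia_1) and (k_max, inertia_kmax).
#'
#' The elbow window `k_max` must extend well beyond any plausible cluster
#' count: with the window barely past the knee the chord hugs the decaying
#' segment and the rule collapses toward small k. A knee is only accepted
#' when it explains most of the attainable inertia reduction
#' (`tail_tolerance`); a featureless curve (e.g. one Gaussian blob, whose
#' inertia decays smoothly like 1/k) has no knee and yields k = 1.
#'
#' @param x numeric matrix (features or embedding coordinates).
#' @param k_max largest k evaluated (capped at n - 1).
#' @param seed integer seed.
#' @param n_init random restarts per k.
#' @param tail_tolerance maximum fraction of the total inertia drop allowed
#'   to remain beyond the knee for the knee to count.
#' @return integer k with attributes `inertia` (the curve), `distance`
#'   (chord distances) and `no_knee`.
#' @export
choose_k_elbow <- function(x, k_max = 20, seed = 1L, n_init = 10,
                           tail_tolerance = 0.1) {
  x <- unclass(as.matrix(x))
  if (k_max < 2) stop("k_max must be >= 2")
  k_max <- min(k_max, nrow(x) - 1L)
  if (k_max < 2) stop("need more observations than k_max")
  curve <- function(ninit) with_seed(seed, vapply(seq_len(k_max), function(k) {
    if (k == 1) return(sum(scale(x, scale = FALSE)^2))
    kmeans_safe(x, k, ninit)$tot.withinss
  }, numeric(1)))
  inertia <- curve(n_init)
  if (any(diff(inertia) > 1e-8 * inertia[1])) {
    # local optima in the flat tail: raise the restart count once
    inertia <- pmin(inertia, curve(3L * n_init))
    if (any(diff(inertia) > 1e-8 * inertia[1]))
      warning("inertia increased with k despite extra restarts")
  }
  ks <- seq_len(k_max)
  drop_total <- inertia[1] - inertia[k_max]
  kx <- (ks - 1) / (k_max - 1)
  ky <- (inertia - inertia[k_max]) / max(drop_total, 1e-12)
  # distance to the chord through (0, 1) and (1, 0) after normalization
  d <- abs(kx + ky - 1) / sqrt(2)
  k <- ks[which.max(d)]
  no_knee <- drop_total <= 1e-12 * max(inertia[1], 1) ||
    (inertia[k] - inertia[k_max]) / max(drop_total, 1e-12) > tail_tolerance
  if (no_knee) k <- 1L
  structure(as.integer(k), inertia = inertia, distance = d,
            no_knee = no_knee)
}

#' k-means phenotype clustering
#'
#' k-means with multiple restarts (Hartigan-Wong), deterministic for a
#' fixed seed. Cluster ids are 0-based and dense.
#'
#' @inheritParams choose_k_elbow
#' @param k number of clusters.
#' @return a `cluster_assignment`: integer vector (0..k-1) with attributes
#'   `k`, `inertia` and `centers`.
#' @export
cluster_assign <- function(x, k, seed = 1L, n_init = 10) {
  x <- unclass(as.matrix(x))
  if (k < 1) stop("k must be >= 1")
  fit <- with_seed(seed, kmeans_safe(x, k, n_init))
  cl <- as.integer(fit$cluster) - 1L
  structure(cl, k = as.integer(k), inertia = fit$tot.withinss,
            centers = fit$centers, class = "cluster_assignment")
}

kmeans_safe <- function(x, k, n_init, retries = 5) {
  for (t in seq_len(retries)) {
    fit <- tryCatch(stats::kmeans(x, centers = k, nstart = n_init,
                                  iter.max = 200),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) return(fit)
  }
  # final attempt, surfacing the error if any
  fit <- suppressWarnings(stats::kmeans(x, centers = k, nstart = n_init * 2,
                                        iter.max = 200))
  if (length(unique(fit$cluster)) != k)
    stop("k-means produced an empty cluster after retries")
  fit
}

#' Project feature rows onto the unit sphere (cosine geometry)
#'
#' Clustering morphometric profiles by their direction rather than their
#' magnitude equalizes the separations between phenotype families, which
#' otherwise differ mostly in overall size terms.
#'
#' @param x numeric matrix (rows = organoids).
#' @return the row-normalized matrix.
#' @export
cosine_normalize <- function(x) {
  x <- unclass(as.matrix(x))
  n <- sqrt(rowSums(x^2))
  n[n < 1e-12] <- 1
  x / n
}

#' Run the full imaging-phenotype mapping chain on a cohort
#'
#' Morphometry (segment, skeletonize, measure, classify), classical feature
#' extraction, PCA + t-SNE embedding, elbow-selected k-means clusters (on
#' cosine-normalized features) and per-line density overlays, all under one
#' master seed.
#'
#' @param cohort an [generate_cohort()] result.
#' @param seed master seed for embedding/clustering.
#' @param pca_dims,perplexity see [embed()].
#' @param k number of clusters; `NULL` selects it by [choose_k_elbow()].
#' @param k_max elbow search window.
#' @return list with `profile`, `features`, `embedding`, `k`, `clusters`,
#'   `densities` (by epithelial/mesenchymal line) and `manifest`.
#' @export
morphomap_pipeline <- function(cohort, seed = 1L, pca_dims = 10,
                               perplexity = 30, k = NULL, k_max = 20) {
  prof <- profile_cohort(cohort)
  fm <- suppressWarnings(extract_features_classical(prof, cohort$manifest))
  xs <- cosine_normalize(fm)
  emb <- embed(fm, pca_dims = pca_dims,
               perplexity = min(perplexity, (nrow(fm) - 2) / 3), seed = seed)
  kc <- choose_k_elbow(xs, k_max = k_max, seed = seed + 1L)
  if (is.null(k)) k <- as.integer(kc)
  cl <- cluster_assign(xs, k, seed = seed + 2L)
  line <- archetype_line(cohort$manifest$phenotype)
  dens <- if (length(unique(line)) > 1 && all(table(line) >= 2))
    density_overlay(emb, line) else NULL
  list(profile = prof, features = fm, embedding = emb, k = k,
       k_curve = kc, clusters = cl, densities = dens,
       manifest = cohort$manifest)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must align")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sum_ij - expected) / (maxi - expected)
}
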