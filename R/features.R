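#' Build a classical (morphometry-based) feature matrix
#'
#' Deterministic image-feature backend: concatenates the structural
#' descriptors measured by [measure()] (sizes, counts, lumen and core
#' geometry, granularity and intensity summaries) and z-scores each feature
#' over the cohort. Zero-variance features are kept as zeros and flagged.
#'
#' @param records data frame of morphometric records, one row per organoid
#'   (e.g. from [profile_cohort()]).
#' @param manifest optional manifest whose rows align with `records`; used
#'   to name rows and report offending images in errors.
#' @return a `feature_matrix`: numeric matrix (organoids x features) with
#'   attributes `feature_names`, `backend = "classical"` and
#'   `zero_variance`.
#' @export
extract_features_classical <- function(records, manifest = NULL) {
  cols <- c("major_axis_um", "core_thickness_um", "n_main_branches",
            "n_nodes", "n_endpoints", "n_terminal_end_buds",
            "n_spiky_branches", "n_lumens", "total_lumen_area_um2",
            "core_area_um2", "core_circularity", "granularity_index",
            "n_components", "n_cycles", "mask_area_um2",
            "mean_branch_radius_um", "skeleton_length_um", "trunk_radius_um")
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("records are missing descriptors: ", paste(miss, collapse = ", "))
  x <- as.matrix(records[, cols])
  storage.mode(x) <- "double"
  bad <- which(!stats::complete.cases(x))
  if (length(bad)) {
    who <- if (!is.null(manifest) && "file" %in% names(manifest))
      manifest$file[bad[1]] else paste("row", bad[1])
    stop("missing/non-finite record for image ", who)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  zero <- sdv < 1e-12
  z <- sweep(x, 2, mu, "-")
  z <- sweep(z, 2, ifelse(zero, 1, sdv), "/")
  z[, zero] <- 0
  if (any(zero))
    warning("zero-variance features: ", paste(cols[zero], collapse = ", "))
  rownames(z) <- if (!is.null(manifest) && "id" %in% names(manifest))
    as.character(manifest$id) else NULL
  structure(z, feature_names = cols, backend = "classical",
            zero_variance = cols[zero], class = c("feature_matrix", "matrix",
                                                  "array"))
}

#' Train a small convolutional feature extractor on a surrogate task
#'
#' Desk-scale stand-in for a fine-tuned deep network: three fixed (seeded,
#' randomly initialized) convolution + ReLU + max-pool blocks provide a
#' random-feature image representation, and a 64-unit dense layer with a
#' softmax head is trained on the surrogate labels (e.g. the line identity
#' the organoids were grown from). The penultimate (dense) activations are
#' the learned embedding. With `epochs = 0` the features are those of the
#' untrained, randomly initialized network, still deterministic for a fixed
#' seed.
#'
#' @param images list of single-channel image matrices.
#' @param labels surrogate class labels, one per image (>= 2 classes).
#' @param architecture `"small_cnn"` (implemented) or `"resnet50"`
#'   (requires a deep-learning runtime; not provided here).
#' @param epochs full-batch gradient-descent epochs for the dense head.
#' @param lr learning rate.
#' @param input_px images are aspect-preserving padded and resized to this
#'   square size.
#' @param seed integer seed controlling every random component.
#' @return a `feature_extractor` object.
#' @export
train_feature_extractor <- function(images, labels,
                                    architecture = c("small_cnn", "resnet50"),
                                    epochs = 60, lr = 0.1, input_px = 64,
                                    seed = 1L) {
  architecture <- match.arg(architecture)
  if (architecture == "resnet50")
    stop("the resnet50 backend requires a deep-learning runtime; ",
         "use architecture = 'small_cnn'")
  labels <- as.character(labels)
  if (length(images) != length(labels))
    stop("images and labels must align")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 label classes")
  y <- match(labels, classes)

  weights <- with_seed(seed, init_cnn_weights(input_px))
  feats <- cnn_forward_all(images, weights, input_px)

  nh <- 64L
  C <- length(classes)
  p <- ncol(feats)
  head <- with_seed(seed + 1L, list(
    W1 = matrix(rnorm(p * nh, 0, sqrt(2 / p)), p, nh), b1 = rep(0, nh),
    W2 = matrix(rnorm(nh * C, 0, sqrt(2 / nh)), nh, C), b2 = rep(0, C)))
  losses <- numeric(0)
  n <- nrow(feats)
  Yhot <- matrix(0, n, C); Yhot[cbind(seq_len(n), y)] <- 1
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      H <- pmax(feats %*% head$W1 + matrix(head$b1, n, nh, byrow = TRUE), 0)
      S <- H %*% head$W2 + matrix(head$b2, n, C, byrow = TRUE)
      S <- S - apply(S, 1, max)
      P <- exp(S); P <- P / rowSums(P)
      losses <- c(losses, -mean(log(pmax(P[cbind(seq_len(n), y)], 1e-12))))
      dS <- (P - Yhot) / n
      dW2 <- t(H) %*% dS; db2 <- colSums(dS)
      dH <- dS %*% t(head$W2); dH[H <= 0] <- 0
      dW1 <- t(feats) %*% dH; db1 <- colSums(dH)
      head$W2 <- head$W2 - lr * dW2; head$b2 <- head$b2 - lr * db2
      head$W1 <- head$W1 - lr * dW1; head$b1 <- head$b1 - lr * db1
    }
  }
  structure(list(weights = weights, head = head, classes = classes,
                 input_px = input_px, epochs = epochs, lr = lr, seed = seed,
                 training_loss = losses, architecture = architecture),
            class = "feature_extractor")
}

init_cnn_weights <- function(input_px) {
  blocks <- list(c(k = 5, cin = 1, f = 8, pool = 4),
                 c(k = 3, cin = 8, f = 16, pool = 2),
                 c(k = 3, cin = 16, f = 16, pool = 2))
  lapply(blocks, function(b) {
    fanin <- b["k"]^2 * b["cin"]
    w <- array(rnorm(b["k"]^2 * b["cin"] * b["f"], 0, sqrt(2 / fanin)),
               dim = c(b["k"], b["k"], b["cin"], b["f"]))
    list(w = w, bias = rep(0, b["f"]), pool = unname(b["pool"]))
  })
}

prep_image_square <- function(img, input_px) {
  nr <- nrow(img); nc <- ncol(img)
  s <- max(nr, nc)
  pad <- matrix(stats::median(img), s, s)  # background-valued padding
  r0 <- (s - nr) %/% 2; c0 <- (s - nc) %/% 2
  pad[r0 + seq_len(nr), c0 + seq_len(nc)] <- img
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(pad),
                                            w = input_px, h = input_px))
  1 - out  # organoid bright on dark, zero-ish background
}

cnn_forward_one <- function(img, weights, input_px) {
  x <- prep_image_square(img, input_px)
  dim(x) <- c(input_px, input_px, 1)
  for (b in weights) x <- cpp_conv_block(x, b$w, b$bias, b$pool)
  as.numeric(x)
}

cnn_forward_all <- function(images, weights, input_px) {
  flat <- (input_px %/% 16)^2 * 16  # after the three pooling stages
  t(vapply(images, cnn_forward_one, numeric(flat),
           weights = weights, input_px = input_px))
}

#' Extract CNN-backend features (penultimate dense activations)
#'
#' @param extractor a [train_feature_extractor()] result.
#' @param images list of image matrices.
#' @return a `feature_matrix` with `backend = "cnn"`.
#' @export
extract_features_cnn <- function(extractor, images) {
  stopifnot(inherits(extractor, "feature_extractor"))
  feats <- cnn_forward_all(images, extractor$weights, extractor$input_px)
  H <- pmax(feats %*% extractor$head$W1 +
            matrix(extractor$head$b1, nrow(feats), length(extractor$head$b1),
                   byrow = TRUE), 0)
  structure(H, feature_names = sprintf("cnn_%02d", seq_len(ncol(H))),
            backend = "cnn", zero_variance = character(),
            class = c("feature_matrix", "matrix", "array"))
}

#' Predict surrogate classes with a trained extractor
#'
#' @inheritParams extract_features_cnn
#' @return character vector of predicted class labels.
#' @export
predict_extractor <- function(extractor, images) {
  H <- extract_features_cnn(extractor, images)
  S <- H %*% extractor$head$W2 +
    matrix(extractor$head$b2, nrow(H), length(extractor$head$b2), byrow = TRUE)
  extractor$classes[max.col(S, ties.method = "first")]
}

#' Epithelial/mesenchymal line identity of the synthetic families
#'
#' Surrogate-label helper mirroring training on cell-line identity: maps
#' each archetype to its parental line group.
#'
#' @param phenotypes character vector of archetype names.
#' @return character vector, `"epithelial"`, `"mesenchymal"` or
#'   `"auxiliary"`.
#' @export
archetype_line <- function(phenotypes) {
  epi <- c("TEBBO", "cystic_branched", "thick_branched", "tree_like")
  mes <- c("branched_mesenchymal", "firework", "star_like", "clump")
  ifelse(phenotypes %in% epi, "epithelial",
         ifelse(phenotypes %in% mes, "mesenchymal", "auxiliary"))
}
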