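#' Per-group kernel-density overlays on a shared embedding grid
#'
#' Gaussian kernel-density estimate for each group of embedded organoids on
#' a common grid covering all points plus a 5% margin; every map is
#' normalized to integrate to one.
#'
#' @param embedding n x 2 coordinate matrix (an [embed()] result).
#' @param group_labels one label per embedded point; every group needs at
#'   least two points.
#' @param bandwidth kernel bandwidth (one number, used for both axes) or
#'   `"auto"` (normal reference rule over all points).
#' @param grid_n grid resolution per axis.
#' @return named list of `density_map` objects (`x`, `y`, `z`, `bandwidth`,
#'   `group`); each `z` integrates to 1 within 1e-6.
#' @export
density_overlay <- function(embedding, group_labels, bandwidth = "auto",
                            grid_n = 101) {
  xy <- unclass(as.matrix(embedding))
  group_labels <- as.character(group_labels)
  if (nrow(xy) != length(group_labels)) stop("labels must align with points")
  cnt <- table(group_labels)
  if (any(cnt < 2)) stop("every group needs >= 2 points: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  mx <- 0.05 * max(diff(rx), 1e-6); my <- 0.05 * max(diff(ry), 1e-6)
  lims <- c(rx[1] - mx, rx[2] + mx, ry[1] - my, ry[2] + my)
  if (identical(bandwidth, "auto")) {
    bandwidth <- mean(c(MASS::bandwidth.nrd(xy[, 1]),
                        MASS::bandwidth.nrd(xy[, 2])))
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    bandwidth <- 0.05 * max(diff(rx), diff(ry), 1e-6)
    warning("singular spread; bandwidth floored at ", signif(bandwidth, 3))
  }
  out <- lapply(sort(unique(group_labels)), function(g) {
    pts <- xy[group_labels == g, , drop = FALSE]
    kd <- MASS::kde2d(pts[, 1], pts[, 2], h = bandwidth, n = grid_n,
                      lims = lims)
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    kd$z <- kd$z / (sum(kd$z) * cell)
    structure(list(group = g, x = kd$x, y = kd$y, z = kd$z,
                   bandwidth = bandwidth), class = "density_map")
  })
  names(out) <- sort(unique(group_labels))
  out
}

#' Integral of a density map (sanity check)
#' @param map a `density_map`.
#' @return the grid integral (should be 1).
#' @export
density_integral <- function(map) {
  sum(map$z) * diff(map$x[1:2]) * diff(map$y[1:2])
}

#' @export
print.density_map <- function(x, ...) {
  cat("density_map (", x$group, "): ", length(x$x), "x", length(x$y),
      " grid, bandwidth ", signif(x$bandwidth, 3), ", integral ",
      signif(density_integral(x), 6), "\n", sep = "")
  invisible(x)
}

#' Render a density overlay on the embedding plane
#'
#' @param x a `density_map`.
#' @param points optional n x 2 coordinates to draw on top.
#' @param ... passed to [graphics::image()].
#' @return the map, invisibly.
#' @export
plot.density_map <- function(x, points = NULL, ...) {
  graphics::image(x$x, x$y, x$z, xlab = "tsne1", ylab = "tsne2",
                  main = x$group, useRaster = TRUE, ...)
  if (!is.null(points))
    graphics::points(points[, 1], points[, 2], pch = 16, cex = 0.4)
  invisible(x)
}

#' Phenotype-composition shift between treatment arms
#'
#' Cross-tabulates cluster/phenotype labels by condition, reports
#' per-condition percentage compositions (each summing to 100), the
#' Jensen-Shannon divergence of every condition against the control arm,
#' and a chi-square test of homogeneity (per-condition tests against
#' control are Benjamini-Hochberg adjusted when there are several arms).
#'
#' @param labels phenotype or cluster labels, one per organoid.
#' @param condition_labels treatment arm per organoid.
#' @param control name of the control arm (default: first level).
#' @return a `composition_shift`: list with `proportions` (% table),
#'   `counts`, `jsd` (bits, vs control), `chisq_p` (overall),
#'   `pairwise_p_adj` and `control`.
#' @export
occupancy_shift <- function(labels, condition_labels, control = NULL) {
  labels <- as.character(labels)
  condition_labels <- as.character(condition_labels)
  if (length(labels) != length(condition_labels)) stop("inputs must align")
  cnt <- table(condition_labels)
  empty <- names(cnt)[cnt == 0]
  if (length(empty)) warning("conditions without organoids excluded: ",
                             paste(empty, collapse = ", "))
  conds <- names(cnt)[cnt > 0]
  if (length(conds) < 2) stop("need at least 2 non-empty conditions")
  control <- control %||% conds[1]
  if (!control %in% conds) stop("control arm not found: ", control)
  tab <- table(factor(condition_labels, levels = conds), labels)
  prop <- sweep(tab, 1, rowSums(tab), "/") * 100
  jsd <- vapply(conds, function(cd)
    js_divergence(tab[cd, ] / sum(tab[cd, ]),
                  tab[control, ] / sum(tab[control, ])), numeric(1))
  chisq_p <- suppressWarnings(chisq.test(tab)$p.value)
  others <- setdiff(conds, control)
  pair <- vapply(others, function(cd)
    suppressWarnings(chisq.test(tab[c(control, cd), ])$p.value), numeric(1))
  structure(list(proportions = prop, counts = tab, jsd = jsd,
                 chisq_p = chisq_p,
                 pairwise_p_adj = p.adjust(pair, method = "BH"),
                 control = control),
            class = "composition_shift")
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' @param p,q nonnegative vectors (normalized internally).
#' @param base logarithm base (2 gives values in `[0, 1]`).
#' @return the divergence.
#' @export
js_divergence <- function(p, q, base = 2) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i], base) - log(b[i], base)))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' @export
print.composition_shift <- function(x, ...) {
  cat("composition_shift (control:", x$control, ")\n")
  print(round(unclass(x$proportions), 1))
  cat("JSD vs control (bits):\n"); print(round(x$jsd, 4))
  cat("chi-square homogeneity p =", format.pval(x$chisq_p), "\n")
  invisible(x)
}
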