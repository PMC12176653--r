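#' Configuration for morphometric measurement
#'
#' @param main_branch_radius_frac an edge incident to the trunk counts as a
#'   main branch when its mean radius is at least this fraction of the trunk
#'   radius.
#' @param bud_ratio an endpoint is a terminal end bud when its local radius
#'   is at least `bud_ratio` times the median edge radius and at least
#'   `bud_bulge_ratio` times its own edge's mean radius (a bud is a local
#'   swelling, not merely a thick branch end).
#' @param bud_bulge_ratio see `bud_ratio`.
#' @param spike_ratio,spike_min_um an endpoint edge is a spiky (invasive)
#'   branch when its mean radius is at most `spike_ratio` times the trunk
#'   radius and it is at least `spike_min_um` long.
#' @param min_lumen_area_um2 holes smaller than this are ignored.
#' @param core_open_frac the core is isolated by morphological opening with
#'   a disc of radius `core_open_frac` times the maximum inscribed radius.
#' @return a named list of settings.
#' @export
measure_config <- function(main_branch_radius_frac = 0.5, bud_ratio = 1.3,
                           bud_bulge_ratio = 1.15,
                           spike_ratio = 0.5, spike_min_um = 30,
                           min_lumen_area_um2 = 80, core_open_frac = 0.45) {
  list(main_branch_radius_frac = main_branch_radius_frac,
       bud_ratio = bud_ratio, bud_bulge_ratio = bud_bulge_ratio,
       spike_ratio = spike_ratio,
       spike_min_um = spike_min_um, min_lumen_area_um2 = min_lumen_area_um2,
       core_open_frac = core_open_frac)
}

#' Measure structural descriptors of a segmented organoid
#'
#' Computes the morphometric record from a mask and its skeleton graph:
#' major axis (maximum Feret diameter), core thickness (twice the maximum
#' inscribed radius), branch/node/endpoint counts, terminal end buds
#' (endpoints with bulbous local radius), spiky invasive branches (thin long
#' endpoint edges), lumens (enclosed background holes, counted and summed),
#' core geometry (largest component after radius-scaled morphological
#' opening; circularity relative to the perfect circle with the core's
#' measured diameter) and a granularity index (coefficient of variation of
#' intensity inside the mask, when the image is supplied).
#'
#' @param mask a [segment()] result.
#' @param graph the matching [skeleton_graph()].
#' @param image optional original image, used for the granularity index.
#' @param config a [measure_config()].
#' @return a `morphometric_record` (named list of descriptors).
#' @examples
#' g <- generate_organoid_image("TEBBO", seed = 11)
#' m <- segment(g$image, 1.29)
#' rec <- measure(m, skeleton_graph(m), image = g$image)
#' rec$n_terminal_end_buds
#' @export
measure <- function(mask, graph, image = NULL, config = measure_config()) {
  stopifnot(inherits(mask, "segmentation_mask"),
            inherits(graph, "skeleton_graph"))
  ps <- mask$pixel_size_um
  rec <- list(major_axis_um = 0, core_thickness_um = 0,
              n_main_branches = 0L, n_nodes = 0L, n_endpoints = 0L,
              n_terminal_end_buds = 0L, n_spiky_branches = 0L,
              n_lumens = 0L, total_lumen_area_um2 = 0, core_area_um2 = 0,
              core_circularity = 0, granularity_index = 0,
              n_components = mask$n_components, n_cycles = 0L,
              mask_area_um2 = 0, mean_branch_radius_um = 0,
              skeleton_length_um = 0, trunk_radius_um = 0)
  class(rec) <- "morphometric_record"
  if (!any(mask$mask)) return(rec)

  m <- mask$mask
  rec$mask_area_um2 <- sum(m) * ps^2
  rec$major_axis_um <- feret_diameter_px(m) * ps
  rec$core_thickness_um <- 2 * graph$max_dt_um
  rec$skeleton_length_um <- graph$skeleton_length_um
  rec$n_cycles <- nrow(graph$cycles)

  lum <- graph$lumens
  lum <- lum[lum$area_um2 >= config$min_lumen_area_um2, , drop = FALSE]
  rec$n_lumens <- nrow(lum)
  rec$total_lumen_area_um2 <- sum(lum$area_um2)

  if (!is.null(image)) {
    v <- image[m]
    if (length(v) && mean(v) > 0)
      rec$granularity_index <- sd(v) / mean(v)
  }

  core <- core_geometry(m, graph$max_dt_um / ps, ps, config$core_open_frac)
  rec$core_area_um2 <- core$area_um2
  rec$core_circularity <- core$circularity

  nodes <- graph$nodes; edges <- graph$edges
  rec$n_nodes <- sum(nodes$kind == "branch_node")
  rec$n_endpoints <- sum(nodes$kind == "endpoint")
  if (nrow(edges) == 0) return(rec)

  rec$mean_branch_radius_um <- mean(edges$mean_radius_um)
  tp <- trunk_path(nodes, edges)
  rec$trunk_radius_um <- tp$trunk_radius_um

  if (length(tp$edge_idx)) {
    tn <- unique(c(edges$from[tp$edge_idx], edges$to[tp$edge_idx]))
    inc <- which(!(seq_len(nrow(edges)) %in% tp$edge_idx) &
                 (edges$from %in% tn | edges$to %in% tn))
    rec$n_main_branches <- sum(edges$mean_radius_um[inc] >=
      config$main_branch_radius_frac * tp$trunk_radius_um)
  }

  med_r <- median(edges$mean_radius_um)
  ep <- nodes$id[nodes$kind == "endpoint"]
  if (length(ep)) {
    buds <- 0L; spiky <- 0L
    for (id in ep) {
      ei <- which(edges$from == id | edges$to == id)[1]
      if (is.na(ei)) next
      tip <- if (edges$from[ei] == id) edges$tip_radius_from_um[ei]
             else edges$tip_radius_to_um[ei]
      local_r <- max(tip, nodes$radius_um[match(id, nodes$id)])
      if (local_r >= config$bud_ratio * med_r &&
          local_r >= config$bud_bulge_ratio * edges$mean_radius_um[ei])
        buds <- buds + 1L
      if (edges$mean_radius_um[ei] <= config$spike_ratio * tp$trunk_radius_um &&
          edges$length_um[ei] >= config$spike_min_um) spiky <- spiky + 1L
    }
    rec$n_terminal_end_buds <- buds
    rec$n_spiky_branches <- spiky
  }
  rec
}

feret_diameter_px <- function(m) {
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(m * 1),
                                          EBImage::makeBrush(3, "box"))) > 0.5
  bnd <- which(m & !er, arr.ind = TRUE)
  if (nrow(bnd) == 0) bnd <- which(m, arr.ind = TRUE)
  if (nrow(bnd) == 1) return(1)
  h <- grDevices::chull(bnd)
  pts <- bnd[h, , drop = FALSE]
  max(dist(pts)) + 1  # +1 px for the two half-pixel extents
}

core_geometry <- function(m, maxdt_px, ps, open_frac) {
  r <- floor(open_frac * maxdt_px)
  if (r < 2) r <- 2
  idx <- which(m, arr.ind = TRUE)
  pad <- r + 2
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(m), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(m), max(idx[, 2]) + pad)
  sub <- m[r0:r1, c0:c1]
  op <- EBImage::imageData(EBImage::opening(EBImage::Image(sub * 1),
        EBImage::makeBrush(2L * r + 1L, "disc"))) > 0.5
  if (!any(op)) return(list(area_um2 = 0, circularity = 0))
  lab <- EBImage::bwlabel(op)
  a <- tabulate(lab[lab > 0])
  big <- which.max(a)
  core <- lab == big
  feret <- feret_diameter_px(core)
  area <- a[big]
  circ <- min(1, area / (pi * (feret / 2)^2))
  list(area_um2 = area * ps^2, circularity = circ)
}

# Trunk = endpoint-to-endpoint skeleton path maximizing the radius-weighted
# length sum(mean_radius x length); searched by DFS in the dominant
# component (graphs are small). Falls back to the single thickest edge when
# fewer than two endpoints exist (pure cycles).
trunk_path <- function(nodes, edges) {
  comp_len <- tapply(edges$length_um, edges$component, sum)
  dom <- as.integer(names(comp_len)[which.max(comp_len)])
  eidx <- which(edges$component == dom)
  e <- edges[eidx, , drop = FALSE]
  score <- e$mean_radius_um * e$length_um
  ep <- nodes$id[nodes$kind == "endpoint" & nodes$component == dom]
  best <- list(score = -1, path = integer())
  if (length(ep) >= 2) {
    nbr <- list()
    for (i in seq_len(nrow(e))) {
      nbr[[as.character(e$from[i])]] <- c(nbr[[as.character(e$from[i])]], i)
      nbr[[as.character(e$to[i])]] <- c(nbr[[as.character(e$to[i])]], i)
    }
    steps <- 0L
    dfs <- function(node, visited, used, acc) {
      steps <<- steps + 1L
      if (steps > 20000L) return()
      if (node %in% ep && length(used) > 0 && acc > best$score) {
        best <<- list(score = acc, path = used)
      }
      for (i in nbr[[as.character(node)]]) {
        if (i %in% used) next
        nxt <- if (e$from[i] == node) e$to[i] else e$from[i]
        if (nxt %in% visited) next
        dfs(nxt, c(visited, nxt), c(used, i), acc + score[i])
      }
    }
    for (s in ep) dfs(s, s, integer(), 0)
  }
  if (best$score < 0) {
    best <- list(score = max(score), path = which.max(score))
  }
  sel <- eidx[best$path]
  list(edge_idx = sel,
       trunk_radius_um = max(edges$max_radius_um[sel]))
}

#' @export
print.morphometric_record <- function(x, ...) {
  cat(sprintf(paste0("morphometric_record: major axis %.0f um, core %.0f um, ",
      "%d nodes, %d endpoints, %d buds, %d lumens, %d component(s)\n"),
      x$major_axis_um, x$core_thickness_um, x$n_nodes, x$n_endpoints,
      x$n_terminal_end_buds, x$n_lumens, x$n_components))
  invisible(x)
}

#' @export
as.data.frame.morphometric_record <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Segment, skeletonize, measure and classify a whole cohort
#'
#' Convenience wrapper running the full morphometry chain over a cohort (or
#' any list of images) and returning one row per organoid.
#'
#' @param cohort an [generate_cohort()] result, or a list of image matrices.
#' @param pixel_size_um pixel size (taken from the cohort manifest when
#'   available).
#' @param config a [measure_config()].
#' @param thresholds a [classify_thresholds()].
#' @param ... passed to [segment()].
#' @return a data frame with all morphometric fields plus `label` and
#'   `label_margin` from [classify_rule_based()].
#' @export
profile_cohort <- function(cohort, pixel_size_um = NULL,
                           config = measure_config(),
                           thresholds = classify_thresholds(), ...) {
  if (inherits(cohort, "organoid_cohort")) {
    images <- cohort$images
    ps <- cohort$manifest$pixel_size_um[1]
  } else {
    images <- cohort
    ps <- pixel_size_um
    if (is.null(ps)) stop("pixel_size_um required for a bare image list")
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    sm <- segment(images[[i]], ps, ...)
    gr <- skeleton_graph(sm)
    rec <- measure(sm, gr, image = images[[i]], config = config)
    cl <- classify_rule_based(rec, thresholds)
    rows[[i]] <- cbind(as.data.frame(rec),
                       data.frame(label = cl$label,
                                  label_margin = cl$margin,
                                  stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
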