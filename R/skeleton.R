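#' Build a skeleton graph from a segmentation mask
#'
#' The mask is hole-filled (lumens are quantified separately as holes, see
#' [measure()]), thinned to a 1-px skeleton (Zhang-Suen) per connected
#' component, and traced into a node/edge graph: endpoints (degree 1),
#' branch nodes (degree >= 3) and edges carrying arc length and a radius
#' profile from the Euclidean distance transform.
#'
#' Thinning artefacts scale with the local radius, so pruning is adaptive:
#' a terminal spur is removed when it adds no mask coverage beyond its
#' junction's inscribed disk (`length + tip radius < spur_radius_factor *
#' junction radius + prune_spur_um`), and junction-junction edges
#' shorter than `merge_radius_factor * local radius` are contracted (this
#' collapses the junction cloud inside a thick core into a single branch
#' node). Components whose whole skeleton is shorter than
#' `blob_length_factor * max inscribed radius` are compact blobs (disks)
#' and contribute no endpoints or branch nodes.
#'
#' @param mask a [segment()] result, or a logical matrix (then
#'   `pixel_size_um` must be given).
#' @param prune_spur_um minimum spur length retained, in micrometres.
#' @param spur_radius_factor,merge_radius_factor,blob_length_factor
#'   radius-adaptive pruning factors (see above).
#' @param pixel_size_um pixel size when `mask` is a bare matrix.
#' @return a `skeleton_graph`: lists `nodes` (id, row, col, kind,
#'   radius_um, component), `edges` (from, to, length_um, mean_radius_um,
#'   max_radius_um, tip radii, component), `cycles`, `lumens` (per-hole
#'   areas), `n_components`, `max_dt_um` and `pixel_size_um`.
#' @examples
#' m <- matrix(FALSE, 60, 60); m[28:32, 10:50] <- TRUE  # a straight bar
#' g <- skeleton_graph(m, pixel_size_um = 1)
#' sum(g$nodes$kind == "endpoint")
#' @export
skeleton_graph <- function(mask, prune_spur_um = 10, spur_radius_factor = 1.0,
                           merge_radius_factor = 1.5, blob_length_factor = 2.5,
                           pixel_size_um = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    ps <- mask$pixel_size_um
    m <- mask$mask
  } else {
    if (is.null(pixel_size_um))
      stop("pixel_size_um is required when mask is a bare matrix")
    ps <- pixel_size_um
    m <- mask
  }
  empty <- function() structure(list(
    nodes = data.frame(id = integer(), row = numeric(), col = numeric(),
                       kind = character(), radius_um = numeric(),
                       component = integer()),
    edges = data.frame(from = integer(), to = integer(),
                       length_um = numeric(), mean_radius_um = numeric(),
                       max_radius_um = numeric(), tip_radius_from_um = numeric(),
                       tip_radius_to_um = numeric(), component = integer()),
    cycles = data.frame(component = integer(), length_um = numeric()),
    lumens = data.frame(component = integer(), area_um2 = numeric()),
    n_components = 0L, n_blob_components = 0L, max_dt_um = 0,
    skeleton_length_um = 0, pixel_size_um = ps), class = "skeleton_graph")
  if (!any(m)) return(empty())

  lab <- EBImage::bwlabel(m)
  filled <- EBImage::fillHull(lab) > 0
  holes <- filled & !m
  lumens <- data.frame(component = integer(), area_um2 = numeric())
  if (any(holes)) {
    hl <- EBImage::bwlabel(holes)
    ha <- tabulate(hl[hl > 0])
    if (length(ha))
      lumens <- data.frame(component = seq_along(ha), area_um2 = ha * ps^2)
  }
  labf <- EBImage::bwlabel(filled)
  ncomp <- max(labf)
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(filled)))

  prune_px <- prune_spur_um / ps
  all_nodes <- list(); all_edges <- list(); all_cycles <- list()
  id_off <- 0L; n_blob <- 0L; skel_len <- 0
  for (cc in seq_len(ncomp)) {
    idx <- which(labf == cc, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(nrow(m), max(idx[, 1]) + 2L)
    c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(ncol(m), max(idx[, 2]) + 2L)
    sub <- labf[r0:r1, c0:c1] == cc
    sdt <- dt[r0:r1, c0:c1]
    skel <- cpp_thin(sub)
    g <- cpp_skel_graph(skel, sdt)
    nodes <- g$nodes; edges <- g$edges
    raw_len <- sum(edges$length_px) + sum(g$cycle_lengths_px)
    maxdt <- max(sdt[sub])
    skel_len <- skel_len + raw_len * ps
    if (raw_len <= blob_length_factor * maxdt || nrow(nodes) == 0) {
      n_blob <- n_blob + 1L
      next
    }
    sg <- simplify_skel(nodes, edges, prune_px, spur_radius_factor,
                        merge_radius_factor)
    nodes <- sg$nodes; edges <- sg$edges
    if (nrow(nodes) == 0 && length(g$cycle_lengths_px) == 0) {
      n_blob <- n_blob + 1L
      next
    }
    if (nrow(nodes)) {
      nodes$row <- nodes$row + r0 - 1; nodes$col <- nodes$col + c0 - 1
      remap <- seq_len(nrow(nodes)) + id_off
      names(remap) <- nodes$id
      nodes$id <- unname(remap)
      if (nrow(edges)) {
        edges$from <- unname(remap[as.character(edges$from)])
        edges$to <- unname(remap[as.character(edges$to)])
      }
      id_off <- id_off + nrow(nodes)
    }
    deg <- node_degrees(nodes, edges)
    all_nodes[[cc]] <- data.frame(id = nodes$id, row = nodes$row,
      col = nodes$col,
      kind = ifelse(deg >= 3, "branch_node",
                    ifelse(deg == 1, "endpoint", "cycle_node")),
      radius_um = nodes$r_px * ps, component = cc)
    if (nrow(edges))
      all_edges[[cc]] <- data.frame(from = edges$from, to = edges$to,
        length_um = edges$length_px * ps, mean_radius_um = edges$mean_r_px * ps,
        max_radius_um = edges$max_r_px * ps,
        tip_radius_from_um = edges$tip_r_from * ps,
        tip_radius_to_um = edges$tip_r_to * ps, component = cc)
    if (length(g$cycle_lengths_px))
      all_cycles[[cc]] <- data.frame(component = cc,
                                     length_um = g$cycle_lengths_px * ps)
  }
  out <- empty()
  if (length(all_nodes)) out$nodes <- do.call(rbind, all_nodes)
  if (length(all_edges)) out$edges <- do.call(rbind, all_edges)
  if (length(all_cycles)) out$cycles <- do.call(rbind, all_cycles)
  out$lumens <- lumens
  out$n_components <- as.integer(ncomp)
  out$n_blob_components <- n_blob
  out$max_dt_um <- max(dt) * ps
  out$skeleton_length_um <- skel_len
  out
}

node_degrees <- function(nodes, edges) {
  if (nrow(nodes) == 0) return(integer())
  deg <- integer(nrow(nodes))
  if (nrow(edges)) {
    t1 <- table(factor(edges$from, levels = nodes$id))
    t2 <- table(factor(edges$to, levels = nodes$id))
    deg <- as.integer(t1 + t2)
  }
  deg
}

# Iterative simplification of a raw traced skeleton: contract short
# junction-junction edges, prune short terminal spurs (radius-adaptive),
# splice out degree-2 pass-through nodes. Operates in pixel units.
simplify_skel <- function(nodes, edges, prune_px, spur_factor, merge_factor) {
  nodes <- as.data.frame(nodes); edges <- as.data.frame(edges)
  # micro self-loops are tracing artefacts (1-px triangles at cluster rims);
  # genuine cycles (net-like masks) are far longer
  if (nrow(edges))
    edges <- edges[!(edges$from == edges$to & edges$length_px < 15), ,
                   drop = FALSE]
  guard <- 0
  repeat {
    guard <- guard + 1
    if (guard > 500) break
    changed <- FALSE
    deg <- node_degrees(nodes, edges)
    names(deg) <- nodes$id

    # prune the shortest eligible terminal spur
    if (nrow(edges)) {
      df <- deg[as.character(edges$from)]; dt_ <- deg[as.character(edges$to)]
      leaf_from <- df == 1 & dt_ >= 3
      leaf_to <- dt_ == 1 & df >= 3
      cand <- which(leaf_from | leaf_to)
      if (length(cand)) {
        # an artefact spur adds no mask coverage: the disk around its tip
        # is (nearly) contained in the junction's inscribed disk. A genuine
        # short branch (e.g. a terminal end bud) protrudes beyond it.
        leaf_id <- ifelse(leaf_from[cand], edges$from[cand], edges$to[cand])
        junc_id <- ifelse(leaf_from[cand], edges$to[cand], edges$from[cand])
        il <- match(leaf_id, nodes$id); ij <- match(junc_id, nodes$id)
        eu <- sqrt((nodes$row[il] - nodes$row[ij])^2 +
                   (nodes$col[il] - nodes$col[ij])^2)
        sel <- cand[eu + nodes$r_px[il] <
                    spur_factor * nodes$r_px[ij] + prune_px]
        if (length(sel)) {
          e <- sel[which.min(edges$length_px[sel])]
          leaf <- if (leaf_from[e]) edges$from[e] else edges$to[e]
          edges <- edges[-e, , drop = FALSE]
          nodes <- nodes[nodes$id != leaf, , drop = FALSE]
          changed <- TRUE
        }
      }
    }

    # contract the shortest eligible junction-junction edge
    if (!changed && nrow(edges)) {
      deg <- node_degrees(nodes, edges); names(deg) <- nodes$id
      jj <- which(edges$from != edges$to &
                  deg[as.character(edges$from)] >= 3 &
                  deg[as.character(edges$to)] >= 3)
      if (length(jj)) {
        ia <- match(edges$from[jj], nodes$id); ib <- match(edges$to[jj], nodes$id)
        thr <- merge_factor * pmax(nodes$r_px[ia], nodes$r_px[ib])
        eu <- sqrt((nodes$row[ia] - nodes$row[ib])^2 +
                   (nodes$col[ia] - nodes$col[ib])^2)
        sel <- jj[eu < thr]
        if (length(sel)) {
          e <- sel[which.min(edges$length_px[sel])]
          a <- edges$from[e]; b <- edges$to[e]
          ia <- match(a, nodes$id); ib <- match(b, nodes$id)
          nodes$row[ia] <- (nodes$row[ia] + nodes$row[ib]) / 2
          nodes$col[ia] <- (nodes$col[ia] + nodes$col[ib]) / 2
          nodes$r_px[ia] <- max(nodes$r_px[ia], nodes$r_px[ib])
          edges <- edges[-e, , drop = FALSE]
          edges$from[edges$from == b] <- a
          edges$to[edges$to == b] <- a
          nodes <- nodes[-ib, , drop = FALSE]
          changed <- TRUE
        }
      }
    }

    # splice out one degree-2 pass-through node
    if (!changed && nrow(nodes)) {
      deg <- node_degrees(nodes, edges); names(deg) <- nodes$id
      v <- nodes$id[deg == 2]
      v <- v[vapply(v, function(id)
        sum(edges$from == id & edges$to == id) == 0, logical(1))]
      if (length(v)) {
        id <- v[1]
        ei <- which(edges$from == id | edges$to == id)
        if (length(ei) == 2) {
          e1 <- edges[ei[1], ]; e2 <- edges[ei[2], ]
          a <- if (e1$from == id) e1$to else e1$from
          b <- if (e2$from == id) e2$to else e2$from
          tip_a <- if (e1$from == id) e1$tip_r_to else e1$tip_r_from
          tip_b <- if (e2$from == id) e2$tip_r_to else e2$tip_r_from
          npx <- e1$npx + e2$npx + 1
          merged <- data.frame(from = a, to = b,
            length_px = e1$length_px + e2$length_px,
            mean_r_px = (e1$mean_r_px * e1$npx + e2$mean_r_px * e2$npx +
                         nodes$r_px[match(id, nodes$id)]) / npx,
            max_r_px = max(e1$max_r_px, e2$max_r_px,
                           nodes$r_px[match(id, nodes$id)]),
            tip_r_from = tip_a, tip_r_to = tip_b, npx = npx)
          edges <- rbind(edges[-ei, , drop = FALSE], merged)
          nodes <- nodes[nodes$id != id, , drop = FALSE]
          changed <- TRUE
        }
      }
    }

    if (!changed) break
  }
  # drop isolated nodes left over from pruning
  deg <- node_degrees(nodes, edges)
  nodes <- nodes[deg > 0, , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", sum(x$nodes$kind == "endpoint"), "endpoints,",
      sum(x$nodes$kind == "branch_node"), "branch nodes,",
      nrow(x$edges), "edges,", nrow(x$cycles), "cycles,",
      x$n_components, "component(s)\n")
  invisible(x)
}
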