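# Vector geometry for the synthetic generator. Organoids are unions of
# capsules (thick segments) and disks, with lumens carved as background
# holes; ground-truth morphometrics are computed from these primitives
# before rasterization, so they are exact by construction.

point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  l2 <- vx * vx + vy * vy
  if (l2 < 1e-12) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- clamp(((px - x1) * vx + (py - y1) * vy) / l2, 0, 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

segs_intersect <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

seg_seg_dist <- function(a, b) {
  if (segs_intersect(a, b)) return(0)
  min(point_seg_dist(a[1], a[2], b[1], b[2], b[3], b[4]),
      point_seg_dist(a[3], a[4], b[1], b[2], b[3], b[4]),
      point_seg_dist(b[1], b[2], a[1], a[2], a[3], a[4]),
      point_seg_dist(b[3], b[4], a[1], a[2], a[3], a[4]))
}

rot2 <- function(x, y, theta) {
  list(x = cos(theta) * x - sin(theta) * y,
       y = sin(theta) * x + cos(theta) * y)
}

empty_segs <- function() data.frame(x1 = numeric(), y1 = numeric(),
  x2 = numeric(), y2 = numeric(), r = numeric(), id = integer(),
  parent = integer())

empty_disks <- function() data.frame(x = numeric(), y = numeric(),
  r = numeric(), kind = character(), parent = integer())

# Minimum clearance between non-related primitives. Segments sharing an
# endpoint (radial spokes) or in a parent/child relation are exempt; so are
# disks sitting on their own parent segment.
clearance_ok <- function(segs, disks, gap = 6) {
  n <- nrow(segs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (identical(segs$parent[i], segs$id[j]) ||
          identical(segs$parent[j], segs$id[i])) next
      shared <- min(
        (segs$x1[i] - segs$x1[j])^2 + (segs$y1[i] - segs$y1[j])^2,
        (segs$x1[i] - segs$x2[j])^2 + (segs$y1[i] - segs$y2[j])^2,
        (segs$x2[i] - segs$x1[j])^2 + (segs$y2[i] - segs$y1[j])^2,
        (segs$x2[i] - segs$x2[j])^2 + (segs$y2[i] - segs$y2[j])^2) < 0.25
      if (shared) next
      d <- seg_seg_dist(unlist(segs[i, 1:4]), unlist(segs[j, 1:4]))
      if (d < segs$r[i] + segs$r[j] + gap) return(FALSE)
    }
  }
  if (nrow(disks) && n) {
    for (k in seq_len(nrow(disks))) {
      if (disks$kind[k] == "core") next  # spokes emanate from the core
      for (i in seq_len(n)) {
        if (identical(disks$parent[k], segs$id[i])) next
        d <- point_seg_dist(disks$x[k], disks$y[k],
                            segs$x1[i], segs$y1[i], segs$x2[i], segs$y2[i])
        if (d < disks$r[k] + segs$r[i] + gap) return(FALSE)
      }
    }
  }
  if (nrow(disks) > 1) {
    free <- which(disks$kind %in% c("bud", "blob"))
    if (length(free) > 1) {
      for (ii in seq_along(free)[-1]) for (jj in seq_len(ii - 1)) {
        i <- free[ii]; j <- free[jj]
        d <- sqrt((disks$x[i] - disks$x[j])^2 + (disks$y[i] - disks$y[j])^2)
        if (d < disks$r[i] + disks$r[j] + gap) return(FALSE)
      }
    }
  }
  TRUE
}

geom_trunk_family <- function(a, max_tries = 400) {
  L <- a$trunk_length_um
  rt <- a$trunk_thickness_um / 2
  nb <- a$n_main_branches
  # attachments need clearance along a thick trunk, or their skeleton
  # junction clouds fuse; cap the branch count by the available spacing
  if (nb > 0) {
    min_gap <- max(50, 1.7 * a$trunk_thickness_um)
    nb <- max(1L, min(nb, as.integer(floor(L / min_gap)) - 1L))
  }
  for (try in seq_len(max_tries)) {
    segs <- data.frame(x1 = -L / 2, y1 = 0, x2 = L / 2, y2 = 0, r = rt,
                       id = 1L, parent = NA_integer_)
    disks <- empty_disks()
    holes <- data.frame(x = numeric(), y = numeric(), r = numeric())
    tips <- list()  # candidate bud sites: main tips first, then trunk ends
    nid <- 1L
    # near-perpendicular branches keep clearance from on-trunk cysts
    ang_lo <- if (a$n_lumens > 0) 75 else 50
    ang_hi <- if (a$n_lumens > 0) 88 else 80
    if (a$n_lumens > 0) {
      # cap the cyst count at what the trunk can hold with clearance
      rc <- a$lumen_radius_um + 7
      need <- rc + a$main_branch_thickness_um / 2 + 7
      a$n_lumens <- max(2L, min(a$n_lumens,
                                1L + as.integer(floor(0.36 * L / need))))
    }
    cyst_fr <- if (a$n_lumens > 0)
      clamp(seq(0.14, 0.86, length.out = a$n_lumens) +
            runif(a$n_lumens, -0.01, 0.01), 0.12, 0.88) else numeric()
    if (nb > 0) {
      if (length(cyst_fr) > 1) {
        # interleave branch attachments midway between cysts
        mids <- (cyst_fr[-1] + cyst_fr[-length(cyst_fr)]) / 2
        fr <- mids[unique(round(seq(1, length(mids), length.out = min(nb, length(mids)))))]
        nb <- length(fr)
      } else {
        fr <- clamp(seq_len(nb) / (nb + 1) + runif(nb, -0.03, 0.03), 0.08, 0.92)
      }
      side <- rep(c(1, -1), length.out = nb) * sample(c(1, -1), 1)
      fwd <- sample(c(-1, 1), nb, replace = TRUE)
      ang <- runif(nb, ang_lo, ang_hi) * pi / 180
      len <- a$main_branch_length_um * exp(clamp(rnorm(nb, 0, 0.05), -0.1, 0.1))
      rb <- a$main_branch_thickness_um / 2
      for (i in seq_len(nb)) {
        ax <- -L / 2 + fr[i] * L
        dx <- fwd[i] * cos(ang[i]); dy <- side[i] * sin(ang[i])
        nid <- nid + 1L
        segs <- rbind(segs, data.frame(x1 = ax, y1 = 0,
          x2 = ax + len[i] * dx, y2 = len[i] * dy, r = rb,
          id = nid, parent = 1L))
        tips[[length(tips) + 1]] <- c(ax + len[i] * dx, len[i] * dy)
      }
      main_ids <- segs$id[-1]
      # depth-2 design: at most two sub-branches per main branch fit with
      # clearance on the attachment window
      nsub_per <- if (nb > 0) min(2L, a$n_sub_branches %/% nb) else 0L
      nsub_tot <- 0L
      if (nsub_per > 0) {
        for (m in seq_len(nb)) {
          ms <- segs[segs$id == main_ids[m], ]
          mdx <- (ms$x2 - ms$x1); mdy <- (ms$y2 - ms$y1)
          ml <- sqrt(mdx^2 + mdy^2); mdx <- mdx / ml; mdy <- mdy / ml
          # short mains hold one sub; keep attachments apart and clear of
          # the branch tip, so junction clouds and terminal stubs survive
          nsub_m <- if (ml < 90) 1L else nsub_per
          sfr <- clamp(seq(0.32, 0.62, length.out = nsub_m) +
                       runif(nsub_m, -0.03, 0.03), 0.28, 0.66)
          sside <- rep(c(1, -1), length.out = nsub_m) * sample(c(1, -1), 1)
          nsub_tot <- nsub_tot + nsub_m
          for (s in seq_len(nsub_m)) {
            rel <- sside[s] * runif(1, 35, 60) * pi / 180
            dd <- rot2(mdx, mdy, rel)
            ax <- ms$x1 + sfr[s] * ml * mdx
            ay <- ms$y1 + sfr[s] * ml * mdy
            sl <- a$sub_branch_length_um * exp(clamp(rnorm(1, 0, 0.05), -0.1, 0.1))
            nid <- nid + 1L
            segs <- rbind(segs, data.frame(x1 = ax, y1 = ay,
              x2 = ax + sl * dd$x, y2 = ay + sl * dd$y,
              r = a$sub_branch_thickness_um / 2, id = nid, parent = ms$id))
            tips[[length(tips) + 1]] <- c(ax + sl * dd$x, ay + sl * dd$y)
          }
        }
      }
    }
    tips[[length(tips) + 1]] <- c(L / 2, 0)
    tips[[length(tips) + 1]] <- c(-L / 2, 0)
    tip_parent <- c(if (nb > 0) segs$id[-1][seq_len(min(nb, length(tips)))] else integer(),
                    1L, 1L)
    nbud <- min(a$n_terminal_end_buds, length(tips))
    if (nbud > 0 && a$bud_radius_um > 0) {
      for (b in seq_len(nbud)) {
        disks <- rbind(disks, data.frame(x = tips[[b]][1], y = tips[[b]][2],
          r = a$bud_radius_um, kind = "bud", parent = tip_parent[b]))
      }
    }
    if (a$n_lumens > 0) {
      wall <- 7
      for (cidx in seq_len(a$n_lumens)) {
        cx <- -L / 2 + cyst_fr[cidx] * L
        disks <- rbind(disks, data.frame(x = cx, y = 0,
          r = a$lumen_radius_um + wall, kind = "cyst", parent = 1L))
        holes <- rbind(holes, data.frame(x = cx, y = 0, r = a$lumen_radius_um))
      }
    }
    if (clearance_ok(segs, disks)) {
      if (nb == 0) nsub_tot <- 0L
      return(list(segs = segs, disks = disks, holes = holes,
                  n_main = as.integer(nb),
                  n_nodes = nb + nsub_tot,
                  n_endpoints = 2L + nb + nsub_tot,
                  n_terminal_end_buds = if (a$bud_radius_um > 0)
                    min(a$n_terminal_end_buds, nb + 2L) else 0L,
                  n_spiky = if (a$name == "tree_like") nsub_tot else 0L))
    }
  }
  stop("could not draw a collision-free ", a$name, " geometry")
}

geom_radial_family <- function(a, max_tries = 400) {
  k <- if (a$name == "firework") a$n_spiky_branches else a$n_main_branches
  rs <- if (a$name == "firework") a$spike_thickness_um / 2
        else a$main_branch_thickness_um / 2
  len <- if (a$name == "firework") a$spike_length_um else a$main_branch_length_um
  Rc <- a$core_radius_um
  jit <- (if (a$name == "firework") 3 else 8) * pi / 180
  # spokes must separate inside the core, else thinning sees merged
  # branches; cap the spoke count and angular jitter accordingly
  needed <- (2 * rs + 2) / (0.8 * Rc)
  k <- max(3L, min(k, as.integer(floor(2 * pi / (needed * 1.15)))))
  jit <- max(0, min(jit, (2 * pi / k - needed) * 0.4))
  for (try in seq_len(max_tries)) {
    th <- sort((2 * pi * seq_len(k) / k + runif(k, -jit, jit)) %% (2 * pi))
    dth <- diff(c(th, th[1] + 2 * pi))
    sep_r <- (2 * rs + 2) / pmax(dth, 1e-6)
    if (any(sep_r > 0.85 * Rc)) next
    ll <- len * exp(clamp(rnorm(k, 0, 0.05), -0.1, 0.1))
    segs <- data.frame(x1 = 0, y1 = 0,
      x2 = (Rc + ll) * cos(th), y2 = (Rc + ll) * sin(th),
      r = rs, id = seq_len(k), parent = NA_integer_)
    disks <- data.frame(x = 0, y = 0, r = Rc, kind = "core", parent = NA_integer_)
    if (clearance_ok(segs, disks))
      return(list(segs = segs, disks = disks,
                  holes = data.frame(x = numeric(), y = numeric(), r = numeric()),
                  n_main = if (a$name == "firework") 0L else as.integer(k),
                  n_nodes = 1L, n_endpoints = as.integer(k),
                  n_terminal_end_buds = 0L,
                  n_spiky = if (a$name == "firework") as.integer(k) else 0L))
  }
  stop("could not draw a collision-free ", a$name, " geometry")
}

geom_clump <- function(a) {
  list(segs = empty_segs(),
       disks = data.frame(x = 0, y = 0, r = a$core_radius_um,
                          kind = "core", parent = NA_integer_),
       holes = data.frame(x = numeric(), y = numeric(), r = numeric()),
       n_nodes = 0L, n_endpoints = 0L, n_terminal_end_buds = 0L, n_spiky = 0L)
}

geom_scattered <- function(a, max_tries = 200) {
  n <- a$n_blobs
  rr <- runif(n, a$blob_radius_range_um[1], a$blob_radius_range_um[2])
  xs <- ys <- numeric(n)
  R <- 130
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- sqrt(runif(1)) * R; v <- runif(1, 0, 2 * pi)
      x <- u * cos(v); y <- u * sin(v)
      if (i == 1 || all(sqrt((x - xs[seq_len(i - 1)])^2 +
                             (y - ys[seq_len(i - 1)])^2) >
                        rr[i] + rr[seq_len(i - 1)] + 12)) {
        xs[i] <- x; ys[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place disconnected scattered blobs")
  }
  list(segs = empty_segs(),
       disks = data.frame(x = xs, y = ys, r = rr, kind = "blob",
                          parent = NA_integer_),
       holes = data.frame(x = numeric(), y = numeric(), r = numeric()),
       n_nodes = 0L, n_endpoints = 0L, n_terminal_end_buds = 0L, n_spiky = 0L)
}

# Build the primitive set for an archetype (uses the current RNG stream),
# apply a random global rotation, and compute exact ground truth.
build_geometry <- function(a) {
  g <- switch(a$name,
    clump = geom_clump(a),
    scattered = geom_scattered(a),
    star_like = , firework = , branched_mesenchymal = geom_radial_family(a),
    geom_trunk_family(a))
  theta <- runif(1, 0, 2 * pi)
  if (nrow(g$segs)) {
    p1 <- rot2(g$segs$x1, g$segs$y1, theta)
    p2 <- rot2(g$segs$x2, g$segs$y2, theta)
    g$segs$x1 <- p1$x; g$segs$y1 <- p1$y; g$segs$x2 <- p2$x; g$segs$y2 <- p2$y
  }
  for (nm in c("disks", "holes")) {
    if (nrow(g[[nm]])) {
      p <- rot2(g[[nm]]$x, g[[nm]]$y, theta)
      g[[nm]]$x <- p$x; g[[nm]]$y <- p$y
    }
  }
  # enclosing circles of every solid primitive -> exact maximum Feret diameter
  cx <- c(g$segs$x1, g$segs$x2, g$disks$x)
  cy <- c(g$segs$y1, g$segs$y2, g$disks$y)
  cr <- c(g$segs$r, g$segs$r, g$disks$r)
  major <- 0
  if (length(cx)) {
    for (i in seq_along(cx)) {
      d <- sqrt((cx - cx[i])^2 + (cy - cy[i])^2) + cr + cr[i]
      major <- max(major, d)
    }
  }
  g$truth <- list(
    major_axis_um = major,
    core_thickness_um = 2 * max(c(g$segs$r, g$disks$r, 0)),
    n_main_branches = g$n_main %||% a$n_main_branches,
    n_nodes = g$n_nodes,
    n_endpoints = g$n_endpoints,
    n_terminal_end_buds = g$n_terminal_end_buds,
    n_lumens = nrow(g$holes),
    n_spiky_branches = g$n_spiky,
    total_lumen_area_um2 = if (nrow(g$holes)) sum(pi * g$holes$r^2) else 0,
    core_area_um2 = if (any(g$disks$kind == "core"))
      pi * max(g$disks$r[g$disks$kind == "core"])^2 else 0,
    n_components = if (a$name == "scattered") a$n_blobs else 1L)
  g
}
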