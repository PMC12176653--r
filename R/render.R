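#' Render one synthetic branched organoid with exact ground truth
#'
#' Draws an archetype geometry (capsule branches, disk cores/buds, carved
#' lumen holes), rasterizes it at the requested pixel size and emulates a
#' brightfield image: dark organoid on a bright background, multiplicative
#' speckle inside the mask (granularity), Gaussian blur (sigma 1 px) and
#' additive Gaussian pixel noise. The returned ground truth is computed from
#' the vector geometry before rasterization and noise, so it is exact.
#'
#' @param archetype a [phenotype_archetype()] (or an archetype name).
#' @param canvas_px integer pair, image height and width in pixels.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param noise_level standard deviation of additive Gaussian noise
#'   (intensity units; the image spans roughly 0.3-0.85).
#' @param seed integer seed; identical arguments give bit-identical images.
#' @return a list with `image` (numeric matrix in `[0,1]`), `mask` (the
#'   pre-noise logical foreground raster) and `truth` (a `ground_truth` row:
#'   phenotype, exact morphometrics, pixel size, seed).
#' @examples
#' g <- generate_organoid_image(phenotype_archetype("clump"), seed = 7)
#' g$truth$n_nodes  # a clump has no branch points
#' @export
generate_organoid_image <- function(archetype, canvas_px = c(512L, 512L),
                                    pixel_size_um = 1.29, noise_level = 0.02,
                                    seed = 1L) {
  if (is.character(archetype)) archetype <- phenotype_archetype(archetype)
  stopifnot(inherits(archetype, "phenotype_archetype"))
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  if (noise_level < 0) stop("noise_level must be >= 0")
  with_seed(seed, {
    geom <- build_geometry(archetype)
    mask <- rasterize_geometry(geom, canvas_px, pixel_size_um)
    img <- render_brightfield(mask, noise_level, archetype$granularity_sigma)
    truth <- c(list(phenotype = archetype$name), geom$truth,
               list(pixel_size_um = pixel_size_um, seed = as.integer(seed)))
    class(truth) <- "ground_truth"
    list(image = img, mask = mask, truth = truth)
  })
}

rasterize_geometry <- function(geom, canvas_px, ps, margin_px = 3) {
  ny <- as.integer(canvas_px[1]); nx <- as.integer(canvas_px[2])
  cx0 <- (nx + 1) / 2; cy0 <- (ny + 1) / 2
  to_px <- function(x, y) list(x = x / ps + cx0, y = y / ps + cy0)
  # explicit bounds check: silent cropping would corrupt the ground truth
  ext <- c(
    if (nrow(geom$segs)) c(abs(c(geom$segs$x1, geom$segs$x2)) + geom$segs$r,
                           abs(c(geom$segs$y1, geom$segs$y2)) + geom$segs$r),
    if (nrow(geom$disks)) c(abs(geom$disks$x) + geom$disks$r,
                            abs(geom$disks$y) + geom$disks$r))
  half_um <- (min(nx, ny) / 2 - margin_px) * ps
  if (length(ext) && max(ext) > half_um)
    stop("geometry (extent ", round(max(ext)), " um) exceeds the canvas (",
         round(half_um), " um half-width); enlarge canvas_px or shrink the archetype")

  mask <- matrix(FALSE, ny, nx)
  paint <- function(mask, x, y, r, value) {
    p <- to_px(x, y); pr <- r / ps
    jr <- max(1L, floor(min(p$x) - max(pr) - 1)):min(nx, ceiling(max(p$x) + max(pr) + 1))
    ir <- max(1L, floor(min(p$y) - max(pr) - 1)):min(ny, ceiling(max(p$y) + max(pr) + 1))
    list(ir = ir, jr = jr)
  }
  if (nrow(geom$disks)) for (k in seq_len(nrow(geom$disks))) {
    d <- geom$disks[k, ]
    b <- paint(mask, d$x, d$y, d$r, TRUE)
    p <- to_px(d$x, d$y); pr <- d$r / ps
    dd <- outer((b$ir - p$y)^2, (b$jr - p$x)^2, "+")
    mask[b$ir, b$jr] <- mask[b$ir, b$jr] | (dd <= pr^2)
  }
  if (nrow(geom$segs)) for (k in seq_len(nrow(geom$segs))) {
    s <- geom$segs[k, ]
    b <- paint(mask, c(s$x1, s$x2), c(s$y1, s$y2), s$r, TRUE)
    p1 <- to_px(s$x1, s$y1); p2 <- to_px(s$x2, s$y2); pr <- s$r / ps
    vx <- p2$x - p1$x; vy <- p2$y - p1$y
    l2 <- max(vx^2 + vy^2, 1e-12)
    X <- matrix(b$jr, length(b$ir), length(b$jr), byrow = TRUE)
    Y <- matrix(b$ir, length(b$ir), length(b$jr))
    tt <- clamp(((X - p1$x) * vx + (Y - p1$y) * vy) / l2, 0, 1)
    dd <- (X - (p1$x + tt * vx))^2 + (Y - (p1$y + tt * vy))^2
    mask[b$ir, b$jr] <- mask[b$ir, b$jr] | (dd <= pr^2)
  }
  if (nrow(geom$holes)) for (k in seq_len(nrow(geom$holes))) {
    h <- geom$holes[k, ]
    b <- paint(mask, h$x, h$y, h$r, FALSE)
    p <- to_px(h$x, h$y); pr <- h$r / ps
    dd <- outer((b$ir - p$y)^2, (b$jr - p$x)^2, "+")
    mask[b$ir, b$jr] <- mask[b$ir, b$jr] & !(dd <= pr^2)
  }
  mask
}

render_brightfield <- function(mask, noise_level, granularity_sigma,
                               bg = 0.85, fg = 0.30) {
  img <- matrix(bg, nrow(mask), ncol(mask))
  n_in <- sum(mask)
  if (n_in) {
    val <- rep(fg, n_in)
    if (granularity_sigma > 0)
      val <- clamp(fg * (1 + granularity_sigma * rnorm(n_in)), 0.05, bg)
    img[mask] <- val
  }
  img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = 1))
  if (noise_level > 0) img <- img + rnorm(length(img), 0, noise_level)
  clamp(img, 0, 1)
}

#' Generate a labelled cohort of synthetic organoid images
#'
#' Per-organoid archetype parameters are drawn around the family defaults
#' with multiplicative lognormal jitter, each organoid gets its own sub-seed
#' split from the master seed, and the dataset order is shuffled
#' deterministically.
#'
#' @param spec named vector or list mapping archetype names to image counts.
#' @param jitter relative standard deviation applied to archetype parameters
#'   (0 disables jitter).
#' @param seed master seed.
#' @inheritParams generate_organoid_image
#' @return an `organoid_cohort`: list with `images` (list of matrices),
#'   `masks` (pre-noise rasters) and `manifest` (one row per organoid with
#'   phenotype label, per-organoid seed, pixel size and all ground-truth
#'   fields).
#' @examples
#' co <- generate_cohort(c(clump = 2, star_like = 2), jitter = 0, seed = 3)
#' table(co$manifest$phenotype)
#' @export
generate_cohort <- function(spec, jitter = 0.1, seed = 1L,
                            canvas_px = c(512L, 512L), pixel_size_um = 1.29,
                            noise_level = 0.02) {
  spec <- unlist(spec)
  if (length(spec) == 0) stop("`spec` must name at least one archetype")
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("`spec` must be named by archetype")
  bad <- setdiff(names(spec), archetype_names())
  if (length(bad)) stop("unknown archetypes: ", paste(bad, collapse = ", "))
  if (any(spec < 1) || any(spec != round(spec))) stop("counts must be integers >= 1")
  if (jitter < 0) stop("jitter must be >= 0")

  labels <- rep(names(spec), times = spec)
  n <- length(labels)
  seeds <- split_seeds(seed, n + 1L)
  ord <- with_seed(seeds[n + 1L], sample.int(n))
  labels <- labels[ord]
  seeds <- seeds[seq_len(n)]  # sub-seed follows dataset position

  images <- vector("list", n)
  masks <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- with_seed(seeds[i] + 1L,
                      jitter_archetype(archetype_defaults(labels[i]), jitter))
    class(arch) <- "phenotype_archetype"
    g <- generate_organoid_image(arch, canvas_px = canvas_px,
                                 pixel_size_um = pixel_size_um,
                                 noise_level = noise_level, seed = seeds[i])
    images[[i]] <- g$image
    masks[[i]] <- g$mask
    rows[[i]] <- data.frame(id = i, file = NA_character_,
                            phenotype = labels[i],
                            c(g$truth[setdiff(names(g$truth), "phenotype")]),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  structure(list(images = images, masks = masks, manifest = manifest,
                 seed = as.integer(seed), jitter = jitter),
            class = "organoid_cohort")
}

#' Write a cohort to disk as 8-bit PNG images plus a manifest CSV
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return the manifest data frame (invisibly), with `file` filled in.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "organoid_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$images)) {
    f <- file.path(dir, sprintf("organoid_%04d_%s.png", i, man$phenotype[i]))
    png::writePNG(cohort$images[[i]], f)
    man$file[i] <- f
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' @export
print.organoid_cohort <- function(x, ...) {
  cat("organoid_cohort:", length(x$images), "images,",
      length(unique(x$manifest$phenotype)), "phenotypes (seed", x$seed,
      ", jitter", x$jitter, ")\n")
  print(table(x$manifest$phenotype))
  invisible(x)
}
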