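#' Segment a brightfield-style organoid image
#'
#' Thresholds the (optionally re-blurred) image with Otsu's method, taking
#' the dark phase as foreground, removes objects below a minimum area and
#' optionally keeps only the largest connected component. The component
#' count before the largest-component step is always recorded, so
#' scattered/multi-object detection still works downstream.
#'
#' @param image single-channel numeric matrix in `[0, 1]`.
#' @param pixel_size_um pixel edge length in micrometres.
#' @param min_object_area_um2 objects smaller than this are removed.
#' @param keep_largest keep only the largest connected component.
#' @param threshold fixed foreground threshold; `NULL` (default) uses Otsu.
#' @return a `segmentation_mask`: list with `mask` (logical matrix),
#'   `pixel_size_um`, `n_components` (after area filtering, before the
#'   largest-component step), `largest_component_only`, `threshold` and
#'   `blank` (TRUE when the image carried no usable contrast).
#' @examples
#' g <- generate_organoid_image("clump", seed = 2)
#' m <- segment(g$image, 1.29)
#' m$n_components
#' @export
segment <- function(image, pixel_size_um, min_object_area_um2 = 25,
                    keep_largest = TRUE, threshold = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a single-channel numeric matrix")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  ps <- pixel_size_um
  out <- function(mask, ncomp, th, blank = FALSE) {
    structure(list(mask = mask, pixel_size_um = ps,
                   n_components = as.integer(ncomp),
                   largest_component_only = keep_largest,
                   threshold = th, blank = blank),
              class = "segmentation_mask")
  }
  rng <- range(image)
  if (!all(is.finite(rng)) || diff(rng) < 0.05)
    return(out(matrix(FALSE, nrow(image), ncol(image)), 0L, NA_real_,
               blank = TRUE))
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(clamp(image, 0, 1)),
                               range = c(0, 1))
  }
  mask <- image < threshold
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(out(mask & FALSE, 0L, threshold, blank = TRUE))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas * ps^2 >= min_object_area_um2)
  mask <- matrix(lab %in% keep, nrow(image), ncol(image))
  ncomp <- length(keep)
  if (ncomp == 0) return(out(mask, 0L, threshold, blank = TRUE))
  if (keep_largest && ncomp > 1) {
    big <- keep[which.max(areas[keep])]
    mask <- matrix(lab == big, nrow(image), ncol(image))
  }
  out(mask, ncomp, threshold)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("segmentation_mask:", sum(x$mask), "px foreground,",
      x$n_components, "component(s), pixel size", x$pixel_size_um, "um\n")
  invisible(x)
}
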