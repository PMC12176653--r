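#' Phenotype archetype parameter sets
#'
#' A `phenotype_archetype` bundles the geometric parameters from which the
#' synthetic generator renders one organoid family. The eight murine families
#' mirror the taxonomy used for branched pancreatic-cancer organoids: four
#' epithelial (terminal end bud branching organoid "TEBBO", cystic branched,
#' thick branched, tree-like) and four mesenchymal (branched mesenchymal,
#' firework, star-like, clump), plus the auxiliary post-treatment "scattered"
#' phenotype (disconnected cell debris).
#'
#' All lengths are in micrometres. Fields beyond the core set (branch lengths
#' and thicknesses, scattered blob count) parameterize the renderer.
#'
#' @param name archetype name, one of [archetype_names()].
#' @param ... overrides for individual fields of the family default.
#' @return an object of class `phenotype_archetype` (a named list).
#' @examples
#' a <- phenotype_archetype("clump", core_radius_um = 50)
#' a$core_radius_um
#' @export
phenotype_archetype <- function(name, ...) {
  name <- match.arg(name, archetype_names())
  a <- archetype_defaults(name)
  dots <- list(...)
  bad <- setdiff(names(dots), names(a))
  if (length(bad)) stop("unknown archetype fields: ", paste(bad, collapse = ", "))
  a[names(dots)] <- dots
  validate_archetype(a)
  structure(a, class = "phenotype_archetype")
}

#' @rdname phenotype_archetype
#' @export
archetype_names <- function() {
  c("TEBBO", "cystic_branched", "thick_branched", "tree_like",
    "branched_mesenchymal", "firework", "star_like", "clump", "scattered")
}

#' The eight murine organoid families (scattered excluded)
#' @return character vector of family names.
#' @export
murine_families <- function() setdiff(archetype_names(), "scattered")

archetype_defaults <- function(name) {
  base <- list(
    name = name,
    trunk_length_um = 0, trunk_thickness_um = 0,
    n_main_branches = 0L, n_sub_branches = 0L,
    n_terminal_end_buds = 0L, bud_radius_um = 0,
    n_lumens = 0L, lumen_radius_um = 0,
    core_radius_um = 0, n_spiky_branches = 0L,
    granularity_sigma = 0.04,
    main_branch_length_um = 0, main_branch_thickness_um = 0,
    sub_branch_length_um = 0, sub_branch_thickness_um = 0,
    spike_length_um = 0, spike_thickness_um = 0,
    n_blobs = 0L, blob_radius_range_um = c(3, 8))
  ov <- switch(name,
    TEBBO = list(trunk_length_um = 340, trunk_thickness_um = 22,
                 n_main_branches = 4L, n_terminal_end_buds = 5L,
                 bud_radius_um = 20,
                 main_branch_length_um = 120, main_branch_thickness_um = 16),
    cystic_branched = list(trunk_length_um = 340, trunk_thickness_um = 26,
                 n_main_branches = 2L, n_lumens = 3L, lumen_radius_um = 15,
                 main_branch_length_um = 100, main_branch_thickness_um = 16),
    thick_branched = list(trunk_length_um = 340, trunk_thickness_um = 34,
                 n_main_branches = 3L, granularity_sigma = 0.10,
                 main_branch_length_um = 110, main_branch_thickness_um = 26),
    tree_like = list(trunk_length_um = 300, trunk_thickness_um = 16,
                 n_main_branches = 4L, n_sub_branches = 8L,
                 n_spiky_branches = 8L,
                 main_branch_length_um = 130, main_branch_thickness_um = 13,
                 sub_branch_length_um = 70, sub_branch_thickness_um = 10),
    branched_mesenchymal = list(core_radius_um = 42, n_main_branches = 5L,
                 granularity_sigma = 0.08,
                 main_branch_length_um = 140, main_branch_thickness_um = 18),
    firework = list(core_radius_um = 25, n_spiky_branches = 16L,
                 spike_length_um = 120, spike_thickness_um = 5),
    star_like = list(core_radius_um = 75, n_main_branches = 6L,
                 main_branch_length_um = 95, main_branch_thickness_um = 10),
    clump = list(core_radius_um = 60, granularity_sigma = 0.06),
    scattered = list(n_blobs = 12L))
  base[names(ov)] <- ov
  base
}

validate_archetype <- function(a) {
  num <- c("trunk_length_um", "trunk_thickness_um", "bud_radius_um",
           "lumen_radius_um", "core_radius_um", "granularity_sigma",
           "main_branch_length_um", "main_branch_thickness_um",
           "sub_branch_length_um", "sub_branch_thickness_um",
           "spike_length_um", "spike_thickness_um")
  for (f in num)
    if (!is.numeric(a[[f]]) || any(a[[f]] < 0)) stop("field `", f, "` must be >= 0")
  cnt <- c("n_main_branches", "n_sub_branches", "n_terminal_end_buds",
           "n_lumens", "n_spiky_branches", "n_blobs")
  for (f in cnt)
    if (any(a[[f]] < 0) || any(a[[f]] != round(a[[f]]))) stop("field `", f, "` must be a count")
  if (a$name == "TEBBO" && a$n_terminal_end_buds < 1)
    stop("TEBBO requires n_terminal_end_buds >= 1")
  if (a$name == "clump" && (a$n_main_branches > 0 || a$n_sub_branches > 0))
    stop("clump has no branches")
  if (a$name == "star_like" && (a$core_radius_um <= 0 || a$n_main_branches < 3))
    stop("star_like requires core_radius_um > 0 and n_main_branches >= 3")
  if (a$name == "scattered" && a$n_blobs < 2)
    stop("scattered requires at least 2 blobs")
  invisible(a)
}

# Draw a jittered copy of an archetype: continuous fields get lognormal
# multiplicative jitter (relative sd `jitter`), counts are resampled around
# the default with the same relative spread, respecting family minima.
jitter_archetype <- function(a, jitter) {
  if (jitter <= 0) return(a)
  cont <- c("trunk_length_um", "trunk_thickness_um", "bud_radius_um",
            "lumen_radius_um", "core_radius_um",
            "main_branch_length_um", "main_branch_thickness_um",
            "sub_branch_length_um", "sub_branch_thickness_um",
            "spike_length_um", "spike_thickness_um")
  jdraw <- function(sd) exp(clamp(rnorm(1, 0, sd), -2.5 * sd, 2.5 * sd))
  for (f in cont)
    if (a[[f]] > 0) a[[f]] <- a[[f]] * jdraw(jitter)
  cnt_min <- c(n_main_branches = 0, n_sub_branches = 0, n_terminal_end_buds = 0,
               n_lumens = 0, n_spiky_branches = 0, n_blobs = 0)
  if (a$name == "TEBBO") cnt_min["n_terminal_end_buds"] <- 1
  if (a$name == "star_like") cnt_min["n_main_branches"] <- 3
  if (a$name == "scattered") cnt_min["n_blobs"] <- 2
  for (f in names(cnt_min)) {
    v <- a[[f]]
    if (v > 0) {
      v <- as.integer(round(v * jdraw(jitter)))
      a[[f]] <- max(v, as.integer(cnt_min[[f]]), if (v > 0) 1L else 0L)
    }
  }
  # sub-branches and spikes of tree-like stay tied to the main-branch count
  if (a$name == "tree_like") {
    a$n_sub_branches <- 2L * a$n_main_branches
    a$n_spiky_branches <- a$n_sub_branches
  }
  if (a$name == "firework") a$n_spiky_branches <- max(a$n_spiky_branches, 8L)
  if (a$name == "TEBBO")
    a$n_terminal_end_buds <- min(a$n_terminal_end_buds, a$n_main_branches + 1L)
  a
}
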