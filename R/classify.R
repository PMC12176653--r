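#' Decision thresholds for rule-based phenotype classification
#'
#' The classifier is a fixed-order decision list over morphometric
#' descriptors; these thresholds parameterize the individual rules. Units
#' are micrometres for radii and dimensionless otherwise.
#'
#' @param scattered_min_components minimum connected components for the
#'   scattered (post-treatment debris) call.
#' @param clump_max_endpoints maximum skeleton endpoints for a clump.
#' @param star_min_circularity,star_min_core_radius_um,star_min_core_frac
#'   star-like requires a near-perfect circular core (the family breaks
#'   circular symmetry only by its invasive branches), a large inscribed
#'   radius and a core dominating the mask area.
#' @param firework_min_endpoints,firework_max_nodes fireworks radiate many
#'   thin branches from a single small centre.
#' @param mesenchymal_min_core_radius_um,mesenchymal_min_endpoints branched
#'   mesenchymal organoids carry a thick cellular core plus invasive
#'   branches.
#' @param cystic_min_lumens cystic branched organoids show swollen lumens.
#' @param tebbo_min_buds TEBBOs carry bulbous terminal end buds.
#' @param tree_min_nodes tree-like organoids have the most branch points.
#' @return a named list of thresholds.
#' @export
classify_thresholds <- function(scattered_min_components = 3,
                                clump_max_endpoints = 1,
                                star_min_circularity = 0.85,
                                star_min_core_radius_um = 55,
                                star_min_core_frac = 0.5,
                                firework_min_endpoints = 8,
                                firework_max_nodes = 2,
                                mesenchymal_min_core_radius_um = 30,
                                mesenchymal_min_endpoints = 3,
                                cystic_min_lumens = 2,
                                tebbo_min_buds = 2,
                                tree_min_nodes = 6) {
  as.list(environment())
}

#' Rule-based phenotype classification of a morphometric record
#'
#' Evaluates a fixed-order decision list (scattered, clump, star-like,
#' firework, branched mesenchymal, cystic branched, TEBBO, tree-like,
#' thick branched, unclassified) and returns the first matching label
#' together with the relative margin on the rule's discriminating feature.
#'
#' @param record a [measure()] result.
#' @param thresholds a [classify_thresholds()].
#' @return list with `label`, `margin` (signed relative margin on the
#'   discriminating feature) and `rule` (the feature that fired).
#' @examples
#' g <- generate_organoid_image("clump", seed = 5)
#' m <- segment(g$image, 1.29)
#' classify_rule_based(measure(m, skeleton_graph(m)))$label
#' @export
classify_rule_based <- function(record, thresholds = classify_thresholds()) {
  r <- record; th <- thresholds
  if (!all(vapply(unclass(r), function(v) all(is.finite(v)), logical(1))))
    stop("record contains non-finite values")
  margin <- function(value, thr) (value - thr) / max(abs(thr), 1e-9)
  core_radius <- r$core_thickness_um / 2
  core_frac <- if (r$mask_area_um2 > 0) r$core_area_um2 / r$mask_area_um2 else 0

  if (r$n_components >= th$scattered_min_components)
    return(list(label = "scattered",
                margin = margin(r$n_components, th$scattered_min_components),
                rule = "n_components"))
  if (r$n_endpoints <= th$clump_max_endpoints && r$n_nodes == 0 &&
      r$mask_area_um2 > 0)
    return(list(label = "clump",
                margin = margin(th$clump_max_endpoints, r$n_endpoints),
                rule = "n_endpoints"))
  if (r$core_circularity >= th$star_min_circularity &&
      core_radius >= th$star_min_core_radius_um &&
      core_frac >= th$star_min_core_frac &&
      r$n_endpoints >= 3)
    return(list(label = "star_like",
                margin = margin(core_radius, th$star_min_core_radius_um),
                rule = "core_radius"))
  if (r$n_endpoints >= th$firework_min_endpoints &&
      r$n_nodes <= th$firework_max_nodes)
    return(list(label = "firework",
                margin = margin(r$n_endpoints, th$firework_min_endpoints),
                rule = "n_endpoints"))
  if (core_radius >= th$mesenchymal_min_core_radius_um &&
      r$n_endpoints >= th$mesenchymal_min_endpoints)
    return(list(label = "branched_mesenchymal",
                margin = margin(core_radius, th$mesenchymal_min_core_radius_um),
                rule = "core_radius"))
  if (r$n_lumens >= th$cystic_min_lumens)
    return(list(label = "cystic_branched",
                margin = margin(r$n_lumens, th$cystic_min_lumens),
                rule = "n_lumens"))
  if (r$n_terminal_end_buds >= th$tebbo_min_buds)
    return(list(label = "TEBBO",
                margin = margin(r$n_terminal_end_buds, th$tebbo_min_buds),
                rule = "n_terminal_end_buds"))
  if (r$n_nodes >= th$tree_min_nodes)
    return(list(label = "tree_like",
                margin = margin(r$n_nodes, th$tree_min_nodes),
                rule = "n_nodes"))
  if (r$n_nodes >= 1 || r$n_main_branches >= 1)
    return(list(label = "thick_branched",
                margin = margin(r$n_nodes, 1), rule = "n_nodes"))
  list(label = "unclassified", margin = 0, rule = "none")
}
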