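#' Simulate a limiting-dilution well table under the single-hit model
#'
#' Each well seeded with `dose` cells responds (contains at least one
#' structure-forming cell) with probability `1 - exp(-f * dose)`, the
#' single-hit Poisson assumption used for extreme limiting dilution assays.
#' The default doses are the bench design of 20, 10, 3 and 1 cells per gel.
#'
#' @param true_frequency structure-forming-unit frequency `f` in (0, 1].
#' @param doses positive integer cell doses (distinct).
#' @param wells_per_dose number of replicate wells (gels) per dose.
#' @param seed integer seed.
#' @return a `limiting_dilution_table` data frame with columns
#'   `dose_cells`, `n_wells`, `n_responding`.
#' @examples
#' generate_limiting_dilution(1 / 3, seed = 1)
#' @export
generate_limiting_dilution <- function(true_frequency,
                                       doses = c(20L, 10L, 3L, 1L),
                                       wells_per_dose = 8L, seed = 1L) {
  if (!is.numeric(true_frequency) || length(true_frequency) != 1L ||
      true_frequency <= 0 || true_frequency > 1)
    stop("true_frequency must lie in (0, 1]")
  if (any(doses <= 0)) stop("doses must be positive")
  if (anyDuplicated(doses)) stop("doses must be distinct")
  if (wells_per_dose < 1) stop("wells_per_dose must be >= 1")
  p <- 1 - exp(-true_frequency * doses)
  resp <- with_seed(seed, rbinom(length(doses), wells_per_dose, p))
  out <- data.frame(dose_cells = as.integer(doses),
                    n_wells = as.integer(wells_per_dose),
                    n_responding = as.integer(resp))
  class(out) <- c("limiting_dilution_table", "data.frame")
  out
}

validate_ld_table <- function(table) {
  need <- c("dose_cells", "n_wells", "n_responding")
  if (!all(need %in% names(table)))
    stop("table needs columns ", paste(need, collapse = ", "))
  if (nrow(table) < 1) stop("table needs at least one row")
  if (any(table$n_responding > table$n_wells) || any(table$n_responding < 0))
    stop("n_responding must lie in [0, n_wells]")
  if (any(table$dose_cells <= 0)) stop("doses must be positive")
  if (anyDuplicated(table$dose_cells)) stop("doses must be distinct")
  table
}

#' Simulate a phenotype-labelled negative binomial count matrix
#'
#' Gene-wise baseline means are drawn lognormally; a disjoint block of
#' `planted_per_phenotype` marker genes per phenotype is up-shifted by
#' `log2fc` in that phenotype's samples only. Counts are NB with variance
#' `mu + dispersion * mu^2`, scaled by per-sample library-size factors drawn
#' uniformly in `depth_range` (recorded in the output).
#'
#' @param n_genes number of genes.
#' @param phenotypes per-sample phenotype labels (e.g. 3 replicates each of
#'   3 phenotypes).
#' @param planted_per_phenotype marker genes planted per phenotype.
#' @param log2fc log2 fold change of planted genes in their phenotype.
#' @param dispersion NB dispersion (alpha); variance = mu + alpha mu^2.
#' @param depth_range range of per-sample library-size factors.
#' @param mean_log_mu,sd_log_mu lognormal parameters of baseline gene means.
#' @param seed integer seed.
#' @return a `count_truth` list: `counts` (genes x samples integer matrix),
#'   `phenotype_labels`, `planted_genes` (phenotype -> gene names),
#'   `true_log2fc`, `dispersion`, `library_size_factors`.
#' @examples
#' ct <- generate_count_matrix(200, rep(c("A", "B"), each = 3), 10,
#'                             log2fc = 3, seed = 1)
#' dim(ct$counts)
#' @export
generate_count_matrix <- function(n_genes, phenotypes, planted_per_phenotype,
                                  log2fc = 3, dispersion = 0.1,
                                  depth_range = c(0.5, 2), seed = 1L,
                                  mean_log_mu = log(60), sd_log_mu = 1) {
  phenotypes <- as.character(phenotypes)
  ph <- unique(phenotypes)
  if (planted_per_phenotype * length(ph) >= n_genes)
    stop("planted genes must be fewer than n_genes")
  if (dispersion <= 0) stop("dispersion must be > 0")
  tab <- table(phenotypes)
  if (length(tab) < 1 || any(tab < 1)) stop("invalid replicate structure")
  with_seed(seed, {
    ns <- length(phenotypes)
    genes <- sprintf("gene_%05d", seq_len(n_genes))
    samples <- sprintf("%s_rep%d", phenotypes,
                       stats::ave(seq_len(ns), phenotypes, FUN = seq_along))
    base_mu <- rlnorm(n_genes, mean_log_mu, sd_log_mu)
    sf <- runif(ns, depth_range[1], depth_range[2])
    planted <- list()
    pool <- seq_len(n_genes)
    for (p in ph) {
      idx <- pool[seq_len(planted_per_phenotype)]
      pool <- setdiff(pool, idx)
      planted[[p]] <- genes[idx]
    }
    fc <- matrix(1, n_genes, ns)
    for (p in ph) {
      gi <- match(planted[[p]], genes)
      fc[gi, phenotypes == p] <- 2^log2fc
    }
    mu <- (base_mu * fc) * rep(sf, each = n_genes)
    counts <- matrix(rnbinom(n_genes * ns, mu = mu, size = 1 / dispersion),
                     n_genes, ns, dimnames = list(genes, samples))
    structure(list(counts = counts, phenotype_labels = phenotypes,
                   planted_genes = planted, true_log2fc = log2fc,
                   dispersion = dispersion, library_size_factors = sf,
                   base_mu = base_mu),
              class = "count_truth")
  })
}

#' Simulate a 7-point 3-fold serial-dilution viability curve
#'
#' Viability follows a Hill curve
#' `v(c) = floor + (1 - floor) / (1 + (c / gi50)^hill)` with seeded Gaussian
#' noise, clipped to `[0, 1.2]` (relative to vehicle control).
#'
#' @param gi50 concentration of half-maximal growth inhibition (same units
#'   as `concentrations`).
#' @param hill Hill slope (> 0).
#' @param floor_viability lower asymptote in `[0, 1)`.
#' @param noise_sd standard deviation of additive measurement noise.
#' @param concentrations increasing concentration series; the default is a
#'   7-point 3-fold dilution ending at 10 (e.g. micromolar).
#' @param seed integer seed.
#' @return a `dose_response_curve` list: `concentrations`, `viability`,
#'   `true_gi50`, `hill`, `floor`, `noise_sd`.
#' @examples
#' generate_dose_response(gi50 = 0.37, noise_sd = 0)$viability
#' @export
generate_dose_response <- function(gi50, hill = 1, floor_viability = 0,
                                   noise_sd = 0.03,
                                   concentrations = 10 / 3^(6:0), seed = 1L) {
  stopifnot_scalar_pos(gi50, "gi50")
  stopifnot_scalar_pos(hill, "hill")
  if (floor_viability < 0 || floor_viability >= 1)
    stop("floor_viability must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  v <- floor_viability + (1 - floor_viability) /
    (1 + (concentrations / gi50)^hill)
  if (noise_sd > 0)
    v <- with_seed(seed, v + rnorm(length(v), 0, noise_sd))
  structure(list(concentrations = concentrations,
                 viability = clamp(v, 0, 1.2), true_gi50 = gi50,
                 hill = hill, floor = floor_viability, noise_sd = noise_sd),
            class = "dose_response_curve")
}
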